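# Independent oracles used to cross-check the package implementation.
# Everything here is written from first principles, not by calling the code
# path under test.

# signed dihedral by explicit plane-basis projection (independent of the
# cross-product atan2 formula used in the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  e1 <- (p1 - p2) - b2 * sum((p1 - p2) * b2) / sum(b2 * b2)  # component of
  e3 <- (p4 - p3) - b2 * sum((p4 - p3) * b2) / sum(b2 * b2)  # bonds off-axis
  e1 <- e1 / sqrt(sum(e1^2)); e3 <- e3 / sqrt(sum(e3^2))
  cosg <- max(-1, min(1, sum(e1 * e3)))
  # sign from the handedness of (e1, e3, b2)
  s <- sign(det(rbind(e1, e3, b2)))
  g <- acos(cosg) * 180 / pi * ifelse(s == 0, 1, s)
  if (g <= -180) g <- g + 360
  g
}

# optimal-superposition RMSD by the Horn quaternion method
oracle_rmsd_quaternion <- function(x, y) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  M <- crossprod(yc, xc)  # 3x3 correlation
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# DBSCAN by brute-force enumeration: core points, union-find over
# core-core links, then border attachment
oracle_dbscan <- function(dm, eps, min_size) {
  n <- nrow(dm)
  if (n == 0) return(integer(0))
  nbrs <- dm <= eps
  core <- rowSums(nbrs) >= min_size
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && core[i] && core[j] && nbrs[i, j]) {
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels <- integer(n)
  cl <- 0L
  seen <- integer(0)
  for (i in seq_len(n)) {
    if (!core[i]) next
    r <- root[i]
    if (!r %in% seen) { cl <- cl + 1L; seen <- c(seen, r) }
    labels[i] <- match(r, seen)
  }
  for (i in seq_len(n)) {            # border points: any reachable core wins
    if (core[i] || labels[i] != 0L) next
    cands <- which(nbrs[i, ] & core)
    if (length(cands)) labels[i] <- labels[cands[1L]]
  }
  labels
}

# plain Lennard-Jones closed form
oracle_lj <- function(r, sigma, eps) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)

# central-difference forces of the (weighted) total energy; five-point
# central stencil so that truncation and roundoff both stay well below the
# 1e-5 relative comparison threshold
fd_forces <- function(chain, params, h = 1e-3) {
  anc <- chain$anchors
  ene <- function(a) total_energy(set_anchors(chain, a), params)$total
  fd <- matrix(0, nrow(anc), 3)
  for (i in seq_len(nrow(anc))) for (k in 1:3) {
    e <- vapply(c(-2, -1, 1, 2), function(m) {
      a <- anc; a[i, k] <- a[i, k] + m * h; ene(a)
    }, numeric(1))
    fd[i, k] <- -(e[1] - 8 * e[2] + 8 * e[3] - e[4]) / (12 * h)
  }
  fd
}

# reproducible mildly compact random chain (perturbed extended conformation,
# optionally shrunk so non-bonded pairs interact appreciably)
make_random_chain <- function(dp, params, seed, jitter = 0.5, shrink = 1) {
  set.seed(seed)
  ch <- build_chain(dp, params)
  anc <- ch$anchors * shrink + matrix(stats::rnorm(3 * (dp + 1), 0, jitter),
                                      dp + 1, 3)
  set_anchors(ch, anc)
}

# isolate one energy-term weight
isolate_term <- function(params, term, value = 1) {
  params$weights[] <- 0
  params$weights[[term]] <- value
  params
}

# random rotation matrix from a seeded QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# R-side assembly of all non-bonded pair terms from the exported per-term
# functions (the independent route against the compiled kernel)
assemble_nonbonded <- function(chain, params) {
  dp <- chain$dp
  nb <- c(GBerne = 0, polGB = 0, pol = 0, caviso = 0, cavtail = 0,
          vdw = 0, eel = 0)
  for (i in seq_len(dp - 1)) for (j in (i + 1):dp) {
    if (j - i <= params$exclude_near) next
    ui <- chain$axes[i, ]; uj <- chain$axes[j, ]
    qi <- chain$charges[i]; qj <- chain$charges[j]
    nb["GBerne"] <- nb["GBerne"] +
      gay_berne(chain$tails[i, ], chain$tails[j, ], ui, uj, params)
    nb["polGB"] <- nb["polGB"] +
      gb_polarization(chain$heads[i, ], chain$heads[j, ], qi, qj, params)
    nb["pol"] <- nb["pol"] +
      head_tail_polarization(chain$heads[i, ], chain$tails[i, ], qi,
                             chain$heads[j, ], chain$tails[j, ], qj, params)
    nb["caviso"] <- nb["caviso"] +
      cavity_iso(chain$heads[i, ], chain$heads[j, ], params)
    nb["cavtail"] <- nb["cavtail"] +
      cavity_tails(chain$tails[i, ], chain$tails[j, ], ui, uj, params)
    nb["vdw"] <- nb["vdw"] + lj_heads(chain$heads[i, ], chain$heads[j, ], params)
    nb["eel"] <- nb["eel"] +
      electrostatics(chain$heads[i, ], chain$heads[j, ], qi, qj, params)
  }
  nb
}
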