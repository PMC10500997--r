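#' Build a coarse-grained heparin chain
#'
#' Constructs the reduced representation of a heparin fragment of `dp` sugar
#' residues: `dp + 1` glycosidic-oxygen anchor points connected by virtual
#' bonds, one interaction site per residue placed exactly midway between its
#' flanking anchors, and a charged head / uncharged tail on each site.
#' Residues alternate IdoA2S / GlcNS6S with per-residue charges taken from
#' `params$charge_split`, so every disaccharide carries a net charge of -4 e.
#'
#' @param dp Degree of polymerization (number of residues), `>= 2`.
#' @param params A [cg_params()] object.
#' @param template Either `"extended"` (all virtual-bond dihedrals at 180
#'   degrees, bond lengths and angles at their equilibrium values - the
#'   maximal end-to-end start used for production runs), or a numeric
#'   `(dp + 1) x 3` matrix of explicit anchor coordinates (Angstrom), such as
#'   one produced by [make_helix_template()].
#'
#' @return An object of class `hp_chain` with fields `dp`, `anchors`,
#'   `sites`, `heads`, `tails`, `charges`, `d` (virtual-bond lengths),
#'   `theta` (virtual-bond angles, degrees) and `gamma` (virtual-bond
#'   dihedrals, degrees in (-180, 180]).
#' @export
#' @examples
#' ch <- build_chain(12, cg_params())
#' sum(ch$charges)  # -24 e
build_chain <- function(dp, params = cg_params(), template = "extended") {
  if (!is.numeric(dp) || length(dp) != 1L || dp != round(dp) || dp < 2) {
    stop("invalid chain: dp must be an integer >= 2", call. = FALSE)
  }
  dp <- as.integer(dp)
  validate_params(params)
  if (is.character(template) && identical(template, "extended")) {
    anchors <- rebuild_cartesian(
      d = rep(params$d0, dp),
      theta = rep(params$theta0, max(dp - 1L, 0L)),
      gamma = rep(180, max(dp - 2L, 0L))
    )
  } else if (is.matrix(template) && is.numeric(template)) {
    if (nrow(template) != dp + 1L || ncol(template) != 3L) {
      stop("topology mismatch: template must provide dp + 1 = ", dp + 1L,
           " anchor rows (got ", nrow(template), ")", call. = FALSE)
    }
    anchors <- template
  } else {
    stop("template must be \"extended\" or a (dp+1) x 3 anchor matrix",
         call. = FALSE)
  }
  dimnames(anchors) <- NULL
  charges <- rep_len(params$charge_split, dp)
  chain <- structure(
    list(dp = dp, anchors = anchors, charges = charges,
         head_offset = params$head_offset, tail_offset = params$tail_offset),
    class = "hp_chain"
  )
  update_geometry(chain)
}

# recompute every derived geometric field from the anchors
update_geometry <- function(chain) {
  a <- chain$anchors
  dp <- chain$dp
  chain$sites <- (a[seq_len(dp), , drop = FALSE] + a[seq_len(dp) + 1L, , drop = FALSE]) / 2
  ic <- internal_coordinates(chain)
  chain$d <- ic$d
  chain$theta <- ic$theta
  chain$gamma <- ic$gamma
  chain <- place_head_tail(chain)
  chain
}

#' Replace the anchor coordinates of a chain
#'
#' Returns the chain with new anchors and every derived quantity (sites,
#' heads, tails, internal coordinates) recomputed.
#'
#' @param chain An `hp_chain`.
#' @param anchors Numeric `(dp + 1) x 3` matrix, Angstrom.
#' @return The updated `hp_chain`.
#' @export
set_anchors <- function(chain, anchors) {
  stopifnot(inherits(chain, "hp_chain"))
  if (!is.matrix(anchors) || nrow(anchors) != chain$dp + 1L || ncol(anchors) != 3L) {
    stop("topology mismatch: need a ", chain$dp + 1L, " x 3 anchor matrix",
         call. = FALSE)
  }
  chain$anchors <- unname(anchors)
  update_geometry(chain)
}

#' Internal coordinates of a virtual-bond chain
#'
#' Computes the virtual-bond lengths `d_i`, virtual-bond angles `theta_i`
#' (vertex angle at each interior anchor; 180 degrees is collinear) and
#' virtual-bond dihedrals `gamma_i` (cis = 0, trans/extended = 180, reported
#' in (-180, 180]) from the anchor positions.
#'
#' A degenerate dihedral (collinear anchor triple) is set to 180 degrees -
#' continuous with the extended conformation - and a warning is emitted.
#'
#' @param chain An `hp_chain`, or a numeric `n x 3` anchor matrix (`n >= 2`).
#' @return A list with numeric vectors `d` (length n-1), `theta` (n-2) and
#'   `gamma` (n-3), angles in degrees.
#' @export
internal_coordinates <- function(chain) {
  a <- if (inherits(chain, "hp_chain")) chain$anchors else chain
  if (!is.matrix(a) || ncol(a) != 3L || nrow(a) < 2L) {
    stop("need at least 2 anchors", call. = FALSE)
  }
  n <- nrow(a)
  b <- a[-1L, , drop = FALSE] - a[-n, , drop = FALSE]      # bond vectors
  d <- sqrt(rowSums(b * b))
  if (any(d < 1e-12)) stop("coincident consecutive anchors", call. = FALSE)
  theta <- numeric(0)
  if (n >= 3L) {
    # vertex angle between -b[i] and b[i+1]
    dots <- -rowSums(b[-(n - 1L), , drop = FALSE] * b[-1L, , drop = FALSE])
    cosv <- pmin(1, pmax(-1, dots / (d[-(n - 1L)] * d[-1L])))
    theta <- acos(cosv) * 180 / pi
  }
  gamma <- numeric(0)
  if (n >= 4L) {
    gamma <- vapply(seq_len(n - 3L), function(i) {
      dihedral_angle(a[i, ], a[i + 1L, ], a[i + 2L, ], a[i + 3L, ])
    }, numeric(1))
  }
  list(d = d, theta = theta, gamma = gamma)
}

# signed dihedral, degrees in (-180, 180]; cis = 0.  Collinear triples are
# degenerate: returns 180 with a warning (continuous with the extended chain).
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-18 || sum(n2 * n2) < 1e-18) {
    warning("degenerate dihedral (collinear anchors); set to 180 degrees by convention",
            call. = FALSE)
    return(180)
  }
  b2n <- b2 / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2n)
  g <- atan2(y, x) * 180 / pi
  if (g <= -180) g <- g + 360
  g
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rebuild Cartesian anchors from internal coordinates
#'
#' Inverse of [internal_coordinates()]: places the first anchor at the
#' origin, the second along +x and the third in the xy-plane (standard
#' orientation), then chains each further anchor from its bond length,
#' virtual-bond angle and dihedral.
#'
#' @param d Virtual-bond lengths, length `n` (Angstrom, all > 0).
#' @param theta Virtual-bond angles, length `n - 1` (degrees, in (0, 180]).
#' @param gamma Virtual-bond dihedrals, length `n - 2` (degrees).
#' @return A numeric `(n + 1) x 3` anchor matrix.
#' @export
rebuild_cartesian <- function(d, theta, gamma) {
  n <- length(d)
  if (n < 1L) stop("need at least one virtual bond", call. = FALSE)
  if (length(theta) != max(n - 1L, 0L) || length(gamma) != max(n - 2L, 0L)) {
    stop("inconsistent internal-coordinate lengths (need n, n-1, n-2)",
         call. = FALSE)
  }
  if (any(d <= 0)) stop("invalid geometry: bond lengths must be > 0", call. = FALSE)
  if (length(theta) && any(theta <= 0 | theta > 180)) {
    stop("invalid geometry: theta must lie in (0, 180] degrees", call. = FALSE)
  }
  a <- matrix(0, n + 1L, 3L)
  a[2L, ] <- c(d[1L], 0, 0)
  if (n >= 2L) {
    th <- theta[1L] * pi / 180
    a[3L, ] <- a[2L, ] + d[2L] * c(-cos(th), sin(th), 0)
  }
  if (n >= 3L) {
    for (i in 3:n) {
      th <- theta[i - 1L] * pi / 180
      ga <- gamma[i - 2L] * pi / 180
      b_prev <- a[i, ] - a[i - 1L, ]
      b_pp <- a[i - 1L, ] - a[i - 2L, ]
      u <- b_prev / sqrt(sum(b_prev^2))
      nv <- cross3(b_pp, b_prev)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) {           # previous triple collinear: pick any normal
        nv <- if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
        nn <- sqrt(sum(nv^2))
      }
      nv <- nv / nn
      m <- cross3(nv, u)
      # local frame (u, m, nv); gamma follows the cis = 0 convention of
      # internal_coordinates()
      dir <- -cos(th) * u + sin(th) * (cos(ga) * m + sin(ga) * nv)
      a[i + 1L, ] <- a[i, ] + d[i] * dir
    }
  }
  a
}

#' Place heads and tails on a chain
#'
#' The head (center of charge) and tail (uncharged part) of site `i` are
#' displaced from the site center along the site axis - the unit vector of
#' virtual bond `i` - by the signed offsets carried by the chain (set from
#' [cg_params()] at build time, overridable here).  Zero offsets collapse
#' head = tail = site, forcing the isotropic limit of every
#' orientation-dependent energy term.
#'
#' @param chain An `hp_chain`.
#' @param params Optional [cg_params()]; when given, its `head_offset` /
#'   `tail_offset` replace the chain's stored offsets.
#' @return The chain with `heads` and `tails` matrices (`dp x 3`) set.
#' @export
place_head_tail <- function(chain, params = NULL) {
  stopifnot(inherits(chain, "hp_chain"))
  if (!is.null(params)) {
    chain$head_offset <- params$head_offset
    chain$tail_offset <- params$tail_offset
  }
  dp <- chain$dp
  a <- chain$anchors
  b <- a[seq_len(dp) + 1L, , drop = FALSE] - a[seq_len(dp), , drop = FALSE]
  u <- b / chain$d
  chain$axes <- u
  chain$heads <- chain$sites + chain$head_offset * u
  chain$tails <- chain$sites + chain$tail_offset * u
  chain
}

#' @export
print.hp_chain <- function(x, ...) {
  cat(sprintf("Heparin CG chain: dp %d (%d anchors), total charge %+g e\n",
              x$dp, x$dp + 1L, sum(x$charges)))
  cat(sprintf("  contour length %.2f A, end-to-end %.2f A\n",
              sum(x$d), end_to_end_distance(x)))
  invisible(x)
}

# invariant checks used by tests and by the dynamics driver on load
check_chain <- function(chain, tol = 1e-9) {
  stopifnot(inherits(chain, "hp_chain"))
  a <- chain$anchors
  dp <- chain$dp
  mid <- (a[seq_len(dp), , drop = FALSE] + a[seq_len(dp) + 1L, , drop = FALSE]) / 2
  if (max(abs(mid - chain$sites)) > tol) stop("midpoint invariant violated")
  dd <- sqrt(rowSums((a[-1L, , drop = FALSE] - a[-(dp + 1L), , drop = FALSE])^2))
  if (max(abs(dd - chain$d)) > tol) stop("virtual-bond lengths inconsistent")
  invisible(TRUE)
}
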