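#' End-to-end distance of a chain or frame
#'
#' Euclidean distance between the first and last glycosidic-oxygen anchors -
#' the chain termini, matching the experimental definition.
#'
#' @param frame An `hp_chain`, a numeric `n x 3` anchor matrix, or a
#'   `cg_trajectory` (per-frame vector returned).
#' @return Distance(s) in Angstrom.
#' @export
end_to_end_distance <- function(frame) {
  if (inherits(frame, "cg_trajectory")) {
    return(apply(frame$frames, 1L, function(f) end_to_end_distance(matrix(f, ncol = 3L))))
  }
  a <- if (inherits(frame, "hp_chain")) frame$anchors else frame
  if (!is.matrix(a) || nrow(a) < 2L) stop("need at least 2 anchors", call. = FALSE)
  sqrt(sum((a[nrow(a), ] - a[1L, ])^2))
}

#' Radius of gyration over interaction sites
#'
#' Root-mean-square distance of the site centers (uniform masses, one site
#' per residue) from their centroid.
#'
#' @param frame An `hp_chain`, a numeric `n x 3` anchor matrix (sites are the
#'   consecutive midpoints), or a `cg_trajectory`.
#' @return Radius / radii of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame) {
  if (inherits(frame, "cg_trajectory")) {
    return(apply(frame$frames, 1L, function(f) radius_of_gyration(matrix(f, ncol = 3L))))
  }
  s <- if (inherits(frame, "hp_chain")) {
    frame$sites
  } else {
    a <- frame
    n <- nrow(a)
    if (n >= 2L) (a[-n, , drop = FALSE] + a[-1L, , drop = FALSE]) / 2 else a
  }
  ctr <- colMeans(s)
  sqrt(mean(rowSums(sweep(s, 2L, ctr)^2)))
}

#' Anchor RMSD after optimal superposition
#'
#' Minimal root-mean-square deviation between two equal-length anchor sets
#' after optimal rigid-body superposition (Kabsch algorithm: centroids
#' removed, rotation from the SVD of the covariance with a reflection
#' guard).
#'
#' @param frame,reference `hp_chain` objects or numeric `n x 3` anchor
#'   matrices with equal anchor counts.
#' @return RMSD in Angstrom.
#' @export
rmsd_anchors <- function(frame, reference) {
  x <- if (inherits(frame, "hp_chain")) frame$anchors else frame
  y <- if (inherits(reference, "hp_chain")) reference$anchors else reference
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y))) {
    stop("alignment error: anchor counts differ", call. = FALSE)
  }
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  s <- svd(crossprod(yc, xc))
  dsign <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, dsign))
  R <- s$u %*% D %*% t(s$v)
  diffs <- xc %*% t(R) - yc
  sqrt(mean(rowSums(diffs^2)))
}

#' Density-based clustering of trajectory frames (DBSCAN)
#'
#' Clusters conformations by the pairwise anchor RMSD (after optimal
#' superposition) with the DBSCAN algorithm: a frame with at least
#' `min_size` frames (itself included) within `eps` is a core point; clusters
#' are the connected components of core points plus their border frames;
#' everything else is noise.  The representative of a cluster is the frame
#' minimizing the total within-cluster distance.
#'
#' @param trajectory A `cg_trajectory`, or a list of `n x 3` anchor matrices.
#' @param eps Distance cutoff, Angstrom (default 4).
#' @param min_size Minimum cluster size (default 2).
#' @return A `cluster_report` list: `labels` (0 = noise), `n_clusters`,
#'   `representatives` (frame indices, one per cluster), `n_noise`, and the
#'   `distance` matrix used.
#' @export
cluster_frames <- function(trajectory, eps = 4, min_size = 2) {
  frames <- trajectory_frame_list(trajectory)
  n <- length(frames)
  out <- list(labels = integer(0), n_clusters = 0L,
              representatives = integer(0), n_noise = 0L,
              distance = matrix(0, 0, 0))
  class(out) <- "cluster_report"
  if (n == 0L) return(out)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dm[i, j] <- dm[j, i] <- rmsd_anchors(frames[[i]], frames[[j]])
    }
  }
  labels <- dbscan_labels(dm, eps, min_size)
  ncl <- max(labels, 0L)
  reps <- integer(ncl)
  for (k in seq_len(ncl)) {
    members <- which(labels == k)
    tot <- rowSums(dm[members, members, drop = FALSE])
    reps[k] <- members[which.min(tot)]
  }
  out$labels <- labels
  out$n_clusters <- ncl
  out$representatives <- reps
  out$n_noise <- sum(labels == 0L)
  out$distance <- dm
  out
}

# classic DBSCAN on a precomputed distance matrix; labels 0 = noise
dbscan_labels <- function(dm, eps, min_size) {
  n <- nrow(dm)
  labels <- rep.int(0L, n)
  visited <- rep.int(FALSE, n)
  neighbors <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))  # incl. self
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(neighbors[[i]]) < min_size) next   # not core (may become border)
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(neighbors[[i]], i)
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (!visited[j]) {
        visited[j] <- TRUE
        if (length(neighbors[[j]]) >= min_size) {
          queue <- union(queue, setdiff(neighbors[[j]], j))
        }
      }
      if (labels[j] == 0L) labels[j] <- cluster
    }
  }
  labels
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("DBSCAN conformational clusters: %d cluster(s), %d noise frame(s)\n",
              x$n_clusters, x$n_noise))
  if (x$n_clusters > 0L) {
    for (k in seq_len(x$n_clusters)) {
      cat(sprintf("  cluster %d: %d frames, representative frame %d\n",
                  k, sum(x$labels == k), x$representatives[k]))
    }
  }
  invisible(x)
}

#' Percentage error against a reference value
#'
#' `100 * |simulated - reference| / reference`, with the direction (above or
#' below the reference) reported separately.
#'
#' @param simulated Simulated value(s), Angstrom.
#' @param reference Reference value, Angstrom (> 0).
#' @return A data.frame with columns `pe` (percent) and `direction`
#'   (`"above"`, `"below"` or `"exact"`).
#' @export
#' @examples
#' percentage_error(60.12, 60)  # 0.2% above
percentage_error <- function(simulated, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("reference must be a single positive value", call. = FALSE)
  }
  pe <- 100 * abs(simulated - reference) / reference
  dir <- ifelse(simulated > reference, "above",
                ifelse(simulated < reference, "below", "exact"))
  data.frame(pe = pe, direction = dir, stringsAsFactors = FALSE)
}

#' Observable series of a trajectory
#'
#' Per-frame end-to-end distance and radius of gyration, with means and
#' standard deviations over the post-equilibration window (the first
#' `equilibration` fraction of frames is discarded; default 10%).
#'
#' @param trajectory A `cg_trajectory`.
#' @param equilibration Fraction of initial frames to discard in [0, 1).
#' @return A list with vectors `eed`, `rg` (all frames), logical `kept`, and
#'   summary scalars `mean_eed`, `sd_eed`, `mean_rg`, `sd_rg`.
#' @export
observable_series <- function(trajectory, equilibration = 0.1) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  if (equilibration < 0 || equilibration >= 1) {
    stop("equilibration fraction must lie in [0, 1)", call. = FALSE)
  }
  eed <- end_to_end_distance(trajectory)
  rg <- radius_of_gyration(trajectory)
  n <- length(eed)
  first <- min(n, floor(n * equilibration) + 1L)
  kept <- seq_len(n) >= first
  list(eed = eed, rg = rg, kept = kept,
       mean_eed = mean(eed[kept]), sd_eed = stats::sd(eed[kept]),
       mean_rg = mean(rg[kept]), sd_rg = stats::sd(rg[kept]))
}

trajectory_frame_list <- function(trajectory) {
  if (inherits(trajectory, "cg_trajectory")) {
    lapply(seq_len(nrow(trajectory$frames)), function(i) {
      matrix(trajectory$frames[i, ], ncol = 3L)
    })
  } else if (is.list(trajectory)) {
    trajectory
  } else {
    stop("expected a cg_trajectory or a list of anchor matrices", call. = FALSE)
  }
}
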