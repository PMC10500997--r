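test_that("end-to-end distance matches geometry and brute force", {
  p <- cg_params()
  tpl <- cbind(0, 0, (0:6) * 4.5)
  ch <- suppressWarnings(build_chain(6, p, template = tpl))  # collinear template
  expect_equal(end_to_end_distance(ch), 27)
  # near-closed ring
  phi <- seq(0, 2 * pi, length.out = 9)
  ring <- cbind(cos(phi), sin(phi), 0) * 3
  expect_lt(end_to_end_distance(ring), 1e-9)
  set.seed(2)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(end_to_end_distance(a), sqrt(sum((a[10, ] - a[1, ])^2)),
               tolerance = 1e-12)
})

test_that("radius of gyration matches its definition", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(10, 0, 0))   # two sites 10 apart
  expect_equal(radius_of_gyration(structure(list(sites = two), class = "hp_chain")), 5)
  set.seed(3)
  s <- matrix(rnorm(60), 20, 3)
  ch <- structure(list(sites = s), class = "hp_chain")
  ctr <- colMeans(s)
  brute <- sqrt(mean(rowSums((s - matrix(ctr, 20, 3, byrow = TRUE))^2)))
  expect_equal(radius_of_gyration(ch), brute, tolerance = 1e-12)
})

test_that("superposition RMSD agrees with the quaternion oracle and its invariances", {
  set.seed(4)
  a <- matrix(rnorm(36, sd = 4), 12, 3)
  expect_equal(rmsd_anchors(a, a), 0, tolerance = 1e-9)
  R <- random_rotation(9)
  expect_lt(rmsd_anchors(a %*% t(R) + 5, a), 1e-9)
  for (rep in 1:10) {
    b <- matrix(rnorm(36, sd = 4), 12, 3)
    r1 <- rmsd_anchors(a, b)
    expect_equal(r1, oracle_rmsd_quaternion(a, b), tolerance = 1e-9)
    expect_equal(r1, rmsd_anchors(b, a), tolerance = 1e-9)
  }
  expect_error(rmsd_anchors(a, matrix(0, 5, 3)), "alignment")
})

test_that("eed is bounded by contour length and rg by half the diameter", {
  p <- cg_params()
  for (seed in 1:8) {
    ch <- make_random_chain(10, p, seed, jitter = 1.2)
    expect_lte(end_to_end_distance(ch), sum(ch$d) + 1e-9)
    dm <- as.matrix(dist(ch$sites))
    expect_lte(radius_of_gyration(ch), max(dm) / 2 + 1e-9)
  }
})

test_that("DBSCAN clustering matches a brute-force implementation on constructed bundles", {
  p <- cg_params()
  base1 <- make_random_chain(6, p, 1, jitter = 1)$anchors
  base2 <- make_random_chain(6, p, 2, jitter = 6)$anchors
  set.seed(10)
  wiggle <- function(a, s) a + matrix(rnorm(length(a), 0, s), nrow(a), 3)
  frames <- c(lapply(1:4, function(i) wiggle(base1, 0.15)),
              lapply(1:4, function(i) wiggle(base2, 0.15)))
  rep1 <- cluster_frames(frames, eps = 4, min_size = 2)
  expect_equal(rep1$n_clusters, 2L)
  expect_equal(rep1$n_noise, 0L)
  # oracle agreement up to label permutation
  lab_o <- oracle_dbscan(rep1$distance, 4, 2)
  expect_equal(rep1$labels == 0L, lab_o == 0L)
  tab <- table(rep1$labels, lab_o)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # representative minimizes the total within-cluster distance
  for (k in seq_len(rep1$n_clusters)) {
    mem <- which(rep1$labels == k)
    tot <- rowSums(rep1$distance[mem, mem, drop = FALSE])
    expect_equal(rep1$representatives[k], mem[which.min(tot)])
  }
})

test_that("DBSCAN edge cases: identical frames, singletons, empty input, order invariance", {
  p <- cg_params()
  a <- make_random_chain(5, p, 3)$anchors
  same <- lapply(1:5, function(i) a)
  r <- cluster_frames(same, eps = 4, min_size = 2)
  expect_equal(r$n_clusters, 1L)
  expect_equal(r$n_noise, 0L)
  single <- cluster_frames(list(a), eps = 4, min_size = 2)
  expect_equal(single$n_clusters, 0L)
  expect_equal(single$n_noise, 1L)
  empty <- cluster_frames(list(), eps = 4, min_size = 2)
  expect_equal(empty$n_clusters, 0L)
  # frame-order invariance up to label permutation
  set.seed(11)
  frames <- c(lapply(1:3, function(i) a + rnorm(1)),
              lapply(1:3, function(i) a * 2 + 30 + rnorm(1)))
  perm <- c(4, 1, 6, 2, 5, 3)
  r1 <- cluster_frames(frames, eps = 4, min_size = 2)
  r2 <- cluster_frames(frames[perm], eps = 4, min_size = 2)
  expect_equal(r1$n_clusters, r2$n_clusters)
  expect_equal(r1$labels[perm] == 0L, r2$labels == 0L)
})

test_that("percentage error reproduces the printed calibration examples", {
  expect_equal(percentage_error(60, 60)$pe, 0)
  pe1 <- percentage_error(60.12, 60)
  expect_equal(pe1$pe, 0.2, tolerance = 1e-9)
  expect_equal(pe1$direction, "above")
  pe2 <- percentage_error(14.8, 60)
  expect_equal(round(pe2$pe, 1), 75.3)
  expect_equal(pe2$direction, "below")
  expect_error(percentage_error(10, 0), "positive")
})

test_that("observable series discards the equilibration transient", {
  p <- cg_params()
  ch <- build_chain(6, p)
  tr <- run_simulation(ch, p, run_config(n_steps = 2000, snapshot_stride = 100,
                                         seed = 9))
  obs <- observable_series(tr, equilibration = 0.1)
  expect_length(obs$eed, 21L)
  expect_equal(sum(obs$kept), 19L)   # floor(21 * 0.1) = 2 frames dropped
  expect_equal(obs$mean_eed, mean(obs$eed[obs$kept]))
  expect_error(observable_series(tr, equilibration = 1.2), "equilibration")
})
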