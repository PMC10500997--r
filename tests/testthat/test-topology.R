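test_that("build_chain produces the documented topology and charge model", {
  p <- cg_params()
  ch <- build_chain(12, p)
  expect_equal(ch$dp, 12L)
  expect_equal(nrow(ch$anchors), 13L)
  expect_equal(nrow(ch$sites), 12L)
  expect_equal(sum(ch$charges), -24)
  # -4 per disaccharide, every disaccharide
  di <- colSums(matrix(ch$charges, nrow = 2))
  expect_true(all(abs(di + 4) < 1e-12))

  ch2 <- build_chain(2, p)
  expect_length(ch2$theta, 1L)
  expect_length(ch2$gamma, 0L)

  # collinear template: EED equals dp * b
  b <- 4.5
  tpl <- cbind(0, 0, (0:6) * b)
  ch6 <- suppressWarnings(build_chain(6, p, template = tpl))  # collinear
  expect_equal(end_to_end_distance(ch6), 6 * b, tolerance = 1e-12)

  expect_error(build_chain(1, p), "dp must be an integer >= 2")
  expect_error(build_chain(6, p, template = matrix(0, 5, 3)),
               "topology mismatch")
})

test_that("extended template is the all-trans maximal-extension start", {
  p <- cg_params()
  ch <- build_chain(10, p)
  expect_true(all(abs(ch$gamma - 180) < 1e-8))
  expect_true(all(abs(ch$d - p$d0) < 1e-9))
  expect_true(all(abs(ch$theta - p$theta0) < 1e-8))
})

test_that("sites sit exactly midway between their anchors after every operation", {
  p <- cg_params()
  for (seed in 1:5) {
    ch <- make_random_chain(9, p, seed)
    mid <- (ch$anchors[1:9, ] + ch$anchors[2:10, ]) / 2
    expect_lt(max(abs(ch$sites - mid)), 1e-9)
    d <- sqrt(rowSums((ch$anchors[2:10, ] - ch$anchors[1:9, ])^2))
    expect_lt(max(abs(d - ch$d)), 1e-9)
  }
})

test_that("internal coordinates match independent dihedral oracles", {
  # cis square -> gamma 0; trans zig-zag -> gamma 180
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(internal_coordinates(sq)$gamma, 0, tolerance = 1e-12)
  zz <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  expect_equal(abs(internal_coordinates(zz)$gamma), 180, tolerance = 1e-9)

  set.seed(91)
  for (rep in 1:10) {
    a <- matrix(rnorm(15, sd = 3), 5, 3)
    ic <- internal_coordinates(a)
    want <- c(oracle_dihedral(a[1, ], a[2, ], a[3, ], a[4, ]),
              oracle_dihedral(a[2, ], a[3, ], a[4, ], a[5, ]))
    expect_equal(ic$gamma, want, tolerance = 1e-8)
    # cross-check against bio3d's torsion implementation
    tb <- bio3d::torsion.xyz(as.vector(t(a)), atm.inc = 1)
    expect_equal(ic$gamma, tb[2:3], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("degenerate (collinear) dihedral is flagged and set to 180", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_warning(ic <- internal_coordinates(a), "degenerate dihedral")
  expect_equal(ic$gamma, 180)
})

test_that("internal <-> Cartesian round trip is the identity", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 10
    d <- runif(n, 4, 6); th <- runif(n - 1, 60, 175); ga <- runif(n - 2, -179, 179)
    a <- rebuild_cartesian(d, th, ga)
    ic <- internal_coordinates(a)
    expect_equal(ic$d, d, tolerance = 1e-8)
    expect_equal(ic$theta, th, tolerance = 1e-8)
    expect_equal(ic$gamma, ga, tolerance = 1e-8)
  }
  expect_equal(rebuild_cartesian(c(2, 2), 90, numeric(0))[1, ], c(0, 0, 0))
  expect_error(rebuild_cartesian(c(1, 1), 190, numeric(0)), "invalid geometry")
  expect_error(rebuild_cartesian(c(1, 1), c(90, 90), numeric(0)),
               "inconsistent internal-coordinate lengths")
})

test_that("dp 68 chain survives the round trip to high precision", {
  set.seed(68)
  n <- 68
  d <- runif(n, 4.5, 5.5); th <- runif(n - 1, 80, 170); ga <- runif(n - 2, -179, 179)
  a <- rebuild_cartesian(d, th, ga)
  a2 <- rebuild_cartesian(internal_coordinates(a)$d,
                          internal_coordinates(a)$theta,
                          internal_coordinates(a)$gamma)
  expect_lt(max(abs(a - a2)), 1e-6)
})

test_that("head/tail placement follows the local frame and collapses at zero offset", {
  p0 <- cg_params(head_offset = 0, tail_offset = 0)
  ch <- build_chain(6, p0)
  expect_equal(ch$heads, ch$sites)
  expect_equal(ch$tails, ch$sites)

  # explicit hand geometry on a straight dimer with offsets (+1, -1)
  p <- cg_params(head_offset = 1, tail_offset = -1)
  tpl <- cbind(0, 0, c(0, 5, 10))
  ch2 <- build_chain(2, p, template = tpl)  # dp 2: no dihedrals
  expect_equal(ch2$heads[1, ], c(0, 0, 3.5))
  expect_equal(ch2$tails[1, ], c(0, 0, 1.5))
  expect_equal(ch2$heads[2, ], c(0, 0, 8.5))
  expect_equal(sqrt(sum((ch2$heads[1, ] - ch2$tails[2, ])^2)), 3)

  # frame covariance: heads/tails co-rotate with the chain
  R <- random_rotation(17)
  ch3 <- make_random_chain(7, p, 3)
  ch3r <- set_anchors(ch3, ch3$anchors %*% t(R))
  expect_equal(ch3r$heads, ch3$heads %*% t(R), tolerance = 1e-9)
  expect_equal(ch3r$tails, ch3$tails %*% t(R), tolerance = 1e-9)
})
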