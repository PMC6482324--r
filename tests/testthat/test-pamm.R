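test_that("farthest-point sampling is exhaustive, forced, and beats random spread", {
  x <- matrix(stats::rnorm(60), ncol = 2)
  expect_setequal(fps_select(x, 30, seed = 1), 1:30)
  expect_error(fps_select(x, 31), "exceeds")
  # 1D forced case: from {0, 1, 10} starting anywhere, 2 picks must span
  x1 <- matrix(c(0, 1, 10), ncol = 1)
  for (seed in 1:5) {
    sel <- fps_select(x1, 2, seed = seed)
    expect_true(10 %in% abs(diff(x1[sel, ])) ||
                  setequal(x1[sel, ], c(0, 10)) || setequal(x1[sel, ], c(1, 10)))
  }
  # max-min spread of FPS beats random selection across seeds
  set.seed(99)
  blob <- matrix(stats::rnorm(1200), ncol = 2)
  min_pair <- function(idx) min(stats::dist(blob[idx, ]))
  for (seed in 1:20) {
    fps <- fps_select(blob, 50, seed = seed)
    set.seed(seed)
    rnd <- sample.int(nrow(blob), 50)
    expect_gte(min_pair(fps), min_pair(rnd))
  }
})

test_that("the adaptive KDE recovers a known density and partitions samples", {
  set.seed(21)
  x <- matrix(stats::rnorm(50000), ncol = 1)
  grid <- fps_select(x, 300, seed = 2)
  g <- estimate_density(x, grid, bandwidth_scale = 0.3)
  at0 <- which.min(abs(g$positions[, 1]))
  expect_equal(g$density[at0], stats::dnorm(g$positions[at0, 1]),
               tolerance = 0.05)
  expect_equal(sum(g$voronoi_weight), 1, tolerance = 1e-12)
  expect_true(all(g$density >= 0 & is.finite(g$density)))
})

test_that("periodic data gives an identical estimate after a full-period shift", {
  set.seed(4)
  ang <- pammotif:::wrap_principal(stats::rnorm(4000, 90, 25), 360)
  x <- matrix(ang, ncol = 1)
  grid <- fps_select(x, 100, seed = 3, period = 360)
  g1 <- estimate_density(x, grid, period = 360)
  x2 <- matrix(pammotif:::wrap_principal(ang + 360, 360), ncol = 1)
  g2 <- estimate_density(x2, grid, period = 360)
  expect_equal(g1$density, g2$density, tolerance = 1e-12)
})

test_that("degenerate (zero-variance) input names the offending dimension", {
  x <- cbind(a = stats::rnorm(50), b = rep(1, 50))
  expect_error(estimate_density(x, 1:10), "b")
})

test_that("quick-shift recovers the planted number of modes", {
  # one isotropic Gaussian -> one cluster
  x1 <- sample_mixture(list(c(0, 0)), list(1), 1, n = 5000, seed = 1)
  f1 <- pamm(x1[, 1:2], n_grid = 300, seed = 2)
  expect_equal(length(f1$weights), 1L)
  expect_equal(f1$weights, 1)
  # two well-separated Gaussians: modes near the true means
  x2 <- sample_mixture(list(c(0, 0), c(10, 10)), list(1, 1), c(0.5, 0.5),
                       n = 20000, seed = 3)
  f2 <- pamm(x2[, 1:2], n_grid = 500, seed = 2)
  expect_equal(length(f2$weights), 2L)
  mu <- f2$means[order(f2$means[, 1]), ]
  expect_lt(max(abs(mu - rbind(c(0, 0), c(10, 10)))), 0.3)
  # three-mode mixture
  x3 <- sample_mixture(list(c(0, 0), c(4, 0), c(0, 4)),
                       list(0.5, 0.5, 0.5), rep(1 / 3, 3),
                       n = 15000, seed = 4)
  f3 <- pamm(x3[, 1:2], n_grid = 500, seed = 2)
  expect_equal(length(f3$weights), 3L)
})

test_that("mixture weights recover planted weights and pruning renormalizes", {
  x <- sample_mixture(list(c(0, 0), c(8, 8)), list(1, 1), c(0.7, 0.3),
                      n = 20000, seed = 5)
  fit <- pamm(x[, 1:2], n_grid = 500, seed = 6)
  expect_equal(length(fit$weights), 2L)
  expect_equal(sort(fit$weights), c(0.3, 0.7), tolerance = 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  # manual pruning: a cluster holding 1e-6 of the mass disappears
  grid <- fit$grid
  asg <- fit$assignment
  tiny <- which(asg == 2)[1]
  grid$voronoi_weight[asg == 2] <- 0
  grid$voronoi_weight[tiny] <- 1e-6
  grid$voronoi_weight[asg == 1] <-
    grid$voronoi_weight[asg == 1] / sum(grid$voronoi_weight[asg == 1]) * (1 - 1e-6)
  m <- suppressWarnings(build_mixture(grid, asg, prune_threshold = 1e-5))
  expect_equal(length(m$weights), 1L)
  expect_equal(m$weights, 1)
})

test_that("motif identifiers form a partition of unity at zeta = 0", {
  x <- sample_mixture(list(c(0, 0), c(5, 0), c(0, 5)),
                      list(0.6, 0.6, 0.6), c(0.4, 0.35, 0.25),
                      n = 9000, seed = 8)
  fit <- pamm(x[, 1:2], n_grid = 400, seed = 9)
  set.seed(10)
  pts <- cbind(stats::runif(1000, -2, 7), stats::runif(1000, -2, 7))
  F0 <- pamm_pmi(fit, pts, zeta = 0)
  expect_lt(max(abs(rowSums(F0) - 1)), 1e-12)
  # with zeta > 0 every identifier is in (0, 1) and the sum is below 1
  Fz <- pamm_pmi(fit, pts, zeta = 1e-5)
  expect_true(all(Fz >= 0 & Fz < 1))
  expect_true(all(rowSums(Fz) <= 1 + 1e-12))
})

test_that("a single-mode model has identifier identically 1 at zeta = 0", {
  x <- sample_mixture(list(c(0, 0)), list(1), 1, n = 4000, seed = 11)
  fit <- pamm(x[, 1:2], n_grid = 200, seed = 12)
  pts <- cbind(stats::rnorm(50), stats::rnorm(50))
  expect_equal(unname(pamm_pmi(fit, pts, k = 1, zeta = 0)), rep(1, 50))
})

test_that("two symmetric equal modes split the midpoint identifier 50/50", {
  model <- structure(list(
    weights = c(0.5, 0.5),
    means = rbind(c(-2, 0), c(2, 0)),
    covariances = array(rep(diag(2), 2), dim = c(2, 2, 2)),
    zeta = 0, period = NULL, dim_names = c("a", "b"),
    provenance = list()), class = "pamm")
  f <- pamm_pmi(model, rbind(c(0, 0)), zeta = 0)
  expect_equal(as.numeric(f), c(0.5, 0.5))
})

test_that("fitting is deterministic and the model file round-trips bit-exactly", {
  x <- sample_mixture(list(c(0, 0), c(6, 0)), list(0.7, 0.7), c(0.6, 0.4),
                      n = 6000, seed = 13)
  f1 <- pamm(x[, 1:2], n_grid = 300, seed = 14)
  f2 <- pamm(x[, 1:2], n_grid = 300, seed = 14)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$covariances, f2$covariances)
  p1 <- tempfile(); p2 <- tempfile()
  write_pamm(f1, p1); write_pamm(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_pamm(p1)
  expect_identical(back$weights, f1$weights)
  expect_identical(unname(back$means), unname(f1$means))
  expect_identical(back$covariances, f1$covariances)
  expect_identical(back$zeta, f1$zeta)
})

test_that("periodic clustering is invariant under a global angle shift", {
  cm <- three_class_modes(sigma = 12)
  x <- labeled_ramachandran(cm, n = 6000, seed = 15)
  shift <- 100
  x2 <- tibble::tibble(
    phi = pammotif:::wrap_principal(x$phi + shift, 360),
    psi = pammotif:::wrap_principal(x$psi + shift, 360)
  )
  f1 <- pamm(x[, c("phi", "psi")], n_grid = 300, period = 360, seed = 16)
  f2 <- pamm(x2, n_grid = 300, period = 360, seed = 16)
  expect_equal(length(f1$weights), length(f2$weights))
  m1 <- f1$means[order(f1$weights), , drop = FALSE]
  m2 <- f2$means[order(f2$weights), , drop = FALSE]
  back <- pammotif:::wrap_delta(m2 - shift - m1, c(360, 360))
  expect_lt(max(abs(back)), 1e-6)
})
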