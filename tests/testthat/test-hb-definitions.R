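test_that("the distance-angle identifier reproduces its truth table", {
  da <- pmi_distance_angle()
  cases <- tibble::tibble(
    d_DA = c(3.6, 2.8, 2.8, 2.8, 2.8),
    d_AH = c(1.9, 2.6, 1.9, 1.9, 1.9),
    d_DH = c(1.0, 1.0, 1.6, 1.0, 1.0),
    angle_ADH = c(10, 10, 10, 35, 10)
  )
  expect_equal(pmi_evaluate(da, cases), c(0, 0, 0, 0, 1))
})

test_that("relaxing any distance-angle threshold never flips 1 to 0", {
  set.seed(31)
  samp <- tibble::tibble(
    d_DA = stats::runif(500, 2, 4.5), d_AH = stats::runif(500, 1, 3.5),
    d_DH = stats::runif(500, 0.8, 2), angle_ADH = stats::runif(500, 0, 60)
  )
  base <- pmi_evaluate(pmi_distance_angle(), samp)
  relaxed <- list(
    pmi_distance_angle(d_DA_max = 4),
    pmi_distance_angle(d_AH_max = 3),
    pmi_distance_angle(d_DH_max = 1.8),
    pmi_distance_angle(angle_max = 45)
  )
  for (p in relaxed) expect_true(all(pmi_evaluate(p, samp) >= base))
})

test_that("the hydrogen-bond mode is the one nearest the reference point", {
  mk <- function(means) structure(list(
    weights = rep(1 / nrow(means), nrow(means)), means = means,
    covariances = array(rep(diag(2) * 0.01, nrow(means)),
                        dim = c(2, 2, nrow(means))),
    zeta = 1e-5, period = NULL, dim_names = c("d_AH", "d_DA"),
    provenance = list()), class = "pamm")
  expect_equal(identify_hb_mode(mk(rbind(c(1.8, 2.7), c(1.0, 1.5)))), 1L)
  expect_equal(identify_hb_mode(mk(rbind(c(9, 9)))), 1L)
  expect_equal(identify_hb_mode(mk(rbind(c(3, 4), c(1.82, 2.74), c(0.9, 1.4)))), 2L)
})

test_that("the PAMM identifier is confident at the planted bond mode", {
  x <- sample_mixture(
    means = list(c(1.82, 2.74), c(3.2, 2.3)),
    sigmas = list(diag(c(0.12, 0.12)^2), diag(c(0.15, 0.15)^2)),
    weights = c(0.55, 0.45), n = 12000, seed = 32
  )
  names(x)[1:2] <- c("d_AH", "d_DA")
  fit <- pamm(x[, c("d_AH", "d_DA")], n_grid = 400, seed = 33)
  p <- pmi_pamm(fit)
  expect_gt(pmi_evaluate(p, tibble::tibble(d_AH = 1.82, d_DA = 2.74)), 0.9)
})

test_that("the DSSP-energy identifier recovers a planted bonded fraction", {
  set.seed(34)
  n <- 10000
  hb <- stats::runif(n) < 0.4
  quads <- tibble::tibble(
    energy = ifelse(hb, -1.5, 0.2),
    d_AH = ifelse(hb, stats::rnorm(n, 1.9, 0.1), stats::rnorm(n, 3.0, 0.15)),
    d_DA = ifelse(hb, stats::rnorm(n, 2.9, 0.1), stats::rnorm(n, 2.25, 0.15))
  )
  p <- fit_dssp_pmi(quads, n_grid = 400)
  expect_equal(p$p_hb, 0.4, tolerance = 0.025)
  expect_gt(pmi_evaluate(p, tibble::tibble(d_AH = 1.9, d_DA = 2.9)), 0.5)
  # with every quadruplet bonded and zeta = 0 the identifier collapses to 1
  all_pos <- quads[hb, ]
  p1 <- fit_dssp_pmi(all_pos, zeta = 0, n_grid = 200)
  sc <- pmi_evaluate(p1, all_pos[1:50, ])
  expect_equal(sc, rep(1, 50))
  # refusing to fit with no bonded quadruplets
  expect_error(fit_dssp_pmi(quads[!hb, ]), "refusing")
})

test_that("agreement is 1 for self, symmetric, and 0 for disjoint identifiers", {
  set.seed(35)
  samp <- tibble::tibble(
    d_AH = stats::runif(10000, 1.2, 4), d_DA = stats::runif(10000, 1.8, 4.5),
    d_DH = stats::runif(10000, 0.9, 2.2), angle_ADH = stats::runif(10000, 0, 60)
  )
  da <- pmi_distance_angle()
  expect_equal(pmi_similarity(samp, da, da)$delta, 1, tolerance = 1e-9)
  quads <- tibble::tibble(
    energy = c(rep(-2, 2000), rep(1, 3000)),
    d_AH = c(stats::rnorm(2000, 1.9, 0.1), stats::rnorm(3000, 3.0, 0.2)),
    d_DA = c(stats::rnorm(2000, 2.9, 0.1), stats::rnorm(3000, 2.3, 0.2))
  )
  dssp <- fit_dssp_pmi(quads, n_grid = 200)
  expect_equal(pmi_similarity(samp, dssp, dssp)$delta, 1, tolerance = 1e-9)
  s_ab <- pmi_similarity(samp, da, dssp)$delta
  s_ba <- pmi_similarity(samp, dssp, da)$delta
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  expect_gte(s_ab, 0); expect_lte(s_ab, 1)
  ia <- pammotif:::new_pmi("distance_angle", function(d) as.numeric(d$d_AH < 2))
  ib <- pammotif:::new_pmi("distance_angle", function(d) as.numeric(d$d_AH >= 3))
  expect_identical(pmi_similarity(samp, ia, ib)$delta, 0)
  # an everywhere-zero identifier is an explicit error
  iz <- pammotif:::new_pmi("distance_angle", function(d) numeric(nrow(d)))
  expect_error(pmi_similarity(samp, da, iz), "zero")
})

test_that("sequence restriction removes intra-residue disagreements", {
  # all disagreement points are intra-residue by construction
  agree <- tibble::tibble(
    d_AH = stats::runif(300, 1.5, 2.0), d_DA = stats::runif(300, 2.5, 3.0),
    donor_chain = "A", donor_resno = 1:300,
    acceptor_chain = "A", acceptor_resno = 1:300 + 5L
  )
  disagree <- tibble::tibble(
    d_AH = stats::runif(100, 3.5, 4.0), d_DA = stats::runif(100, 2.0, 2.4),
    donor_chain = "A", donor_resno = 1:100,
    acceptor_chain = "A", acceptor_resno = 1:100
  )
  samp <- dplyr::bind_rows(agree, disagree)
  fa <- pammotif:::new_pmi("distance_angle", function(d) as.numeric(d$d_AH < 2.2))
  fb <- pammotif:::new_pmi("distance_angle",
                           function(d) as.numeric(d$d_AH < 2.2 | d$d_DA < 2.4))
  full <- pmi_similarity(samp, fa, fb)
  restr <- restricted_similarity(samp, fa, fb, "same_residue")
  expect_lt(full$delta, 1)
  expect_equal(restr$delta, 1, tolerance = 1e-12)
  # a restriction that removes nothing leaves the score unchanged
  only_agree <- restricted_similarity(agree, fa, fb, "same_residue")
  expect_equal(only_agree$delta, pmi_similarity(agree, fa, fb)$delta)
  # adjacent-residue exclusion also drops |sep| == 1, different chains never
  cross <- agree
  cross$acceptor_chain <- "B"
  cross$acceptor_resno <- cross$donor_resno
  expect_equal(nrow(restrict_samples(cross, "adjacent_residue")), nrow(cross))
  near <- agree
  near$acceptor_resno <- near$donor_resno + 1L
  expect_equal(nrow(restrict_samples(near, "adjacent_residue")), 0L)
  expect_error(restricted_similarity(near, fa, fb, "adjacent_residue"), "every sample")
})
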