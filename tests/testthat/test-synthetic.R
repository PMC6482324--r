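test_that("mixture sampling matches its specification statistically", {
  means <- list(c(0, 0), c(5, 5), c(-5, 5))
  weights <- c(0.5, 0.3, 0.2)
  x <- sample_mixture(means, list(0.4, 0.4, 0.4), weights, n = 10000, seed = 81)
  # component frequencies within 3 sigma of the multinomial expectation
  freq <- tabulate(x$component, 3) / nrow(x)
  for (k in 1:3) {
    se <- sqrt(weights[k] * (1 - weights[k]) / nrow(x))
    expect_lt(abs(freq[k] - weights[k]), 3 * se)
  }
  # component means within 4 sigma / sqrt(n_k) of their targets
  for (k in 1:3) {
    sub <- x[x$component == k, 1:2]
    n_k <- nrow(sub)
    expect_lt(max(abs(colMeans(as.matrix(sub)) - means[[k]])), 4 * 0.4 / sqrt(n_k))
  }
  # weights of length 1 put every sample in component 1
  x1 <- sample_mixture(list(c(0, 0)), list(1), 1, n = 50, seed = 1)
  expect_true(all(x1$component == 1L))
  expect_error(
    sample_mixture(list(c(0, 0)), list(matrix(c(1, 2, 2, 1), 2)), 1, 10),
    "positive definite")
  expect_error(sample_mixture(means, list(1, 1, 1), c(0.5, 0.4), 10), "length")
})

test_that("generators are seeded and bit-reproducible", {
  a <- sample_mixture(list(c(0, 0)), list(1), 1, n = 100, seed = 7)
  b <- sample_mixture(list(c(0, 0)), list(1), 1, n = 100, seed = 7)
  expect_identical(a, b)
  b1 <- build_backbone(phi = -57, psi = -47, n_residues = 5, noise_sd = 0.02, seed = 3)
  b2 <- build_backbone(phi = -57, psi = -47, n_residues = 5, noise_sd = 0.02, seed = 3)
  expect_identical(b1$atoms, b2$atoms)
  r1 <- labeled_ramachandran(three_class_modes(), 100, seed = 5)
  r2 <- labeled_ramachandran(three_class_modes(), 100, seed = 5)
  expect_identical(r1, r2)
})

test_that("the toy hydrogen-bond structure realizes its geometries exactly", {
  geo <- hb_toy_geometries()
  toy <- build_hb_toy(geo)
  atoms <- toy$atoms
  # per-flavor filtered counts equal the specification
  for (fl in unique(geo$flavor)) {
    tr <- filter_hb_triplets(hb_triplets(atoms, fl))
    expect_equal(nrow(tr), sum(geo$flavor == fl), info = fl)
  }
  # distances and angle recovered to high precision, pre-write
  tr <- dplyr::bind_rows(lapply(unique(geo$flavor), function(fl)
    filter_hb_triplets(hb_triplets(atoms, fl))))
  tr <- tr[order(tr$donor_resno), ]
  gt <- attr(toy, "ground_truth")[order(attr(toy, "ground_truth")$resno), ]
  expect_equal(tr$d_DA, gt$d_DA, tolerance = 1e-9)
  expect_equal(tr$d_AH, gt$d_AH, tolerance = 1e-9)
  expect_equal(tr$d_DH, gt$d_DH, tolerance = 1e-9)
  expect_equal(tr$angle_ADH, gt$angle_ADH, tolerance = 1e-7)
  # a geometry violating the sum filter yields no filtered triplet
  far <- build_hb_toy(tibble::tibble(flavor = "N-H...O", d_DA = 6.5,
                                     d_AH = 4.0, d_DH = 2.6))
  expect_equal(nrow(filter_hb_triplets(hb_triplets(far$atoms, "N-H...O"))), 0L)
  # infeasible distances are rejected
  expect_error(build_hb_toy(tibble::tibble(flavor = "N-H...O", d_DA = 5,
                                           d_AH = 1, d_DH = 1)),
               "triangle")
  # a stated angle inconsistent with the distances is rejected
  bad <- hb_toy_geometries()[1, ]
  bad$angle_ADH <- 25
  expect_error(build_hb_toy(bad), "inconsistent")
})

test_that("labeled Ramachandran draws live on the torus with true labels", {
  cm <- three_class_modes(sigma = 10)
  x <- labeled_ramachandran(cm, 3000, seed = 9)
  expect_true(all(x$phi > -180 & x$phi <= 180))
  expect_true(all(x$psi > -180 & x$psi <= 180))
  expect_setequal(unique(x$label), c("H", "E", "C"))
  # each sample lies near its own class mode (10 sigma separation)
  for (k in 1:3) {
    sub <- x[x$label == cm$code[k], ]
    dphi <- abs(((sub$phi - cm$phi[k] + 180) %% 360) - 180)
    expect_lt(max(dphi), 6 * cm$sigma[k])
  }
  expect_error(labeled_ramachandran(tibble::tibble(
    code = "Q", phi = 0, psi = 0, sigma = 1, weight = 1), 10), "unknown")
})

test_that("generated PDB files are column-compliant for an external reader", {
  toy <- build_hb_toy(hb_toy_geometries())
  f <- tempfile(fileext = ".pdb")
  write_pdb(toy, f)
  res <- system2("python", c("-c", shQuote(paste0(
    "from Bio.PDB import PDBParser; import warnings; warnings.filterwarnings('ignore'); ",
    "s = PDBParser().get_structure('t', '", f, "'); ",
    "print(sum(1 for a in s.get_atoms()))"
  ))), stdout = TRUE, stderr = FALSE)
  expect_equal(as.integer(res[length(res)]), nrow(toy$atoms))
})

test_that("ground-truth sidecars accompany every generated structure", {
  toy <- build_hb_toy(hb_toy_geometries())
  f <- tempfile(fileext = ".tsv")
  write_ground_truth(toy, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(hb_toy_geometries()))
  expect_true(all(c("flavor", "d_DA", "d_AH", "d_DH", "angle_ADH") %in% names(back)))
  plain <- pammotif:::new_protein_structure("x", 1, toy$atoms)
  expect_error(write_ground_truth(plain, f), "no ground truth")
})
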