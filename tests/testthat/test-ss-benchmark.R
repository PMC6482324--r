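# A hand-specified mixture model with well-separated unit-variance modes,
# used to make joint tables with known structure.
toy_model <- function(means) {
  k <- nrow(means)
  structure(list(
    weights = rep(1 / k, k), means = means,
    covariances = array(rep(diag(ncol(means)) * 0.25, k),
                        dim = c(ncol(means), ncol(means), k)),
    zeta = 0, period = NULL,
    dim_names = paste0("f", seq_len(ncol(means))),
    provenance = list()), class = "pamm")
}

test_that("the joint table is a probability table and is diagonal for separated data", {
  means <- rbind(c(0, 0), c(20, 0), c(0, 20))
  model <- toy_model(means)
  set.seed(51)
  n_per <- 200
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(stats::rnorm(n_per * 2, sd = 0.5), ncol = 2), 2, means[k, ], "+")))
  labels <- rep(c("E", "H", "C"), each = n_per)
  tab <- joint_ss_table(x, labels, model)
  expect_equal(sum(tab$table), 1, tolerance = 1e-12)
  expect_true(all(tab$table >= 0))
  # essentially all mass on the matched (cluster, label) cells
  expect_equal(tab$table["1", "E"], 1 / 3, tolerance = 1e-6)
  expect_equal(tab$table["2", "H"], 1 / 3, tolerance = 1e-6)
  expect_equal(tab$table["3", "C"], 1 / 3, tolerance = 1e-6)
  expect_error(joint_ss_table(x, rep("Z", nrow(x)), model), "alphabet")
})

test_that("a known 30% label mix reproduces the hand count in hard mode", {
  means <- rbind(c(0, 0), c(20, 0))
  model <- toy_model(means)
  set.seed(52)
  # 100 label-E points in cluster 1; of 100 label-H points, 30 in cluster 2
  x <- rbind(
    matrix(stats::rnorm(200, sd = 0.3), ncol = 2),                 # E, cluster 1
    matrix(stats::rnorm(140, sd = 0.3), ncol = 2),                 # H, cluster 1
    sweep(matrix(stats::rnorm(60, sd = 0.3), ncol = 2), 2, c(20, 0), "+")  # H, cl 2
  )
  labels <- c(rep("E", 100), rep("H", 100))
  tab <- joint_ss_table(x, labels, model, hard = TRUE)
  expect_equal(unname(tab$table["1", "E"]), 100 / 200)
  expect_equal(unname(tab$table["1", "H"]), 70 / 200)
  expect_equal(unname(tab$table["2", "H"]), 30 / 200)
})

test_that("clusters map to the three-state group of their argmax label", {
  mk_tab <- function(P) {
    rownames(P) <- seq_len(nrow(P))
    structure(list(table = P, n_residues = 100), class = "ss_joint")
  }
  P <- matrix(c(0.5, 0.05, 0.05, 0.4), 2, 2, dimnames = list(NULL, c("H", "S")))
  m <- map_ss_clusters(mk_tab(P))
  expect_equal(m$class, c("helix", "coil"))   # S belongs to the coil group
  # X never wins the argmax
  P2 <- matrix(c(0.1, 0.9), 1, 2, dimnames = list(NULL, c("E", "X")))
  m2 <- map_ss_clusters(mk_tab(P2))
  expect_equal(m2$best_label, "E")
  expect_equal(m2$class, "strand")
})

test_that("Q3 reproduces hand-summed arithmetic on a 3x8 table", {
  labs <- c("B", "E", "G", "H", "I", "T", "S", "C")
  set.seed(53)
  P <- matrix(stats::runif(24), 3, 8, dimnames = list(1:3, labs))
  P <- P / sum(P)
  tab <- structure(list(table = P, n_residues = 100), class = "ss_joint")
  mapping <- tibble::tibble(cluster = 1:3,
                            best_label = c("E", "H", "C"),
                            class = c("strand", "helix", "coil"))
  hand <- (P[1, "B"] + P[1, "E"]) +
    (P[2, "G"] + P[2, "H"] + P[2, "I"]) +
    (P[3, "C"] + P[3, "S"] + P[3, "T"])
  expect_equal(q3_score(tab, mapping), unname(hand), tolerance = 1e-12)
  # a perfect diagonal table scores 1
  Pd <- matrix(0, 3, 8, dimnames = list(1:3, labs))
  Pd[1, "E"] <- 0.3; Pd[2, "H"] <- 0.4; Pd[3, "C"] <- 0.3
  tabd <- structure(list(table = Pd, n_residues = 100), class = "ss_joint")
  expect_equal(q3_score(tabd), 1)
  expect_equal(q8_score(tabd), 1)
})

test_that("Q8 equals the brute-force best single label per cluster", {
  labs <- setdiff(ss_alphabet(), "X")
  set.seed(54)
  P <- matrix(stats::runif(40), 5, 8, dimnames = list(1:5, labs))
  P <- P / sum(P)
  tab <- structure(list(table = P, n_residues = 100), class = "ss_joint")
  brute <- sum(apply(P, 1, max))
  expect_equal(q8_score(tab), brute, tolerance = 1e-12)
  # a single cluster with labels uniform over 8 classes captures 1/8
  Pu <- matrix(1 / 8, 1, 8, dimnames = list(1, labs))
  tabu <- structure(list(table = Pu, n_residues = 100), class = "ss_joint")
  expect_equal(q8_score(tabu), 0.125)
})

test_that("Q3 >= Q8, is invariant to cluster relabeling, and X drops cleanly", {
  labs <- ss_alphabet()
  set.seed(55)
  P <- matrix(stats::runif(45), 5, 9, dimnames = list(1:5, labs))
  P <- P / sum(P)
  tab <- structure(list(table = P, n_residues = 100), class = "ss_joint")
  expect_gte(q3_score(tab) + 1e-12, q8_score(tab))
  # permuting cluster rows leaves Q3 unchanged
  perm <- c(3, 1, 5, 2, 4)
  Pp <- P[perm, ]
  rownames(Pp) <- 1:5
  tabp <- structure(list(table = Pp, n_residues = 100), class = "ss_joint")
  expect_equal(q3_score(tabp), q3_score(tab), tolerance = 1e-12)
  # after dropping X the renormalized table still sums to 1
  expect_equal(sum(pammotif:::drop_x(tab)), 1, tolerance = 1e-12)
})

test_that("label files in all three dialects parse to the shared alphabet", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tresno\tcode",
               paste("A", 1:5, c("H", "H", "E", "C", "X"), sep = "\t")), tsv)
  lt <- read_ss_labels(tsv, "tsv")
  expect_equal(nrow(lt), 5L)
  expect_equal(lt$code, c("H", "H", "E", "C", "X"))

  dssp <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  >  S+", # H at column 17
    "    2    2 A E  E     S+",
    "    3    3 A T        S+"  # blank structure column -> X
  ), dssp)
  ld <- read_ss_labels(dssp, "dssp")
  expect_equal(ld$code, c("H", "E", "X"))
  expect_equal(ld$resno, 1:3)

  stride <- tempfile(fileext = ".stride")
  writeLines(c(
    "REM  -------------------- Secondary structure summary ---------",
    "ASG  MET A    1    1    C          Coil    360.00    126.22     241.2",
    "ASG  ALA A    2    2    H    AlphaHelix    -64.84    -35.65      53.6",
    "ASG  GLY A    3    3    E        Strand   -124.17    142.86      23.4"
  ), stride)
  ls <- read_ss_labels(stride, "stride")
  expect_equal(ls$code, c("C", "H", "E"))

  bad <- tempfile()
  writeLines(c("chain\tresno\tcode", "A\t1\tQ"), bad)
  expect_error(read_ss_labels(bad, "tsv"), "unknown")
})

test_that("unlabeled residues become X with a warning when labels attach", {
  rec <- tibble::tibble(chain = "A", resno = 1:4)
  lab <- tibble::tibble(chain = "A", resno = 1:3, code = c("H", "H", "E"))
  expect_warning(out <- attach_labels(rec, lab), "without a label")
  expect_equal(out$label, c("H", "H", "E", "X"))
})
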