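# Seeded generators for every kind of test input the pipeline consumes:
# planted Gaussian mixtures, toy polypeptide backbones at prescribed
# dihedrals, and PDB-format structures holding prescribed donor-H-acceptor
# geometries. All are geometric constructions with known ground truth, not
# physically relaxed models.

#' Sample a planted Gaussian mixture
#'
#' Draws from a mixture with known means, covariances and weights,
#' recording the true component of every sample. Periodic dimensions are
#' wrapped into their principal range.
#'
#' @param means list of component mean vectors.
#' @param sigmas list of covariance matrices (a scalar is taken as an
#'   isotropic standard deviation).
#' @param weights mixture weights (must sum to 1).
#' @param n number of samples.
#' @param period optional per-dimension period.
#' @param seed integer seed.
#' @return Tibble with feature columns `x1..xd` and the true `component`.
#' @export
sample_mixture <- function(means, sigmas, weights, n, period = NULL, seed = 1L) {
  stopifnot(length(means) == length(sigmas), length(means) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  d <- length(means[[1]])
  period <- normalize_period(period, d)
  chols <- lapply(sigmas, function(s) {
    S <- if (length(s) == 1L) diag(s^2, d) else as.matrix(s)
    tryCatch(chol(S), error = function(e)
      stop("covariance is not positive definite", call. = FALSE))
  })
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  Z <- matrix(stats::rnorm(n * d), n, d)
  X <- matrix(0, n, d)
  for (k in seq_along(means)) {
    idx <- which(comp == k)
    if (length(idx) == 0L) next
    X[idx, ] <- sweep(Z[idx, , drop = FALSE] %*% chols[[k]], 2L,
                      means[[k]], "+")
  }
  if (!is.null(period)) {
    for (j in seq_len(d)) {
      if (!is.na(period[j])) X[, j] <- wrap_principal(X[, j], period[j])
    }
  }
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("x", seq_len(d))
  out$component <- comp
  out
}

# NeRF atom placement: position d bonded to c with |cd| = bond, angle
# b-c-d = angle (degrees) and torsion a-b-c-d = torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- pracma_cross(ab, bc)
  if (vnorm(n) < 1e-12) stop("degenerate reference frame in atom placement", call. = FALSE)
  n <- n / vnorm(n)
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Build a toy polypeptide backbone at prescribed dihedrals
#'
#' Constructs an all-backbone (N, CA, C, O, H) chain in ideal peptide
#' geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, N-H 1.0
#' Angstrom; omega fixed at 180 degrees) whose extracted phi/psi match the
#' targets exactly at zero noise. The carbonyl O and amide H sit in the
#' peptide plane, so helical conformations form the usual backbone
#' hydrogen-bond geometry.
#'
#' @param phi,psi target dihedrals (degrees); recycled to `n_residues`.
#' @param n_residues chain length (>= 2).
#' @param labels optional per-residue secondary-structure codes carried in
#'   the returned records.
#' @param noise_sd Gaussian coordinate noise (Angstrom).
#' @param seed seed for the noise.
#' @param structure_id identifier of the resulting structure.
#' @param resolution resolution recorded in the REMARK 2 header when the
#'   structure is written; toy structures default to 1.0 Angstrom so they
#'   pass the selection filters by construction.
#' @return A `protein_structure`; the per-residue targets (and labels, if
#'   given) are attached as `attr(, "ground_truth")`.
#' @export
build_backbone <- function(phi, psi, n_residues = max(length(phi), length(psi)),
                           labels = NULL, noise_sd = 0, seed = 1L,
                           structure_id = "toyback", resolution = 1.0) {
  stopifnot(n_residues >= 2L)
  phi <- rep(phi, length.out = n_residues)
  psi <- rep(psi, length.out = n_residues)
  if (!is.null(labels)) labels <- rep(labels, length.out = n_residues)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_NH <- 1.0
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8; a_CNH <- 119.5
  N <- matrix(0, n_residues, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCa, 0, 0)
  ang <- a_NCaC * pi / 180
  C[1, ] <- CA[1, ] + b_CaC * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_residues) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_CN, a_CaCN, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_NCa, a_CNCa, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], b_CaC, a_NCaC, phi[i])
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_CO, a_CaCO, psi[i] + 180)
    H[i, ] <- if (i == 1L) {
      place_atom(C[1, ], CA[1, ], N[1, ], b_NH, a_CNH, 180)
    } else {
      place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_NH, a_CNH, 0)
    }
  }
  atoms <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    atoms[[i]] <- tibble::tibble(
      name = c("N", "CA", "C", "O", "H"),
      element = c("N", "C", "C", "O", "H"),
      x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1], H[i, 1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2], H[i, 2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3], H[i, 3]),
      resno = i
    )
  }
  at <- dplyr::bind_rows(atoms)
  if (noise_sd > 0) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    at$x <- at$x + stats::rnorm(nrow(at), sd = noise_sd)
    at$y <- at$y + stats::rnorm(nrow(at), sd = noise_sd)
    at$z <- at$z + stats::rnorm(nrow(at), sd = noise_sd)
  }
  at <- tibble::tibble(
    eleno = seq_len(nrow(at)), name = at$name, altloc = "",
    resname = "GLY", chain = "A", resno = at$resno, insert = "",
    x = at$x, y = at$y, z = at$z, occupancy = 1, element = at$element,
    is_hetero = FALSE
  )
  s <- new_protein_structure(structure_id, resolution, at)
  attr(s, "ground_truth") <- tibble::tibble(
    chain = "A", resno = seq_len(n_residues), phi = phi, psi = psi,
    label = if (is.null(labels)) NA_character_ else labels
  )
  s
}

#' Feasible toy hydrogen-bond geometries
#'
#' Five mixed-flavor (d_DA, d_AH, d_DH) geometries (with the donor angle
#' implied by the distances) used as the default input of
#' [build_hb_toy()].
#'
#' @return Tibble with `flavor`, `d_DA`, `d_AH`, `d_DH`.
#' @export
hb_toy_geometries <- function() {
  tibble::tibble(
    flavor = c("N-H...O", "N-H...O", "N-H...N", "O-H...O", "O-H...N"),
    d_DA = c(2.9, 3.1, 2.95, 2.75, 3.0),
    d_AH = c(1.95, 2.2, 2.05, 1.80, 2.1),
    d_DH = c(1.00, 1.02, 1.00, 0.98, 1.00)
  )
}

#' Build a toy structure of isolated hydrogen-bond triplets
#'
#' Places one donor/hydrogen/acceptor group per requested geometry, each
#' group 20 Angstrom from the next so no cross-group triplet can pass the
#' geometric pre-filters. Three distances determine the donor angle by the
#' law of cosines; a supplied `angle_ADH` column is checked against the
#' implied value and must agree to 1e-6 degrees.
#'
#' @param geometries tibble with `flavor`, `d_DA`, `d_AH`, `d_DH` (and
#'   optionally `angle_ADH`); see [hb_toy_geometries()].
#' @param structure_id identifier.
#' @param resolution recorded resolution (Angstrom).
#' @return A `protein_structure`; the realized per-group geometry is
#'   attached as `attr(, "ground_truth")`.
#' @export
build_hb_toy <- function(geometries, structure_id = "hbtoy", resolution = 1.0) {
  g <- geometries
  cosang <- (g$d_DH^2 + g$d_DA^2 - g$d_AH^2) / (2 * g$d_DH * g$d_DA)
  if (any(abs(cosang) > 1)) {
    stop("infeasible geometry: distances violate the triangle inequality",
         call. = FALSE)
  }
  ang <- acos(cosang) * 180 / pi
  if ("angle_ADH" %in% names(g)) {
    off <- abs(g$angle_ADH - ang)
    if (any(!is.na(off) & off > 1e-6)) {
      stop("supplied angle_ADH inconsistent with the three distances",
           call. = FALSE)
    }
  }
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    fl <- parse_flavor(g$flavor[i])
    off <- (i - 1) * 20
    don <- c(off, 0, 0)
    hyd <- c(off + g$d_DH[i], 0, 0)
    th <- ang[i] * pi / 180
    acc <- c(off + g$d_DA[i] * cos(th), g$d_DA[i] * sin(th), 0)
    rows[[i]] <- tibble::tibble(
      name = c(paste0(fl$donor, "D"), "H", paste0(fl$acceptor, "A")),
      element = c(fl$donor, "H", fl$acceptor),
      x = c(don[1], hyd[1], acc[1]),
      y = c(don[2], hyd[2], acc[2]),
      z = c(don[3], hyd[3], acc[3]),
      resno = i
    )
  }
  at <- dplyr::bind_rows(rows)
  at <- tibble::tibble(
    eleno = seq_len(nrow(at)), name = at$name, altloc = "",
    resname = "UNK", chain = "A", resno = at$resno, insert = "",
    x = at$x, y = at$y, z = at$z, occupancy = 1, element = at$element,
    is_hetero = FALSE
  )
  s <- new_protein_structure(structure_id, resolution, at)
  gt <- g[, c("flavor", "d_DA", "d_AH", "d_DH")]
  gt$angle_ADH <- ang
  gt$resno <- seq_len(nrow(g))
  attr(s, "ground_truth") <- gt
  s
}

#' Labeled synthetic Ramachandran samples
#'
#' Draws (phi, psi) pairs from per-class wrapped Gaussians centered on the
#' given class modes, recording the class code as the secondary-structure
#' label. Emulates the label-to-mode correspondence of real
#' dihedral/secondary-structure data with a known ground truth.
#'
#' @param class_modes tibble with `code` (labels from [ss_alphabet()]),
#'   `phi`, `psi` (degrees), `sigma` (degrees) and `weight`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return Tibble with `phi`, `psi` (wrapped into `(-180, 180]`) and
#'   `label`.
#' @export
labeled_ramachandran <- function(class_modes, n, seed = 1L) {
  cm <- class_modes
  bad <- setdiff(cm$code, ss_alphabet())
  if (length(bad) > 0L) stop("unknown class code(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  draws <- sample_mixture(
    means = purrr::map2(cm$phi, cm$psi, c),
    sigmas = as.list(cm$sigma),
    weights = cm$weight / sum(cm$weight),
    n = n, period = 360, seed = seed
  )
  tibble::tibble(phi = draws$x1, psi = draws$x2,
                 label = cm$code[draws$component])
}

#' Write a structure as a PDB file
#'
#' Fixed-width ATOM records plus a `REMARK 2` resolution header, with
#' coordinates at the format's native 0.001-Angstrom precision. The files
#' are column-compliant and round-trip through [read_structure()] (and
#' external PDB readers).
#'
#' @param structure a `protein_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  lines <- character(0)
  if (!is.na(structure$resolution)) {
    lines <- sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.", structure$resolution)
  }
  name_field <- ifelse(nchar(at$name) <= 3L,
                       sprintf(" %-3s", at$name),
                       sprintf("%-4s", at$name))
  rec <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(at$is_hetero, "HETATM", "ATOM"),
                 at$eleno %% 100000L, name_field, substr(at$altloc, 1, 1),
                 at$resname, at$chain, at$resno, substr(at$insert, 1, 1),
                 at$x, at$y, at$z, at$occupancy, 0, at$element)
  writeLines(c(lines, rec, "END"), path)
  invisible(path)
}

#' Write a ground-truth sidecar table
#'
#' Every generator attaches its ground truth as an attribute; this writes
#' it next to the structure as a TSV so fixtures are self-describing.
#'
#' @param structure a generated `protein_structure`.
#' @param path output TSV path.
#' @export
write_ground_truth <- function(structure, path) {
  gt <- attr(structure, "ground_truth")
  if (is.null(gt)) stop("structure carries no ground truth", call. = FALSE)
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
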