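# The three hydrogen-bond definitions are represented uniformly as "pmi"
# objects: a kind tag plus an evaluator mapping a feature tibble (columns
# d_AH, d_DA and, for the distance-angle heuristic, d_DH and angle_ADH) to
# scores in [0, 1].

new_pmi <- function(kind, evaluator, ...) {
  structure(c(list(kind = kind, evaluator = evaluator), list(...)),
            class = "pmi")
}

#' @export
print.pmi <- function(x, ...) {
  cat("<pmi> kind:", x$kind, "\n")
  invisible(x)
}

#' Evaluate a probabilistic motif identifier on feature rows
#'
#' @param pmi a `pmi` object (see [pmi_pamm()], [pmi_distance_angle()],
#'   [fit_dssp_pmi()]).
#' @param data tibble with the feature columns the identifier needs
#'   (`d_AH`, `d_DA`; the distance-angle heuristic also uses `d_DH` and
#'   `angle_ADH`).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
pmi_evaluate <- function(pmi, data) {
  stopifnot(inherits(pmi, "pmi"))
  s <- pmi$evaluator(data)
  pmin(1, pmax(0, s))
}

#' Distance-angle hydrogen-bond identifier
#'
#' The conventional geometric criterion: a triplet is a hydrogen bond iff
#' `d_DA < 3.5`, `d_AH < 2.5`, `d_DH < 1.5` (Angstrom) and
#' `angle_ADH < 30` degrees, all strict. The identifier is the indicator
#' of that region.
#'
#' @param d_DA_max,d_AH_max,d_DH_max,angle_max the four thresholds.
#' @return A `pmi` object of kind `"distance_angle"`.
#' @export
pmi_distance_angle <- function(d_DA_max = 3.5, d_AH_max = 2.5,
                               d_DH_max = 1.5, angle_max = 30.0) {
  new_pmi("distance_angle", function(data) {
    as.numeric(data$d_DA < d_DA_max & data$d_AH < d_AH_max &
                 data$d_DH < d_DH_max & data$angle_ADH < angle_max)
  }, thresholds = c(d_DA = d_DA_max, d_AH = d_AH_max,
                    d_DH = d_DH_max, angle_ADH = angle_max))
}

#' Identify the hydrogen-bond mode of a PAMM model
#'
#' Among the fitted Gaussian modes, the hydrogen bond is the one whose
#' mean is nearest (Euclidean) to the reference point
#' `(d_AH, d_DA) = (1.82, 2.74)` Angstrom. Ties go to the lowest mode
#' index and are reported.
#'
#' @param model a `pamm` model fitted on `(d_AH, d_DA)` features.
#' @param reference the reference point, in feature order.
#' @return Integer mode index.
#' @export
identify_hb_mode <- function(model, reference = c(1.82, 2.74)) {
  stopifnot(length(model$weights) >= 1L)
  d2 <- colSums((t(model$means) - reference)^2)
  hits <- which(d2 == min(d2))
  if (length(hits) > 1L) message("tie in hydrogen-bond mode selection; taking mode ", hits[1])
  hits[1]
}

#' PAMM-derived hydrogen-bond identifier
#'
#' Wraps one mode of a fitted PAMM model (by default the one selected by
#' [identify_hb_mode()]) as a `pmi` evaluated at `(d_AH, d_DA)`.
#'
#' @param model a `pamm` model fitted on `(d_AH, d_DA)` features.
#' @param mode mode index; `NULL` selects the hydrogen-bond mode.
#' @param zeta background parameter; defaults to the model's.
#' @param reference reference point for mode selection.
#' @return A `pmi` object of kind `"pamm"`.
#' @export
pmi_pamm <- function(model, mode = NULL, zeta = model$zeta,
                     reference = c(1.82, 2.74)) {
  mode <- mode %||% identify_hb_mode(model, reference)
  new_pmi("pamm", function(data) {
    pamm_pmi(model, cbind(d_AH = data$d_AH, d_DA = data$d_DA),
             k = mode, zeta = zeta)
  }, model = model, mode = mode, zeta = zeta)
}

# Compressed adaptive KDE: the FPS-grid estimator reused as a generative
# density, P(x) = sum_g w_g G(x | grid_g, H_g) with Voronoi weights w_g.
kde_fit <- function(x, n_grid = 2000, bandwidth_scale = 0.3, f_loc = 0.15,
                    period = NULL, seed = 1L) {
  X <- as_feature_matrix(x)
  n_grid <- min(n_grid, nrow(X))
  grid <- estimate_density(X, fps_select(X, n_grid, seed = seed, period = period),
                           bandwidth_scale = bandwidth_scale, f_loc = f_loc,
                           period = period)
  structure(list(grid = grid), class = "pammotif_kde")
}

kde_density <- function(fit, x) {
  g <- fit$grid
  X <- as_feature_matrix(x)
  d <- ncol(g$positions)
  out <- numeric(nrow(X))
  lognorm <- -0.5 * d * log(2 * pi)
  for (i in seq_len(nrow(g$positions))) {
    if (g$voronoi_weight[i] == 0) next
    dx <- wrap_delta(sweep(X, 2L, g$positions[i, ], "-"), g$period)
    ch <- chol(g$bandwidths[, , i])
    q <- colSums(backsolve(ch, t(dx), transpose = TRUE)^2)
    out <- out + g$voronoi_weight[i] *
      exp(lognorm - sum(log(diag(ch))) - 0.5 * q)
  }
  out
}

#' Fit the DSSP-energy hydrogen-bond identifier
#'
#' Splits the backbone quadruplets by the Kabsch-Sander criterion
#' (`energy < -0.5` kcal/mol), estimates the conditional densities of
#' `(d_AH, d_DA)` for the bonded and non-bonded populations with the same
#' adaptive FPS-grid KDE used throughout, and returns the identifier
#' `p_HB * P_HB(x) / (p_HB * P_HB(x) + (1 - p_HB) * P_nonHB(x) + zeta)`.
#'
#' @param quads tibble from [dssp_quadruplets()] (needs `energy`, `d_AH`,
#'   `d_DA`; rows with `NA` energy are dropped).
#' @param zeta background parameter.
#' @param n_grid,bandwidth_scale,f_loc,seed KDE parameters.
#' @return A `pmi` object of kind `"dssp_energy"` with fields `p_hb` and
#'   the two density fits.
#' @export
fit_dssp_pmi <- function(quads, zeta = 1e-5, n_grid = 2000,
                         bandwidth_scale = 0.3, f_loc = 0.15, seed = 1L) {
  quads <- quads[!is.na(quads$energy), , drop = FALSE]
  hb <- quads$energy < -0.5
  p_hb <- mean(hb)
  if (p_hb == 0) {
    stop("no hydrogen-bond-positive quadruplets (E < -0.5 kcal/mol); ",
         "refusing to fit an identically-zero identifier", call. = FALSE)
  }
  Xp <- cbind(d_AH = quads$d_AH[hb], d_DA = quads$d_DA[hb])
  fit_p <- kde_fit(Xp, n_grid = n_grid, bandwidth_scale = bandwidth_scale,
                   f_loc = f_loc, seed = seed)
  fit_n <- NULL
  if (p_hb < 1) {
    Xn <- cbind(d_AH = quads$d_AH[!hb], d_DA = quads$d_DA[!hb])
    fit_n <- kde_fit(Xn, n_grid = n_grid, bandwidth_scale = bandwidth_scale,
                     f_loc = f_loc, seed = seed)
  }
  new_pmi("dssp_energy", function(data) {
    X <- cbind(d_AH = data$d_AH, d_DA = data$d_DA)
    num <- p_hb * kde_density(fit_p, X)
    den <- num + zeta +
      if (is.null(fit_n)) 0 else (1 - p_hb) * kde_density(fit_n, X)
    out <- num / den
    out[den == 0] <- 0
    out
  }, p_hb = p_hb, zeta = zeta, density_hb = fit_p, density_nonhb = fit_n)
}

#' Agreement between two hydrogen-bond identifiers
#'
#' The probability, over an empirical sample of `(d_AH, d_DA)` geometries,
#' that both identifiers flag a configuration as a hydrogen bond relative
#' to the probability that either one does, normalized so that identical
#' identifiers score exactly 1. All integrals are Monte-Carlo averages on
#' the sample, which realizes the total geometry distribution:
#' `delta = <f_A f_B> / <f_A + f_B - f_A f_B> / lambda`, with
#' `lambda = sqrt(r_A * r_B)` and `r_X = <f_X^2> / <2 f_X - f_X^2>`.
#'
#' @param data feature tibble (the pooled triplets, or a restricted
#'   subset) with the columns both identifiers need.
#' @param pmi_a,pmi_b two `pmi` objects.
#' @return Tibble with `delta`, `lambda`, `n_samples`.
#' @export
pmi_similarity <- function(data, pmi_a, pmi_b) {
  if (nrow(data) == 0L) stop("empty sample set", call. = FALSE)
  fa <- pmi_evaluate(pmi_a, data)
  fb <- pmi_evaluate(pmi_b, data)
  if (all(fa == 0) || all(fb == 0)) {
    stop("an identifier evaluates to zero on every sample; ",
         "agreement is undefined", call. = FALSE)
  }
  ra <- mean(fa^2) / mean(2 * fa - fa^2)
  rb <- mean(fb^2) / mean(2 * fb - fb^2)
  lambda <- sqrt(ra * rb)
  num <- mean(fa * fb)
  den <- mean(fa + fb - fa * fb)
  tibble::tibble(delta = num / den / lambda, lambda = lambda,
                 n_samples = nrow(data))
}

#' Restrict triplet samples by donor/acceptor sequence separation
#'
#' Removes triplets whose donor and acceptor sit in the same residue
#' (`"same_residue"`) or in the same or directly adjacent residues of the
#' same chain (`"adjacent_residue"`). Atoms on different chains are never
#' considered nearby.
#'
#' @param data triplet tibble with `donor_chain`, `donor_resno`,
#'   `acceptor_chain`, `acceptor_resno`.
#' @param exclusion `"none"`, `"same_residue"` or `"adjacent_residue"`.
#' @return The filtered tibble.
#' @export
restrict_samples <- function(data, exclusion = c("none", "same_residue",
                                                 "adjacent_residue")) {
  exclusion <- match.arg(exclusion)
  if (exclusion == "none") return(data)
  same_chain <- data$donor_chain == data$acceptor_chain
  sep <- abs(data$donor_resno - data$acceptor_resno)
  lim <- if (exclusion == "same_residue") 0L else 1L
  data[!(same_chain & sep <= lim), , drop = FALSE]
}

#' Agreement score on a sequence-restricted sample
#'
#' [pmi_similarity()] computed after [restrict_samples()]; errors if the
#' restriction empties the sample.
#'
#' @inheritParams pmi_similarity
#' @inheritParams restrict_samples
#' @export
restricted_similarity <- function(data, pmi_a, pmi_b,
                                  exclusion = c("same_residue",
                                                "adjacent_residue")) {
  exclusion <- match.arg(exclusion)
  kept <- restrict_samples(data, exclusion)
  if (nrow(kept) == 0L) stop("restriction removed every sample", call. = FALSE)
  out <- pmi_similarity(kept, pmi_a, pmi_b)
  out$exclusion <- exclusion
  out
}
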