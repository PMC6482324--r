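#' Farthest-point sampling of a sparse grid
#'
#' Greedy max-min selection: after a seeded first pick, each subsequent
#' point maximizes the minimum (periodic-aware) distance to the points
#' already selected. Ties are broken toward the lowest index so the
#' selection is fully deterministic given the seed.
#'
#' @param x data frame or matrix of features (rows = samples).
#' @param n_grid number of points to select.
#' @param seed integer seed controlling the first pick.
#' @param period optional per-dimension period (`NA` = aperiodic); a scalar
#'   is recycled.
#' @return Integer vector of `n_grid` distinct row indices.
#' @export
fps_select <- function(x, n_grid, seed = 1L, period = NULL) {
  X <- as_feature_matrix(x)
  n <- nrow(X)
  if (n_grid > n) stop("n_grid (", n_grid, ") exceeds number of samples (", n, ")",
                       call. = FALSE)
  period <- normalize_period(period, ncol(X))
  sel <- integer(n_grid)
  sel[1] <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    sample.int(n, 1L)
  })
  if (n_grid == 1L) return(sel)
  dmin <- sq_dist_to_point(X, X[sel[1], ], period)
  for (k in 2:n_grid) {
    sel[k] <- which.max(dmin)   # which.max takes the lowest index on ties
    if (k < n_grid) {
      d_new <- sq_dist_to_point(X, X[sel[k], ], period)
      dmin <- pmin(dmin, d_new)
    }
  }
  sel
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Adaptive kernel density estimate on a sparse grid
#'
#' For every grid point the kernel covariance is the sample covariance of
#' the nearest fraction `f_loc` of the data (minimum-image displacements
#' for periodic dimensions), shrunk by `bandwidth_scale^2`. Each grid
#' point carries the fraction of samples for which it is the nearest grid
#' point (its Voronoi weight), and the density is that of the compressed
#' estimator: the mixture of the grid kernels weighted by their Voronoi
#' populations. Evaluating the compressed mixture (rather than ballooning
#' each grid point's own kernel over the raw samples) keeps the estimate
#' monotone in sparse tails, where per-point bandwidths grow large.
#' Because a sparse grid cannot support features below its own spacing,
#' each kernel's geometric-mean width is floored at twice the distance to
#' the nearest grid neighbour: narrower kernels turn the compressed
#' density into a field of spikes whose heights fluctuate with the Voronoi
#' populations, and the mode search then chases that sampling noise.
#'
#' @param x features (data frame or matrix).
#' @param grid integer indices of the grid points (e.g. from
#'   [fps_select()]).
#' @param bandwidth_scale multiplicative shrink applied to the local
#'   covariance before it is used as the kernel bandwidth.
#' @param f_loc fraction of the dataset defining the local neighbourhood.
#' @param period optional per-dimension period.
#' @return A `pamm_grid` object: list with `positions` (g x d matrix),
#'   `density`, `voronoi_weight`, `local_scale` (geometric-mean standard
#'   deviation of the unscaled local covariance), `bandwidths` (d x d x g
#'   array, after scaling), `period`, `n_samples`.
#' @export
estimate_density <- function(x, grid, bandwidth_scale = 0.3, f_loc = 0.15,
                             period = NULL) {
  X <- as_feature_matrix(x)
  n <- nrow(X); d <- ncol(X)
  period <- normalize_period(period, d)
  stopifnot(bandwidth_scale > 0, f_loc > 0, f_loc <= 1)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    nm <- colnames(X) %||% paste0("dim", seq_len(d))
    stop("degenerate data: zero variance in dimension ",
         paste(nm[v == 0], collapse = ", "), call. = FALSE)
  }
  G <- X[grid, , drop = FALSE]
  g <- nrow(G)
  k_loc <- min(n, max(d + 2L, as.integer(ceiling(f_loc * n))))
  # distance to the nearest other grid point: the grid's local resolution
  dnn <- vapply(seq_len(g), function(i) {
    d2g <- sq_dist_to_point(G, G[i, ], period)
    d2g[i] <- Inf
    sqrt(min(d2g))
  }, numeric(1))
  vor_d2 <- rep(Inf, n)
  vor_id <- integer(n)
  lscale <- numeric(g)
  hwidth <- numeric(g)
  H <- array(0, dim = c(d, d, g))
  for (i in seq_len(g)) {
    dx <- wrap_delta(sweep(X, 2L, G[i, ], "-"), period)
    d2 <- rowSums(dx * dx)
    # running Voronoi assignment (strict < keeps the earlier grid index on ties)
    upd <- d2 < vor_d2
    vor_d2[upd] <- d2[upd]
    vor_id[upd] <- i
    # local covariance from the k_loc nearest samples
    thr <- sort(d2, partial = k_loc)[k_loc]
    nb <- which(d2 <= thr)
    if (length(nb) > k_loc) nb <- nb[order(d2[nb])][seq_len(k_loc)]
    dnb <- dx[nb, , drop = FALSE]
    mu <- colMeans(dnb)
    dc <- sweep(dnb, 2L, mu, "-")
    S <- crossprod(dc) / (nrow(dc) - 1L)
    S <- regularize_spd(S)
    lscale[i] <- exp(mean(log(diag(chol(S))))) # geometric-mean std dev
    Hi <- bandwidth_scale^2 * S
    gm_width <- bandwidth_scale * lscale[i]
    if (gm_width < 2 * dnn[i]) {
      Hi <- Hi * (2 * dnn[i] / gm_width)^2
      gm_width <- 2 * dnn[i]
    }
    H[, , i] <- Hi
    hwidth[i] <- gm_width
  }
  w <- tabulate(vor_id, nbins = g) / n
  # density of the compressed mixture at every grid point
  dens <- numeric(g)
  log_norm <- -0.5 * d * log(2 * pi)
  for (j in seq_len(g)) {
    if (w[j] == 0) next
    dxg <- wrap_delta(sweep(G, 2L, G[j, ], "-"), period)
    ch <- chol(H[, , j])
    q <- colSums(backsolve(ch, t(dxg), transpose = TRUE)^2)
    dens <- dens + w[j] * exp(log_norm - sum(log(diag(ch))) - 0.5 * q)
  }
  structure(
    list(positions = G, density = dens,
         voronoi_weight = w,
         local_scale = lscale, bandwidths = H,
         bandwidth_width = hwidth,
         period = period, n_samples = n,
         dim_names = colnames(X)),
    class = "pamm_grid"
  )
}

# Symmetrize and, if near-singular, ridge a covariance matrix.
regularize_spd <- function(S) {
  S <- (S + t(S)) / 2
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok || any(diag(S) <= 0) ||
      rcond_spd(S) < 1e-10) {
    eps <- 1e-8 * sum(diag(S)) / nrow(S)
    if (eps <= 0) eps <- 1e-12
    S <- S + diag(eps, nrow(S))
  }
  S
}

rcond_spd <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(1, 0))
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Quick-shift mode seeking on a density-annotated grid
#'
#' Each grid point links to its nearest grid point of strictly higher
#' density within `qs_scale` times its local length scale; points with no
#' such neighbour are modes. Following the links partitions the grid into
#' one cluster per mode. The linking radius is floored at three grid
#' spacings and at twice the kernel width at that point: the estimated
#' density cannot support separate modes below its own smoothing scale,
#' and without the floors coarse grids fragment single density basins
#' into artificial modes wherever the estimate ripples at grid
#' resolution.
#'
#' @param grid a `pamm_grid` from [estimate_density()].
#' @param qs_scale scaling of the quick-shift linking radius.
#' @return Integer cluster assignment per grid point (1..K, numbered by
#'   decreasing mode density), with the mode grid indices in
#'   `attr(, "modes")`.
#' @export
quick_shift <- function(grid, qs_scale = 1.0) {
  G <- grid$positions
  g <- nrow(G)
  dens <- grid$density
  parent <- integer(g)
  for (i in seq_len(g)) {
    d2 <- sq_dist_to_point(G, G[i, ], grid$period)
    d2[i] <- Inf
    radius <- max(qs_scale * grid$local_scale[i], 3 * sqrt(min(d2)),
                  2 * grid$bandwidth_width[i])
    cand <- which(dens > dens[i] & d2 <= radius^2)
    parent[i] <- if (length(cand) == 0L) i else cand[which.min(d2[cand])]
  }
  root <- seq_len(g)
  for (i in seq_len(g)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    root[i] <- r
  }
  modes <- sort(unique(root))
  modes <- modes[order(-dens[modes], modes)]  # stable: density then index
  cl <- match(root, modes)
  attr(cl, "modes") <- modes
  cl
}

#' Build a Gaussian mixture from grid clusters
#'
#' One Gaussian per cluster: the weight is the summed Voronoi weight of the
#' member grid points (the fraction of data in the cluster's basin) and the
#' mean/covariance are the Voronoi-weighted moments of the member grid
#' points, computed in minimum-image displacement space relative to the
#' cluster mode for periodic dimensions. Clusters below `prune_threshold`
#' are removed and the weights renormalized.
#'
#' @param grid a `pamm_grid`.
#' @param assignment cluster assignment from [quick_shift()].
#' @param prune_threshold minimum mixture weight a cluster must carry.
#' @param zeta background parameter stored with the model (used by
#'   [pamm_pmi()]).
#' @param provenance optional named list of fitting parameters recorded in
#'   the model.
#' @return A `pamm` model object; see [pamm()].
#' @export
build_mixture <- function(grid, assignment, prune_threshold = 1e-5,
                          zeta = 1e-5, provenance = list()) {
  modes <- attr(assignment, "modes")
  G <- grid$positions
  d <- ncol(G)
  K <- length(modes)
  w <- numeric(K)
  mu <- matrix(0, K, d)
  Sig <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    idx <- which(assignment == k)
    wk <- grid$voronoi_weight[idx]
    w[k] <- sum(wk)
    ref <- G[modes[k], ]
    dx <- wrap_delta(sweep(G[idx, , drop = FALSE], 2L, ref, "-"), grid$period)
    if (sum(wk) <= 0) wk <- rep(1 / length(idx), length(idx))
    wn <- wk / sum(wk)
    m <- colSums(dx * wn)
    dc <- sweep(dx, 2L, m, "-")
    S <- crossprod(dc * sqrt(wn), dc * sqrt(wn)) / max(1 - sum(wn^2), .Machine$double.eps)
    if (length(idx) < d + 1L) {
      warning("cluster ", k, " has only ", length(idx),
              " grid points; covariance regularized", call. = FALSE)
    }
    Sig[, , k] <- regularize_spd(S)
    mu[k, ] <- ref + m
    if (!is.null(grid$period)) {
      for (j in seq_len(d)) {
        if (!is.na(grid$period[j])) mu[k, j] <- wrap_principal(mu[k, j], grid$period[j])
      }
    }
  }
  keep <- which(w >= prune_threshold)
  if (length(keep) == 0L) stop("all clusters fell below the prune threshold", call. = FALSE)
  w <- w[keep] / sum(w[keep])
  mu <- mu[keep, , drop = FALSE]
  Sig <- Sig[, , keep, drop = FALSE]
  colnames(mu) <- grid$dim_names
  structure(
    list(weights = w, means = mu, covariances = Sig, zeta = zeta,
         period = grid$period, dim_names = grid$dim_names,
         provenance = provenance),
    class = "pamm"
  )
}

#' Probabilistic analysis of molecular motifs (PAMM)
#'
#' Fits a Gaussian mixture to the modes of the data's probability density:
#' a sparse grid is chosen by farthest-point sampling, an adaptive kernel
#' density estimate is computed on it, quick-shift links each grid point to
#' its nearest higher-density neighbour within a local radius, and each
#' resulting basin becomes one Gaussian whose weight is the fraction of
#' data it captures. Dimensions may be periodic (dihedral angles), in which
#' case all distances, kernels and moments use minimum-image conventions.
#'
#' @param x features: data frame or matrix, rows = observations.
#' @param n_grid grid size; must not exceed the number of samples.
#' @param bandwidth_scale shrink factor on the locally adaptive bandwidth.
#' @param qs_scale quick-shift radius scaling (in units of the local
#'   length scale of the data around each grid point).
#' @param f_loc fraction of samples defining each grid point's local
#'   covariance.
#' @param prune_threshold clusters with mixture weight below this are
#'   discarded and the remaining weights renormalized.
#' @param zeta background parameter used when evaluating motif identifiers.
#' @param period per-dimension period (`NA` = aperiodic), e.g. 360 for
#'   dihedrals in degrees.
#' @param seed integer seed (farthest-point sampling first pick and the
#'   optional subsampling).
#' @param max_samples optional cap on the number of samples used (seeded
#'   uniform subsample, reported via message).
#' @return A `pamm` object with elements `weights`, `means`,
#'   `covariances` (d x d x K), `zeta`, `period`, `provenance`, plus the
#'   diagnostic `grid` and `assignment`. Methods: [tidy()], [glance()],
#'   [predict.pamm()], [autoplot.pamm()].
#' @examples
#' set.seed(1)
#' x <- sample_mixture(
#'   means = list(c(0, 0), c(4, 0)), sigmas = list(0.5, 0.5),
#'   weights = c(0.6, 0.4), n = 2000, seed = 7
#' )
#' fit <- pamm(x[, c("x1", "x2")], n_grid = 200, seed = 3)
#' glance(fit)
#' tidy(fit)
#' @export
pamm <- function(x, n_grid = 2000, bandwidth_scale = 0.3, qs_scale = 1.0,
                 f_loc = 0.15, prune_threshold = 1e-5, zeta = 1e-5,
                 period = NULL, seed = 1L, max_samples = NULL) {
  X <- as_feature_matrix(x)
  if (!is.null(max_samples) && nrow(X) > max_samples) {
    message("subsampling ", max_samples, " of ", nrow(X), " samples (seed ", seed, ")")
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    X <- X[sample.int(nrow(X), max_samples), , drop = FALSE]
  }
  grid_idx <- fps_select(X, n_grid, seed = seed, period = period)
  grid <- estimate_density(X, grid_idx, bandwidth_scale = bandwidth_scale,
                           f_loc = f_loc, period = period)
  assignment <- quick_shift(grid, qs_scale = qs_scale)
  model <- build_mixture(grid, assignment, prune_threshold = prune_threshold,
                         zeta = zeta,
                         provenance = list(
                           n_grid = n_grid, bandwidth_scale = bandwidth_scale,
                           qs_scale = qs_scale, f_loc = f_loc,
                           prune_threshold = prune_threshold, seed = seed,
                           n_samples = nrow(X)))
  model$grid <- grid
  model$assignment <- assignment
  model
}

#' @export
print.pamm <- function(x, ...) {
  cat("<pamm> Gaussian mixture motif model\n")
  cat("  modes: ", length(x$weights), "  dims: ", ncol(x$means),
      "  zeta: ", format(x$zeta), "\n", sep = "")
  cat("  weights: ", paste(signif(x$weights, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Log-density of every mode at every row of X: n x K matrix of
# log(p_k) + log G(x | mu_k, Sigma_k), minimum-image aware.
pamm_log_terms <- function(model, X) {
  K <- length(model$weights)
  d <- ncol(model$means)
  n <- nrow(X)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dx <- wrap_delta(sweep(X, 2L, model$means[k, ], "-"), model$period)
    ch <- chol(model$covariances[, , k])
    q <- colSums(backsolve(ch, t(dx), transpose = TRUE)^2)
    L[, k] <- log(model$weights[k]) - 0.5 * q -
      0.5 * d * log(2 * pi) - sum(log(diag(ch)))
  }
  L
}

#' Evaluate the mixture density of a PAMM model
#'
#' @param model a `pamm` object.
#' @param x points at which to evaluate (data frame or matrix).
#' @return Numeric vector of densities.
#' @export
pamm_density <- function(model, x) {
  X <- as_feature_matrix(x)
  L <- pamm_log_terms(model, X)
  M <- apply(L, 1L, max)
  exp(M) * rowSums(exp(L - M))
}

#' Probabilistic motif identifiers
#'
#' The PMI of mode `k` at point `x` is
#' `p_k G(x | mu_k, Sigma_k) / (P(x) + zeta)`, where `P` is the full
#' mixture density and `zeta` a small background parameter that sends the
#' identifier to zero far from every mode. With `zeta = 0` the identifiers
#' are posterior responsibilities and sum to one at every point.
#'
#' @param model a `pamm` object.
#' @param x evaluation points.
#' @param k mode index (or `NULL` for all modes).
#' @param zeta background parameter; defaults to the model's.
#' @return A numeric vector (single `k`) or an n x K matrix.
#' @export
pamm_pmi <- function(model, x, k = NULL, zeta = model$zeta) {
  X <- as_feature_matrix(x)
  L <- pamm_log_terms(model, X)
  M <- apply(L, 1L, max)
  E <- exp(L - M)
  denom <- rowSums(E) + zeta * exp(-M)
  # Far from every mode all terms underflow; the PMI limit there is 0.
  denom[!is.finite(denom) | denom <= 0] <- Inf
  F <- E / denom
  if (is.null(k)) F else F[, k]
}

#' Predict method for PAMM models
#'
#' @param object a `pamm` model.
#' @param newdata points to evaluate.
#' @param type `"pmi"` (with the model's zeta), `"responsibility"`
#'   (zeta = 0), `"cluster"` (argmax responsibility) or `"density"`.
#' @param ... unused.
#' @export
predict.pamm <- function(object, newdata,
                         type = c("pmi", "responsibility", "cluster", "density"),
                         ...) {
  type <- match.arg(type)
  switch(type,
    pmi = pamm_pmi(object, newdata),
    responsibility = pamm_pmi(object, newdata, zeta = 0),
    cluster = max.col(pamm_pmi(object, newdata, zeta = 0), ties.method = "first"),
    density = pamm_density(object, newdata)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PAMM model: one row per Gaussian mode
#'
#' @param x a `pamm` object.
#' @param ... unused.
#' @return Tibble with `mode`, `weight`, one `mean_*` column per feature
#'   dimension and the generalized variance `det_cov`.
#' @export
tidy.pamm <- function(x, ...) {
  d <- ncol(x$means)
  nm <- x$dim_names %||% paste0("dim", seq_len(d))
  out <- tibble::tibble(mode = seq_along(x$weights), weight = x$weights)
  for (j in seq_len(d)) out[[paste0("mean_", nm[j])]] <- x$means[, j]
  out$det_cov <- vapply(seq_along(x$weights),
                        function(k) det(x$covariances[, , k]), numeric(1))
  out
}

#' One-line summary of a PAMM model
#'
#' @param x a `pamm` object.
#' @param ... unused.
#' @export
glance.pamm <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$weights),
    n_dims = ncol(x$means),
    zeta = x$zeta,
    n_grid = x$provenance$n_grid %||% NA_integer_,
    n_samples = x$provenance$n_samples %||% NA_integer_,
    seed = x$provenance$seed %||% NA_integer_
  )
}

#' Write a PAMM model to a versioned plain-text file
#'
#' Numbers are written with 17 significant digits so a write/read cycle is
#' bit-exact.
#'
#' @param model a `pamm` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pamm <- function(model, path) {
  d <- ncol(model$means)
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    "# pammotif model v1",
    paste0("dims ", d),
    paste0("modes ", length(model$weights)),
    paste0("zeta ", sprintf("%.17g", model$zeta)),
    paste0("period ", if (is.null(model$period)) "none" else
      paste(ifelse(is.na(model$period), "NA", sprintf("%.17g", model$period)),
            collapse = " ")),
    paste0("dim_names ", paste(model$dim_names %||% paste0("dim", seq_len(d)),
                               collapse = " ")),
    paste0("provenance ", paste(names(model$provenance),
                                vapply(model$provenance, function(v)
                                  paste(format(v), collapse = ","), character(1)),
                                sep = "=", collapse = " "))
  )
  for (k in seq_along(model$weights)) {
    lines <- c(lines, paste("mode",
                            sprintf("%.17g", model$weights[k]),
                            num(model$means[k, ]),
                            num(t(model$covariances[, , k]))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAMM model written by [write_pamm()]
#'
#' @param path model file.
#' @return A `pamm` object.
#' @export
read_pamm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# pammotif model v1", lines[1])) {
    stop("not a pammotif model file: ", path, call. = FALSE)
  }
  field <- function(key) sub(paste0("^", key, " "), "",
                             grep(paste0("^", key, " "), lines, value = TRUE)[1])
  d <- as.integer(field("dims"))
  K <- as.integer(field("modes"))
  zeta <- as.numeric(field("zeta"))
  per_raw <- field("period")
  period <- if (identical(per_raw, "none")) NULL else
    suppressWarnings(as.numeric(strsplit(per_raw, " ")[[1]]))
  dim_names <- strsplit(field("dim_names"), " ")[[1]]
  mode_lines <- grep("^mode ", lines, value = TRUE)
  stopifnot(length(mode_lines) == K)
  w <- numeric(K); mu <- matrix(0, K, d); Sig <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) {
    v <- as.numeric(strsplit(mode_lines[k], " ")[[1]][-1])
    w[k] <- v[1]
    mu[k, ] <- v[2:(d + 1)]
    Sig[, , k] <- matrix(v[(d + 2):(d + 1 + d * d)], d, d, byrow = TRUE)
  }
  colnames(mu) <- dim_names
  structure(list(weights = w, means = mu, covariances = Sig, zeta = zeta,
                 period = period, dim_names = dim_names,
                 provenance = list(file = path)),
            class = "pamm")
}
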