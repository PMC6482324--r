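# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap values into the principal range of a periodic variable
#'
#' Maps each value into `(-period/2, period/2]`; the upper boundary is kept
#' so that dihedral angles live in `(-180, 180]`.
#'
#' @param x numeric vector.
#' @param period period of the variable (e.g. 360 for angles in degrees).
#' @return numeric vector of the same length.
#' @keywords internal
#' @noRd
wrap_principal <- function(x, period) {
  y <- x - period * floor(x / period + 0.5)
  # floor() maps +period/2 to -period/2; keep the positive boundary instead
  y[y == -period / 2] <- period / 2
  y
}

# Minimum-image displacement: componentwise dx wrapped into
# [-period/2, period/2). `period` may contain NA for aperiodic dimensions.
wrap_delta <- function(dx, period) {
  if (is.null(period)) return(dx)
  if (is.matrix(dx)) {
    for (j in seq_len(ncol(dx))) {
      if (!is.na(period[j])) {
        dx[, j] <- dx[, j] - period[j] * round(dx[, j] / period[j])
      }
    }
    dx
  } else {
    ok <- !is.na(period)
    dx[ok] <- dx[ok] - period[ok] * round(dx[ok] / period[ok])
    dx
  }
}

# Normalize a user-supplied periodicity spec to a per-dimension vector with
# NA marking aperiodic dimensions.
normalize_period <- function(period, n_dims) {
  if (is.null(period)) return(NULL)
  if (length(period) == 1L) period <- rep(period, n_dims)
  if (length(period) != n_dims) {
    stop("`period` must have length 1 or n_dims (", n_dims, ")", call. = FALSE)
  }
  if (all(is.na(period))) return(NULL)
  if (any(!is.na(period) & period <= 0)) {
    stop("periods must be positive", call. = FALSE)
  }
  as.numeric(period)
}

# Coerce feature input (data frame or matrix) to a numeric matrix, checking
# finiteness. Keeps column names for reporting.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("feature matrix contains non-finite entries", call. = FALSE)
  x
}

# Squared distance from every row of X to point p, with optional
# minimum-image wrapping.
sq_dist_to_point <- function(X, p, period = NULL) {
  dx <- sweep(X, 2L, p, "-")
  dx <- wrap_delta(dx, period)
  rowSums(dx * dx)
}

vnorm <- function(v) sqrt(sum(v * v))
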