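#' SOAP descriptor configuration
#'
#' Parameters of the smooth-overlap-of-atomic-positions power spectrum:
#' each neighbour atom contributes a Gaussian of width `sigma` to a
#' species-resolved density, which is expanded in `n_max` orthonormalized
#' radial functions and spherical harmonics up to `l_max` within a cutoff
#' `cutoff`; a cosine taper of width `transition` takes the density
#' smoothly to zero at the cutoff. The radial basis (equispaced Gaussians,
#' Loewdin-orthonormalized on a fixed quadrature) is precomputed here.
#'
#' @param cutoff environment radius (Angstrom).
#' @param sigma atom-density smearing width (Angstrom).
#' @param n_max radial basis size.
#' @param l_max angular band limit.
#' @param species ordered element list resolved in the density.
#' @param transition width of the smooth cutoff taper (Angstrom).
#' @param n_quad quadrature intervals for the radial integrals.
#' @return A `soap_config` object.
#' @export
soap_config <- function(cutoff = 6.0, sigma = 0.5, n_max = 8L, l_max = 6L,
                        species = c("C", "N", "O"), transition = 0.5,
                        n_quad = 200L) {
  stopifnot(cutoff > 0, sigma > 0, n_max >= 1, l_max >= 0,
            transition >= 0, transition < cutoff)
  # composite Simpson quadrature on [0, cutoff]
  if (n_quad %% 2L == 1L) n_quad <- n_quad + 1L
  r_q <- seq(0, cutoff, length.out = n_quad + 1L)
  h <- cutoff / n_quad
  w_q <- h / 3 * c(1, rep(c(4, 2), length.out = n_quad - 1L), 1)
  centers <- seq(0, cutoff, length.out = n_max)
  width <- if (n_max > 1L) centers[2] - centers[1] else cutoff / 2
  phi <- outer(centers, r_q, function(ck, r) exp(-(r - ck)^2 / (2 * width^2)))
  S <- phi %*% (t(phi) * (w_q * r_q^2))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12))) %*% t(es$vectors)
  Rn <- W %*% phi                     # n_max x n_quad orthonormal radial basis
  structure(
    list(cutoff = cutoff, sigma = sigma, n_max = as.integer(n_max),
         l_max = as.integer(l_max), species = toupper(species),
         transition = transition, r_q = r_q, w_q = w_q, Rn = Rn),
    class = "soap_config"
  )
}

soap_cutoff_fn <- function(r, cutoff, transition) {
  out <- numeric(length(r))
  inner <- r <= cutoff - transition
  taper <- r > cutoff - transition & r <= cutoff
  out[inner] <- 1
  if (transition > 0) {
    out[taper] <- 0.5 * (1 + cos(pi * (r[taper] - cutoff + transition) / transition))
  }
  out
}

# Real spherical harmonics Y_lm for all (l, m) with l <= l_max, evaluated
# at unit directions given by (cos_theta, phi_az). Returns a matrix with
# one row per direction and columns ordered l = 0..l_max, within each l
# m = 0, (1, cos), (1, sin), (2, cos), (2, sin), ...
real_sph_harm <- function(cos_theta, phi_az, l_max) {
  n <- length(cos_theta)
  x <- cos_theta
  sx <- sqrt(pmax(0, 1 - x^2))
  n_lm <- (l_max + 1L)^2
  Y <- matrix(0, n, n_lm)
  # associated Legendre values P[l, m]
  P <- vector("list", l_max + 1L)
  for (l in 0:l_max) P[[l + 1L]] <- matrix(0, n, l + 1L)
  P[[1L]][, 1L] <- 1
  if (l_max >= 1L) {
    for (m in 1:l_max) {
      # P_m^m = (2m-1)!! * (1 - x^2)^(m/2)  (Condon-Shortley phase omitted;
      # any orthonormal real basis of each l-subspace works here)
      P[[m + 1L]][, m + 1L] <- prod(seq(1, 2 * m - 1, by = 2)) * sx^m
    }
    for (m in 0:(l_max - 1L)) {
      P[[m + 2L]][, m + 1L] <- (2 * m + 1) * x * P[[m + 1L]][, m + 1L]
      if (m + 2L <= l_max) {
        for (l in (m + 2L):l_max) {
          P[[l + 1L]][, m + 1L] <-
            ((2 * l - 1) * x * P[[l]][, m + 1L] -
               (l + m - 1) * P[[l - 1L]][, m + 1L]) / (l - m)
        }
      }
    }
  }
  col <- 1L
  for (l in 0:l_max) {
    nl0 <- sqrt((2 * l + 1) / (4 * pi))
    Y[, col] <- nl0 * P[[l + 1L]][, 1L]
    col <- col + 1L
    if (l >= 1L) {
      for (m in 1:l) {
        nlm <- nl0 * sqrt(exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        base <- sqrt(2) * nlm * P[[l + 1L]][, m + 1L]
        Y[, col] <- base * cos(m * phi_az)
        Y[, col + 1L] <- base * sin(m * phi_az)
        col <- col + 2L
      }
    }
  }
  Y
}

# exp(-x) * i_l(x) for the modified spherical Bessel function of the first
# kind, stable for large x via the scaled besselI.
scaled_sph_bessel_i <- function(x, l) {
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselI(xs, l + 0.5, expon.scaled = TRUE)
  }
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- exp(-x[small]) * x[small]^l / dfact
  }
  out
}

#' SOAP power spectrum of one atomic environment
#'
#' Expands the species-resolved, Gaussian-smeared neighbour density around
#' `center` in orthonormal radial functions and real spherical harmonics,
#' then contracts over the magnetic index to the rotationally invariant
#' power spectrum. Off-diagonal species/radial pairs carry a sqrt(2)
#' factor so that the Euclidean dot product of two power spectra equals
#' the full rotational-overlap kernel at exponent 2.
#'
#' @param xyz neighbour coordinates, one atom per row (Angstrom).
#' @param species element symbol per neighbour row.
#' @param center 3-vector, the expansion center.
#' @param config a [soap_config()].
#' @return Named numeric power-spectrum vector (components indexed by
#'   species pair, radial pair and angular momentum l). Environments with
#'   no neighbour inside the cutoff give the zero vector with a warning.
#' @export
soap_environment <- function(xyz, species, center, config = soap_config()) {
  xyz <- if (is.matrix(xyz)) xyz else as.matrix(xyz)
  species <- toupper(as.character(species))
  ns <- length(config$species)
  n_max <- config$n_max; l_max <- config$l_max
  rel <- sweep(xyz, 2L, as.numeric(center), "-")
  r <- sqrt(rowSums(rel^2))
  keep <- r > 1e-9 & r <= config$cutoff & species %in% config$species
  labels <- soap_component_labels(config)
  if (!any(keep)) {
    warning("environment has no neighbour inside the cutoff; zero vector",
            call. = FALSE)
    return(stats::setNames(numeric(length(labels)), labels))
  }
  rel <- rel[keep, , drop = FALSE]
  r <- r[keep]
  species <- species[keep]
  a <- 1 / (2 * config$sigma^2)
  fc <- soap_cutoff_fn(r, config$cutoff, config$transition)
  cos_theta <- rel[, 3] / r
  phi_az <- atan2(rel[, 2], rel[, 1])
  Y <- real_sph_harm(cos_theta, phi_az, l_max)
  l_of_col <- rep(0:l_max, times = 2 * (0:l_max) + 1)
  cmat <- matrix(0, ns * n_max, (l_max + 1L)^2)
  for (i in seq_along(r)) {
    base <- config$w_q * config$r_q^2 * exp(-a * (config$r_q - r[i])^2)
    x_q <- 2 * a * config$r_q * r[i]
    Inl <- matrix(0, n_max, l_max + 1L)
    for (l in 0:l_max) {
      Inl[, l + 1L] <- config$Rn %*% (base * scaled_sph_bessel_i(x_q, l))
    }
    si <- match(species[i], config$species)
    rows <- (si - 1L) * n_max + seq_len(n_max)
    contrib <- Inl[, l_of_col + 1L, drop = FALSE] *
      matrix(Y[i, ], n_max, length(l_of_col), byrow = TRUE)
    cmat[rows, ] <- cmat[rows, ] + 4 * pi * fc[i] * contrib
  }
  # contract over m within each l
  nb <- ns * n_max
  p <- numeric(length(labels))
  idx <- 0L
  for (b1 in seq_len(nb)) {
    for (b2 in b1:nb) {
      fac <- if (b1 == b2) 1 else sqrt(2)
      for (l in 0:l_max) {
        cols <- which(l_of_col == l)
        idx <- idx + 1L
        p[idx] <- fac * sum(cmat[b1, cols] * cmat[b2, cols]) / sqrt(2 * l + 1)
      }
    }
  }
  stats::setNames(p, labels)
}

soap_component_labels <- function(config) {
  nb <- length(config$species) * config$n_max
  bn <- paste0(rep(config$species, each = config$n_max),
               rep(seq_len(config$n_max), length(config$species)))
  out <- character(0)
  for (b1 in seq_len(nb)) {
    for (b2 in b1:nb) {
      out <- c(out, paste0(bn[b1], "_", bn[b2], "_l", 0:config$l_max))
    }
  }
  out
}

#' SOAP power spectra for all C-alpha environments of a structure
#'
#' One descriptor per C-alpha atom, built from all C, N and O atoms (the
#' configured species) within the cutoff, excluding solvent/hetero records
#' and the center atom itself.
#'
#' @param structure a `protein_structure`.
#' @param config a [soap_config()].
#' @return Tibble with residue identity columns (`chain`, `resno`,
#'   `insert`, `resname`) followed by the power-spectrum components.
#' @export
compute_soap <- function(structure, config = soap_config()) {
  atoms <- if (inherits(structure, "protein_structure")) structure$atoms else structure
  atoms <- atoms[!atoms$is_hetero, , drop = FALSE]
  ca <- atoms[atoms$name == "CA" & atoms$element == "C", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), , drop = FALSE]
  if (nrow(ca) == 0L) stop("structure has no C-alpha atoms", call. = FALSE)
  nb <- atoms[atoms$element %in% config$species, , drop = FALSE]
  nb_xyz <- as.matrix(nb[, c("x", "y", "z")])
  labels <- soap_component_labels(config)
  P <- matrix(0, nrow(ca), length(labels), dimnames = list(NULL, labels))
  for (i in seq_len(nrow(ca))) {
    center <- as.numeric(ca[i, c("x", "y", "z")])
    d2 <- (nb_xyz[, 1] - center[1])^2 + (nb_xyz[, 2] - center[2])^2 +
      (nb_xyz[, 3] - center[3])^2
    close <- d2 <= config$cutoff^2
    P[i, ] <- soap_environment(nb_xyz[close, , drop = FALSE],
                               nb$element[close], center, config)
  }
  dplyr::bind_cols(
    tibble::tibble(chain = ca$chain, resno = ca$resno,
                   insert = ca$insert, resname = ca$resname),
    tibble::as_tibble(P)
  )
}

#' Farthest-point selection of descriptor components
#'
#' Selects `n_keep` columns of a descriptor matrix by greedy max-min
#' selection on the squared Euclidean distance between component profiles
#' (each component represented by its values across the sample
#' environments). Used to thin the SOAP power spectrum before PCA while
#' maintaining its span.
#'
#' @param mat numeric matrix, environments in rows, components in columns.
#' @param n_keep number of components to keep.
#' @param seed seed for the first pick.
#' @return Integer vector of column indices.
#' @export
select_soap_components <- function(mat, n_keep, seed = 1L) {
  mat <- as_feature_matrix(mat)
  nz <- sum(colSums(mat != 0) > 0L)
  if (n_keep > nz) {
    stop("n_keep (", n_keep, ") exceeds the ", nz, " nonzero components",
         call. = FALSE)
  }
  fps_select(t(mat), n_keep, seed = seed)
}

#' Fit a centered PCA reducer
#'
#' @param mat numeric matrix (or data frame), samples in rows.
#' @param d number of principal components to retain.
#' @return A `pca_reducer` with the training `scores` (tibble `PC1..PCd`),
#'   the centering vector, rotation and singular values; apply to new data
#'   with [predict()].
#' @export
fit_pca <- function(mat, d) {
  X <- as_feature_matrix(mat)
  if (nrow(X) <= d) stop("need more samples than components", call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-10)
  if (d > rank) stop("d (", d, ") exceeds the data rank (", rank, ")", call. = FALSE)
  obj <- structure(
    list(center = pr$center, rotation = pr$rotation[, seq_len(d), drop = FALSE],
         sdev = pr$sdev, d = as.integer(d),
         explained = pr$sdev^2 / sum(pr$sdev^2)),
    class = "pca_reducer"
  )
  obj$scores <- tibble::as_tibble(predict(obj, X))
  obj
}

#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  S <- sweep(X, 2L, object$center, "-") %*% object$rotation
  colnames(S) <- paste0("PC", seq_len(object$d))
  S
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat("<pca_reducer> d =", x$d, "of", length(x$center), "features;",
      "explained variance:",
      paste0(round(100 * x$explained[seq_len(x$d)], 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Persist a PCA reducer as plain text
#'
#' @param reducer a `pca_reducer`.
#' @param path output file.
#' @export
write_pca_reducer <- function(reducer, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c("# pammotif pca v1",
             paste0("d ", reducer$d),
             paste0("p ", length(reducer$center)),
             paste0("center ", num(reducer$center)))
  for (j in seq_len(reducer$d)) {
    lines <- c(lines, paste0("rotation ", num(reducer$rotation[, j])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PCA reducer written by [write_pca_reducer()]
#'
#' @param path reducer file.
#' @export
read_pca_reducer <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# pammotif pca v1", lines[1])) stop("not a reducer file", call. = FALSE)
  getv <- function(key) {
    as.numeric(strsplit(sub(paste0("^", key, " "), "",
                            grep(paste0("^", key, " "), lines, value = TRUE)[1]),
                        " ")[[1]])
  }
  d <- as.integer(getv("d")); p <- as.integer(getv("p"))
  center <- getv("center")
  rot_lines <- grep("^rotation ", lines, value = TRUE)
  rotation <- vapply(rot_lines, function(l)
    as.numeric(strsplit(sub("^rotation ", "", l), " ")[[1]]), numeric(p))
  dimnames(rotation) <- NULL
  structure(list(center = center, rotation = rotation, sdev = NULL,
                 d = d, explained = NULL),
            class = "pca_reducer")
}
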