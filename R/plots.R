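#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PAMM model's grid and modes
#'
#' For 2-dimensional models (the first two dimensions otherwise): the
#' sparse grid colored by cluster assignment, sized by density, with mode
#' means marked.
#'
#' @param object a `pamm` model fitted with [pamm()] (the diagnostic grid
#'   must be present).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pamm <- function(object, ...) {
  if (is.null(object$grid)) stop("model carries no diagnostic grid", call. = FALSE)
  G <- object$grid$positions
  nm <- object$dim_names %||% paste0("dim", seq_len(ncol(G)))
  df <- tibble::tibble(
    x = G[, 1], y = G[, 2],
    density = object$grid$density,
    cluster = factor(as.integer(object$assignment))
  )
  mu <- tibble::tibble(x = object$means[, 1], y = object$means[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster,
                                     size = .data$density), alpha = 0.7) +
    ggplot2::geom_point(data = mu, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::scale_size_continuous(range = c(0.3, 2.5), guide = "none") +
    ggplot2::labs(x = nm[1], y = nm[2], colour = "motif") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cluster-label joint table
#'
#' @param object an `ss_joint` from [joint_ss_table()].
#' @param conditional plot `P(y | A)` instead of the joint probability.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ss_joint <- function(object, conditional = FALSE, ...) {
  long <- tidy(object)
  fill <- if (conditional) "p_label_given_cluster" else "p_joint"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label,
                                     y = factor(.data$cluster),
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (conditional) "P(y|A)" else "P(A,y)") +
    ggplot2::labs(x = "secondary-structure label", y = "motif cluster") +
    ggplot2::theme_minimal()
}

#' Plot a hydrogen-bond identifier over the distance plane
#'
#' Evaluates the identifier on a (d_AH, d_DA) raster; for the
#' distance-angle heuristic the donor-hydrogen distance and angle are held
#' at prototypical bonded values (d_DH 1.0 Angstrom, angle 10 degrees).
#'
#' @param pmi a `pmi` object.
#' @param d_ah,d_da axis ranges (Angstrom).
#' @param n raster resolution per axis.
#' @return A ggplot object.
#' @export
plot_pmi_surface <- function(pmi, d_ah = c(1, 4.5), d_da = c(1.5, 5), n = 120) {
  grid <- tidyr::expand_grid(
    d_AH = seq(d_ah[1], d_ah[2], length.out = n),
    d_DA = seq(d_da[1], d_da[2], length.out = n)
  )
  grid$d_DH <- 1.0
  grid$angle_ADH <- 10
  grid$score <- pmi_evaluate(pmi, grid)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$d_AH, y = .data$d_DA,
                                     fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "acceptor-hydrogen distance (A)",
                  y = "donor-acceptor distance (A)",
                  fill = "PMI") +
    ggplot2::theme_minimal()
}
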