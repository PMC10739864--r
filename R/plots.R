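#' Plot an edge-operator spectrum in the complex plane
#'
#' Eigenvalues as points, the bulk disc of radius `r` shaded; isolated
#' eigenvalues (the community signal) highlighted.
#'
#' @param object An `nb_spectrum` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_spectrum <- function(object, ...) {
  df <- tidy(object)
  th <- seq(0, 2 * pi, length.out = 256)
  circle <- tibble(re = object$bulk_radius * cos(th),
                   im = object$bulk_radius * sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_polygon(data = circle, fill = "grey85", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$isolated), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "darkorange")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re(λ)", y = "Im(λ)",
                  title = paste0("Spectrum of the ", object$kind, " matrix"),
                  subtitle = paste0("bulk radius r = ",
                                    format(object$bulk_radius, digits = 4),
                                    "; ", length(object$isolated),
                                    " isolated eigenvalues")) +
    ggplot2::theme_minimal()
}

#' Plot the detectability diagnostic curves
#'
#' The affinity gap `c_in - c_out` and the threshold `k sqrt(c)` as functions
#' of `k`; their crossing marks `k_max`.
#'
#' @param object An `nb_kmax` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_kmax <- function(object, ...) {
  df <- object$table |>
    tidyr::pivot_longer(c("gap", "threshold"), names_to = "curve",
                        values_to = "value") |>
    dplyr::mutate(curve = dplyr::recode(.data$curve,
                                        gap = "c_in - c_out",
                                        threshold = "k√c"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_max, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "number of clusters k", y = NULL, colour = NULL,
                  title = paste0("Detectability scan (", object$operator,
                                 " operator): k_max = ", object$k_max)) +
    ggplot2::theme_minimal()
}

#' Plot an operator-comparison benchmark
#'
#' Mean AMI against the planted labels as a function of `w_in`, one curve per
#' operator, ribbon = +/- one standard deviation.
#'
#' @param object An `nb_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_benchmark <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w_in, y = .data$mean_ami,
                                   colour = .data$operator,
                                   fill = .data$operator)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ami - .data$sd_ami,
                                      ymax = .data$mean_ami + .data$sd_ami),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "intra-block probability w_in", y = "mean AMI",
                  colour = NULL, fill = NULL,
                  title = "Operator comparison on planted SBMs") +
    ggplot2::theme_minimal()
}

#' Plot a spectral-clustering embedding
#'
#' First two embedding coordinates coloured by cluster.
#'
#' @param object An `nb_cluster` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_cluster <- function(object, ...) {
  emb <- object$embedding
  if (ncol(emb) < 3L) {
    emb$dim2 <- 0
  }
  df <- dplyr::left_join(emb, object$partition, by = "node")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "embedding dim 1", y = "embedding dim 2",
                  colour = "cluster",
                  title = paste0(object$operator, " spectral embedding, k = ",
                                 object$k)) +
    ggplot2::theme_minimal()
}
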