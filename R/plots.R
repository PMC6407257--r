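# ggplot2 views of the main result types.

#' @export
autoplot.gtm_model <- function(object, labels = NULL, ...) {
  if (is.null(object$responsibilities)) {
    stop_gtmap("Fit the model (max_iter > 0) before plotting.",
               "gtmap_parameter_error")
  }
  pos <- gtm_mean_positions(object$responsibilities, object$grid)
  if (!is.null(labels)) pos$label <- as.character(labels)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "map x", y = "map y",
                  title = "Mean positions on the GTM map")
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7) +
      ggplot2::labs(colour = "population")
  }
}

#' @export
autoplot.ancestry_model <- function(object, ...) {
  if (is.null(object$grid)) {
    stop_gtmap("The ancestry model carries no grid; refit with `grid = `.",
               "gtmap_parameter_error")
  }
  nm <- node_color_map(object)
  ggplot2::ggplot(nm, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$a_max,
                                   alpha = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_alpha(range = c(0.2, 1)) +
    ggplot2::labs(x = "map x", y = "map y", fill = "most probable ancestry",
                  alpha = "posterior",
                  title = "Nodes coloured by most probable ancestry")
}

#' @export
autoplot.cv_result <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$class, y = .data$f1_mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$f1_mean - .data$f1_dispersion,
                                        ymax = .data$f1_mean + .data$f1_dispersion),
                           width = 0.25) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "F1 (mean ± 95% interval)",
                  title = "Per-class cross-validated F1")
}

#' Plot a principal-component sweep
#'
#' @param sweep_tbl Output of [pc_sweep()].
#' @return A ggplot of overall weighted F1 against the number of principal
#'   components.
#' @export
plot_pc_sweep <- function(sweep_tbl) {
  ggplot2::ggplot(sweep_tbl, ggplot2::aes(x = .data$n_pcs,
                                          y = .data$overall_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$overall_f1 - .data$dispersion,
                                          ymax = .data$overall_f1 + .data$dispersion)) +
    ggplot2::labs(x = "principal components", y = "overall weighted F1",
                  title = "Classification performance by number of PCs")
}

#' @importFrom rlang .data
NULL
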