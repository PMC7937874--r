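#' Plot a PCA result
#'
#' `type = "scree"` draws the eigenvalue profile along the principal
#' component modes; `type = "projection"` maps the frames onto two principal
#' components (colored by source ensemble for a joint PCA, otherwise by
#' frame index).
#'
#' @param object A `"go_pca"` object.
#' @param type `"scree"` or `"projection"`.
#' @param n_modes Modes shown in the scree plot.
#' @param components Two components for the projection plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.go_pca <- function(object, type = c("scree", "projection"),
                            n_modes = 10, components = c(1, 2), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    df <- tidy(object, n_modes = n_modes)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$eigenvalue)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::labs(x = "principal component mode",
                      y = expression(eigenvalue ~ (nm^2))) +
        ggplot2::theme_minimal()
    )
  }
  pcs <- paste0("PC", components)
  df <- object$projections
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]]))
  if ("ensemble" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$ensemble),
                                 alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$frame), alpha = 0.6)
  }
  p + ggplot2::labs(x = paste0(pcs[1], " (nm)"), y = paste0(pcs[2], " (nm)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-residue RMSF profile plot
#'
#' @param rmsf_tbl Tibble from [rmsf()].
#' @return A ggplot object.
#' @export
plot_rmsf <- function(rmsf_tbl) {
  ggplot2::ggplot(rmsf_tbl,
                  ggplot2::aes(x = .data$resid, y = .data$rmsf,
                               colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (nm)") +
    ggplot2::theme_minimal()
}

#' Interface-contact fraction time series plot
#'
#' @param qab_tbl Tibble from [qab()].
#' @return A ggplot object.
#' @export
plot_qab <- function(qab_tbl) {
  xvar <- if ("time" %in% names(qab_tbl)) "time" else "frame"
  ggplot2::ggplot(qab_tbl,
                  ggplot2::aes(x = .data[[xvar]], y = .data$qab)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = if (xvar == "time") "time (ns)" else "frame",
                  y = expression(Q[AB])) +
    ggplot2::theme_minimal()
}

#' Minimum-distance time series plot
#'
#' @param dist_tbl Tibble from [min_distance_series()].
#' @return A ggplot object.
#' @export
plot_min_distance <- function(dist_tbl) {
  xvar <- if ("time" %in% names(dist_tbl)) "time" else "frame"
  ggplot2::ggplot(dist_tbl,
                  ggplot2::aes(x = .data[[xvar]], y = .data$min_dist)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "time") "time (ns)" else "frame",
                  y = "minimum distance (nm)") +
    ggplot2::theme_minimal()
}
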