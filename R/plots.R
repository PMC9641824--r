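#' Plot a segmented track
#'
#' Daily roost-to-roost path coloured by day class, one panel per
#' individual.
#'
#' @param object A `track_segmentation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.track_segmentation <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$roost_end_lon,
                                    y = .data$roost_end_lat)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$day_class), size = 2) +
    ggplot2::facet_wrap(~individual_id) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Day class") +
    ggplot2::theme_minimal()
}

#' Ordination plot
#'
#' First two principal coordinates, optionally coloured by a grouping
#' vector.
#'
#' @param object A `pcoa_ord`.
#' @param group Optional per-sample grouping vector.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_ord <- function(object, group = NULL, ...) {
  pts <- object$points
  if (!is.null(group)) pts$group <- group
  pct <- round(100 * object$prop_explained[1:2], 1)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  p <- if (is.null(group)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group),
                            linetype = "dashed")
  }
  p + ggplot2::labs(x = paste0("Axis 1 (", pct[1], "%)"),
                    y = paste0("Axis 2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Differential-abundance log-fold-change plot
#'
#' Selected taxa as a horizontal lollipop of log-fold changes; positive
#' values mean higher abundance at higher covariate values (or in the
#' second factor level).
#'
#' @param object A `da_fit`.
#' @param selected_only Show only selected taxa.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.da_fit <- function(object, selected_only = TRUE, ...) {
  res <- object$results
  if (selected_only) res <- dplyr::filter(res, .data$selected)
  res <- dplyr::arrange(res, .data$lfc)
  res$taxon <- factor(res$taxon, levels = res$taxon)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$lfc, y = .data$taxon)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$lfc,
                                       yend = .data$taxon), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$lfc > 0), size = 2,
                        show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Log-fold change", y = NULL) +
    ggplot2::theme_minimal()
}
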