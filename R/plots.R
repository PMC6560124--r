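# QC visualisation: ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the bridge-distance distribution behind a width estimate
#'
#' Histogram of the per-vertex bridge distances with the median (the
#' reported sulcal width) marked.  A long tail of short bridges usually
#' comes from the sulcus's end walls; the median is robust to it.
#'
#' @param object A `sulc_width` from [compute_width()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sulc_width
#' @export
autoplot.sulc_width <- function(object, ...) {
  ggplot2::ggplot(object$bridges, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$width, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s: width %.2f mm (median of %d bridges)",
                      object$label_name, object$width, object$n_bridges),
      x = "bridge distance (mm)", y = "loop vertices")
}

#' Plot the fundus-distance distribution behind a depth estimate
#'
#' @param object A `sulc_depth` from [compute_depth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sulc_depth
#' @export
autoplot.sulc_depth <- function(object, ...) {
  ggplot2::ggplot(object$fundus, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkorange", colour = "white") +
    ggplot2::geom_vline(xintercept = object$depth, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s: depth %.2f mm (median over %d fundus vertices)",
                      object$label_name, object$depth, object$n_fundus),
      x = "distance to outer surface (mm)", y = "fundus vertices")
}

#' Plot per-sulcus measure distributions and failure rates for a cohort
#'
#' @param object A `sulc_cohort` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object: boxplots of width/depth per sulcus, with the
#'   per-sulcus failure percentage in the strip label.
#' @method autoplot sulc_cohort
#' @export
autoplot.sulc_cohort <- function(object, ...) {
  qc <- object$summary$qc |>
    dplyr::mutate(lab = sprintf("%s (%s: %.0f%% fail)", .data$sulcus,
                                .data$metric, 100 * .data$failure_rate))
  df <- object$measures |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::left_join(qc, by = c("hemi", "sulcus", "metric"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sulcus, y = .data$value,
                                   fill = .data$hemi)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate (mm)")
}
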