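# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the delivery-metric time series of a case
#'
#' Near-wall mole percentages (D/15 and D/30 layers) and the running maximum
#' normalised wall concentration, per species, against time in periods.
#'
#' @param object a `case_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot case_result
#' @export
autoplot.case_result <- function(object, ...) {
  m <- tidyr::pivot_longer(object$metrics,
                           c("nearwall_D15_pct", "nearwall_D30_pct"),
                           names_to = "layer", values_to = "pct")
  m$layer <- ifelse(m$layer == "nearwall_D15_pct", "D/15", "D/30")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$period, y = .data$pct,
                                  colour = .data$species,
                                  linetype = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (periods)", y = "moles near wall (%)",
                  colour = "species", linetype = "layer") +
    ggplot2::theme_minimal()
}

#' Plot wall surface-concentration profiles of a case
#'
#' @param result a `case_result`.
#' @param times subset of snapshot times to show (default all).
#' @return a ggplot.
#' @export
plot_surface_profiles <- function(result, times = NULL) {
  pr <- result$profiles
  if (!is.null(times)) {
    keep <- vapply(pr$t, function(t) any(abs(t - times) < 1e-6), logical(1))
    pr <- pr[keep, ]
  }
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$z, y = .data$c_norm,
                                   colour = factor(round(.data$t, 1)))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "axial position (cm)", y = "wall c/ci",
                  colour = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot colocalisation scores of an ensemble
#' @param object a `coloc_table` from [colocalise()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coloc_table
#' @export
autoplot.coloc_table <- function(object, ...) {
  d <- object[order(object$cs), ]
  d$case <- factor(d$case_id, levels = d$case_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$case, y = .data$cs)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "case", y = "colocalisation score") +
    ggplot2::theme_minimal()
}

#' Plot cluster assignments of the colocalisation scores
#' @param object a `cluster_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  d <- object$table
  d$cluster <- factor(d$cluster)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$cs,
                                  colour = .data$cluster)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "cluster (sorted by mean CS)", y = "CS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the mean-absolute-SHAP feature ranking
#' @param object an `attribution_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot attribution_result
#' @export
autoplot.attribution_result <- function(object, ...) {
  d <- object$ranking
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_abs_shap, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP| (CS units)", y = NULL) +
    ggplot2::theme_minimal()
}
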