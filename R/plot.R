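# Timeline visualisations: annotated vs detected periods with their
# overlap, in the style used to audit interaction detectors.

#' Timeline plot of truth vs detected periods
#'
#' Truth periods in green, detected periods in blue, their overlap in red;
#' one horizontal lane per source, time on the x axis in minutes.
#'
#' @param truth,detected Period tibbles with `start_s`, `end_s`.
#' @return A ggplot object.
#' @export
plot_period_timeline <- function(truth, detected) {
  seg <- dplyr::bind_rows(
    dplyr::mutate(truth[c("start_s", "end_s")], source = "truth"),
    dplyr::mutate(detected[c("start_s", "end_s")], source = "detected")
  )
  ov <- dplyr::bind_rows(purrr::pmap(truth[c("start_s", "end_s")], function(start_s, end_s) {
    hit <- detected[detected$start_s <= end_s & detected$end_s >= start_s, ]
    if (nrow(hit) == 0) return(NULL)
    tibble(start_s = pmax(start_s, hit$start_s), end_s = pmin(end_s, hit$end_s))
  }))
  lane <- c(truth = 2, detected = 1)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start_s / 60, xmax = (.data$end_s + 0.25) / 60,
                   ymin = lane[.data$source] - 0.35, ymax = lane[.data$source] + 0.35,
                   fill = .data$source)
    ) +
    ggplot2::scale_fill_manual(values = c(truth = "#2e7d32", detected = "#1565c0")) +
    ggplot2::scale_y_continuous(breaks = c(1, 2), labels = c("detected", "truth"),
                                limits = c(0.5, 2.5)) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (nrow(ov) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ov,
      ggplot2::aes(xmin = .data$start_s / 60, xmax = (.data$end_s + 0.25) / 60,
                   ymin = 0.65, ymax = 2.35),
      fill = "#c62828", alpha = 0.35
    )
  }
  p
}

#' Plot a period matching
#'
#' Timeline of the matched truth and detected periods with per-pair IoU in
#' the subtitle.
#'
#' @param object A [match_periods()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.period_matches <- function(object, ...) {
  m <- object$matches
  truth <- tibble(start_s = m$truth_start_s, end_s = m$truth_end_s)
  det <- dplyr::bind_rows(
    tibble(start_s = m$det_start_s, end_s = m$det_end_s),
    object$false_detections
  )
  g <- glance(object)
  plot_period_timeline(truth, det) +
    ggplot2::labs(
      title = "Truth vs detected interaction periods",
      subtitle = sprintf("mean IoU %.2f, mean OBOA %.2f over %d matched periods",
                         g$mean_iou, g$mean_oboa, g$n_matched)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
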