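#' Plot a summary-score composition bar chart
#'
#' One stacked bar per case, subdivided into the four pathology axes
#' (ADNC, microvascular, Lewy body, LATE-NC), ordered by total score --
#' the standard at-a-glance view of comorbid pathology burden across a
#' cohort.
#'
#' @param scores Output of [summary_score()] including a `case_id` column.
#' @return A ggplot object.
#' @export
plot_score_composition <- function(scores) {
  stopifnot("case_id" %in% names(scores))
  long <- scores %>%
    select("case_id", "adnc_subscore", "uvbi_subscore",
           "lbd_subscore", "late_subscore") %>%
    tidyr::pivot_longer(-"case_id", names_to = "axis", values_to = "subscore") %>%
    mutate(axis = factor(.data$axis,
                         levels = c("adnc_subscore", "uvbi_subscore",
                                    "lbd_subscore", "late_subscore"),
                         labels = c("ADNC", "µVBI", "LBD", "LATE-NC")))
  order <- scores %>% arrange(.data$total) %>% pull("case_id")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$case_id, levels = order),
    y = .data$subscore, fill = .data$axis)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(ADNC = "grey55", `µVBI` = "slateblue",
                                          LBD = "black", `LATE-NC` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Summary neuropathology score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot longitudinal CASI trajectories
#'
#' @param casi Long-format CASI table (`case_id`, `date`, `casi`).
#' @param referral_threshold Score triggering dementia evaluation
#'   (drawn as a dashed line; default 85).
#' @return A ggplot object.
#' @export
plot_casi_trajectories <- function(casi, referral_threshold = 85) {
  ggplot2::ggplot(casi, ggplot2::aes(x = .data$date, y = .data$casi,
                                     group = .data$case_id,
                                     color = .data$case_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = referral_threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "CASI score") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Autoplot a threshold calibration
#'
#' Shows the pooled positive and negative cumulative object fractions over
#' the 0-255 intensity axis with the selected threshold, the visual
#' counterpart of the percentile calibration rule.
#'
#' @param object An `npq_calibration` result from
#'   [calibrate_positive_threshold()]; must carry the pooled histograms as
#'   attributes `positive_cdf`/`negative_cdf` or be re-plotted from the
#'   training histograms via the `positive_histograms`/`negative_histograms`
#'   arguments.
#' @param positive_histograms,negative_histograms Training histograms (as
#'   in [calibrate_positive_threshold()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npq_calibration
#' @export
autoplot.npq_calibration <- function(object, positive_histograms,
                                     negative_histograms, ...) {
  pool <- function(hs) {
    s <- Reduce(`+`, hs)
    cumsum(s) / sum(s)
  }
  df <- tibble(
    intensity = rep(0:255, 2),
    fraction = c(pool(positive_histograms), pool(negative_histograms)),
    slides = rep(c("positive", "negative"), each = 256)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$intensity, .data$fraction,
                                   color = .data$slides)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Mean object DAB intensity",
                  y = "Cumulative object fraction", color = NULL) +
    ggplot2::theme_minimal()
}
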