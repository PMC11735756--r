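# ggplot2 autoplot methods for the main result types.

#' Plot a power curve
#'
#' Monte-Carlo power against cohort size with the closed-form
#' `1 - (1 - p)^N` overlaid and the target power marked.
#'
#' @param object A `power_curve`.
#' @param target Target power line (default 0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_curve <- function(object, target = 0.95, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power_closed_form),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$power,
      ymin = .data$power - 2 * .data$power_se,
      ymax = pmin(1, .data$power + 2 * .data$power_se))) +
    ggplot2::geom_hline(yintercept = target, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::labs(x = "cohort size N", y = "power",
                  title = sprintf("Binomial power, p = %.2g",
                                  attr(object, "p"))) +
    ggplot2::theme_minimal()
}

#' Plot a time-resolved decoding AUC
#'
#' @param object A `timepoint_auc` tibble from [timepoint_decode()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timepoint_auc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60",
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from fifth-tone onset (s)", y = "test AUC") +
    ggplot2::theme_minimal()
}

#' Plot decoding results against their permutation null
#'
#' Histogram of permutation AUCs per contrast x decoder with the observed
#' test AUC marked.
#'
#' @param object A `decoding_results` tibble from [run_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_results <- function(object, ...) {
  nulls <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object), "contrast", "decoder",
                  "perm_aucs"), "perm_aucs")
  obs <- glance(object)
  ggplot2::ggplot(nulls, ggplot2::aes(.data$perm_aucs)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$auc),
                        colour = "firebrick") +
    ggplot2::facet_grid(contrast ~ decoder) +
    ggplot2::labs(x = "AUC", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus schedule
#'
#' Series onsets along the session, coloured by global label, one row per
#' block.
#'
#' @param object A `stimulus_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus_schedule <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$onset, factor(.data$block),
                               colour = .data$global_label)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time (s)", y = "block", colour = "global") +
    ggplot2::theme_minimal()
}
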