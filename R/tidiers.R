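# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power curve
#'
#' One row per candidate cohort size with the Monte-Carlo power estimate, its
#' SE, the mean success count, and the closed-form power `1 - (1 - p)^N`.
#'
#' @param x A `power_curve`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.power_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.power_curve
#' @param target Target power used for the minimal sample size.
#' @export
glance.power_curve <- function(x, target = 0.95, ...) {
  n_min <- tryCatch(minimal_sample_size(x, target), error = function(e) NA_integer_)
  tibble::tibble(p = attr(x, "p"), alpha = attr(x, "alpha"),
                 n_sims = attr(x, "n_sims"), target = target,
                 n_minimal = n_min,
                 mean_k_at_minimal = if (is.na(n_min)) NA_real_ else
                   x$mean_k[x$n == n_min])
}

#' Tidy decoding results
#'
#' `tidy()` returns per-trial decision scores (long); `glance()` one row per
#' contrast x decoder with AUC and significance.
#'
#' @param x A `decoding_results` tibble from [run_recording()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.decoding_results <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "id", "contrast", "decoder", "scores"),
    "scores")
}

#' @rdname tidy.decoding_results
#' @export
glance.decoding_results <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "id", "contrast", "decoder", "auc",
                "cv_auc", "p_empirical", "p_wilcoxon", "significant", "n_perm")
}

#' Tidy a sedation model selection
#'
#' `tidy()` returns the selected model's coefficients; `glance()` the selected
#' terms, adjusted R2 and AIC.
#'
#' @param x A `model_selection` from [sedation_model_selection()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.model_selection <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std_error = cf[, 2], statistic = cf[, 3], p_value = cf[, 4])
}

#' @rdname tidy.model_selection
#' @export
glance.model_selection <- function(x, ...) {
  tibble::tibble(
    selected = paste(x$selected, collapse = " + "),
    n_terms = length(x$selected),
    adj_r2 = summary(x$model)$adj.r.squared,
    aic = stats::AIC(x$model),
    family = x$family)
}
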