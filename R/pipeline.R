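# Orchestration: end-to-end decoding of one recording and of a whole cohort,
# with deterministic seed fan-out and provenance.

#' Run configuration for end-to-end analyses
#'
#' Bundles every stage's parameters behind one global seed. All child seeds
#' are derived deterministically from `seed` and the stage name, so a rerun
#' with the same config reproduces every number.
#'
#' @param contrasts Label dimensions to decode (`"global"`, `"local"`).
#' @param decoders Decoders to run (`"stta"`, `"svm_concat"`).
#' @param stta,svm Stage configs ([stta_config()], [svm_config()]).
#' @param n_perm Permutations for the null (>= 100 per the analysis plan).
#' @param min_perm Floor on `n_perm` (lower for scaled-down runs).
#' @param alpha Significance level.
#' @param criterion Significance criterion, see [significance()].
#' @param cv_frac CV fraction of the 80/20 split.
#' @param amp_thresh,bad_channel_frac Cleaning thresholds.
#' @param baseline Apply baseline correction (default TRUE).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(contrasts = c("global", "local"),
                       decoders = c("stta", "svm_concat"),
                       stta = NULL, svm = NULL,
                       n_perm = 100L, min_perm = 100L, alpha = 0.05,
                       criterion = "both", cv_frac = 0.8,
                       amp_thresh = 150, bad_channel_frac = 0.2,
                       baseline = TRUE, seed = 1L) {
  structure(list(contrasts = contrasts, decoders = decoders,
                 stta = stta %||% stta_config(seed = child_seed(seed, "stta")),
                 svm = svm %||% svm_config(seed = child_seed(seed, "svm")),
                 n_perm = n_perm, min_perm = min_perm, alpha = alpha,
                 criterion = criterion, cv_frac = cv_frac,
                 amp_thresh = amp_thresh,
                 bad_channel_frac = bad_channel_frac,
                 baseline = baseline, seed = seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips every scalar and list field of [run_config()] (and its nested
#' [stta_config()] / [svm_config()]) so a run is fully described by one file.
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stta$windows <- lapply(raw$stta$windows, as.numeric)
  stta <- do.call(stta_config,
                  raw$stta[intersect(names(raw$stta),
                                     names(formals(stta_config)))])
  svm <- do.call(svm_config,
                 raw$svm[intersect(names(raw$svm), names(formals(svm_config)))])
  args <- raw[setdiff(names(raw), c("stta", "svm"))]
  do.call(run_config, c(args, list(stta = stta, svm = svm)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Decode one recording end to end
#'
#' Pipeline per contrast and decoder: clean -> baseline-correct ->
#' GFP-normalize (STTA) -> 80/20 split -> CV selection -> refit -> test AUC ->
#' permutation null -> significance. Returns one row per contrast x decoder.
#'
#' @param epochs An [eeg_epochs] (already band-passed/epoched; use
#'   [bandpass()] + [extract_epochs()] for continuous data).
#' @param config A [run_config()].
#' @param id Recording identifier carried into the output.
#' @return A `decoding_results` tibble: `id`, `contrast`, `decoder`, `auc`,
#'   `cv_auc`, `p_empirical`, `p_wilcoxon`, `significant`, `n_perm`,
#'   `selected` (list-column: k/window or kernel/C/gamma), `scores`
#'   (list-column), `perm_aucs` (list-column).
#' @export
run_recording <- function(epochs, config = run_config(), id = "rec") {
  cleaned <- tryCatch(
    reject_and_interpolate(epochs, config$amp_thresh,
                           config$bad_channel_frac)$epochs,
    error = function(e) stop("[cleaning] ", conditionMessage(e)))
  if (config$baseline) cleaned <- baseline_correct(cleaned)
  normed <- gfp_normalize(cleaned)

  rows <- list()
  for (contrast in config$contrasts) {
    for (decoder in config$decoders) {
      input <- if (decoder == "stta") normed else cleaned
      dcfg <- if (decoder == "stta") config$stta else config$svm
      res <- tryCatch(
        run_decoder(input, decoder, dcfg, contrast,
                    cv_frac = config$cv_frac,
                    seed = child_seed(config$seed, id, contrast, "split")),
        error = function(e) stop("[decode:", decoder, "] ",
                                 conditionMessage(e)))
      perms <- tryCatch(
        permutation_null(input, decoder, dcfg, contrast,
                         n_perm = config$n_perm, cv_frac = config$cv_frac,
                         seed = child_seed(config$seed, id, contrast, decoder),
                         min_perm = config$min_perm),
        error = function(e) stop("[permutation:", decoder, "] ",
                                 conditionMessage(e)))
      sig <- significance(res$auc, perms, alpha = config$alpha,
                          criterion = config$criterion,
                          min_perm = config$min_perm)
      selected <- if (decoder == "stta")
        list(k = res$k, window = res$window)
      else list(kernel = res$kernel, cost = res$cost, gamma = res$gamma)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, contrast = contrast, decoder = decoder,
        auc = res$auc, cv_auc = res$cv_auc,
        p_empirical = sig$p_empirical, p_wilcoxon = sig$p_wilcoxon,
        significant = sig$significant, n_perm = sig$n_perm,
        selected = list(selected), scores = list(res$scores),
        perm_aucs = list(perms))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("decoding_results", class(out))
  out
}

#' Run a whole cohort and compute the group-level statistics
#'
#' Either decodes a list of recordings (filling the cohort table's `auc` and
#' `significant` columns) or takes the table's existing columns as given,
#' then computes, per day: the FOUR and CPC Pearson correlations, the
#' outcome Fisher test, Kruskal-Wallis comparisons of clinical features
#' between decodable and non-decodable recordings, and the sedation
#' forward-selection model.
#'
#' @param cohort A list as returned by [simulate_cohort()] (`table` +
#'   optional `recordings`), or just a `cohort_table`.
#' @param config A [run_config()]; used only when recordings are decoded.
#' @param kw_features Clinical columns compared across decoding groups.
#' @return A list of class `cohort_results`: `table` (with decoded `auc` /
#'   `significant` when recordings were supplied), `correlations` (tibble),
#'   `fisher` (tibble or NULL with a `skipped` message), `kruskal` (tibble),
#'   `model_selection` (a `model_selection` or NULL).
#' @export
run_cohort <- function(cohort, config = run_config(),
                       kw_features = c("propofol", "fentanyl", "midazolam",
                                       "temperature", "age")) {
  if (tibble::is_tibble(cohort)) cohort <- list(table = cohort,
                                                recordings = NULL)
  tab <- cohort$table
  if (!is.null(cohort$recordings)) {
    stopifnot(length(cohort$recordings) == nrow(tab))
    res <- purrr::imap(cohort$recordings, function(ep, i)
      run_recording(ep, config, id = tab$id[i]))
    first <- purrr::map(res, ~ dplyr::slice(.x, 1L))
    tab$auc <- purrr::map_dbl(first, "auc")
    tab$significant <- purrr::map_lgl(first, "significant")
  }
  if (nrow(tab) < 2L) stop("need at least 2 recordings")

  correlations <- tab |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) {
      one <- function(y, nm) tryCatch(
        dplyr::mutate(correlate(d$auc, y), scale = nm),
        error = function(e) NULL)
      dplyr::bind_rows(one(d$four, "four"), one(d$cpc, "cpc"))
    }) |>
    dplyr::ungroup()

  fisher <- tryCatch(outcome_fisher(tab),
                     error = function(e) {
                       message("Fisher test skipped: ", conditionMessage(e))
                       NULL
                     })

  kruskal <- purrr::map_dfr(kw_features, function(f) {
    tryCatch(
      dplyr::mutate(kruskal_wallis(tab[[f]],
                                   ifelse(tab$significant, "decodable",
                                          "non-decodable")),
                    feature = f, .before = 1L),
      error = function(e) NULL)
  })

  modsel <- tryCatch(sedation_model_selection(tab),
                     error = function(e) {
                       message("model selection skipped: ",
                               conditionMessage(e))
                       NULL
                     })

  structure(list(table = tab, correlations = correlations, fisher = fisher,
                 kruskal = kruskal, model_selection = modsel,
                 config_seed = config$seed),
            class = "cohort_results")
}
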