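# On-disk formats: epoch container (flat CSV matrix + JSON sidecar), cohort
# table CSV, decoding-result JSON.

#' Write / read an epoch set
#'
#' The container is a directory: `data.csv` holds the flattened array (one row
#' per trial x channel, samples as columns), `labels.csv` the per-trial
#' labels, `channels.csv` the channel metadata, and `meta.json` the sidecar
#' (dimensions, times, sfreq, log).
#'
#' @param epochs An [eeg_epochs].
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly; `read_epochs()` returns the [eeg_epochs].
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- epochs$data
  dm <- dim(d)
  flat <- matrix(aperm(d, c(2, 1, 3)), dm[1] * dm[2], dm[3]) # trial-major rows
  utils::write.table(flat, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  readr::write_csv(epochs$labels, file.path(dir, "labels.csv"))
  readr::write_csv(epochs$channels, file.path(dir, "channels.csv"))
  jsonlite::write_json(
    list(dim = dm, times = epochs$times, sfreq = epochs$sfreq,
         log = epochs$log),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  dm <- meta$dim
  data <- aperm(array(flat, dim = c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  eeg_epochs(data = data, times = meta$times, sfreq = meta$sfreq,
             labels = readr::read_csv(file.path(dir, "labels.csv"),
                                      show_col_types = FALSE),
             channels = readr::read_csv(file.path(dir, "channels.csv"),
                                        show_col_types = FALSE),
             log = meta$log)
}

#' Write / read a cohort table
#'
#' Plain CSV with the documented column dictionary (`id`, `day`, `auc`,
#' `significant`, `four`, `cpc`, `outcome`, sedative infusion rates,
#' `temperature`, `age`, `sex`).
#'
#' @param table A `cohort_table`.
#' @param path CSV path.
#' @return `path` invisibly; `read_cohort_csv()` returns the tibble.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Serialize decoding results to JSON
#'
#' One JSON object per contrast x decoder row with AUC, p-values, the
#' selected hyperparameters and the permutation null.
#'
#' @param results A `decoding_results` tibble from [run_recording()].
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
write_decoding_json <- function(results, path) {
  recs <- purrr::pmap(tibble::as_tibble(results), function(...) {
    row <- list(...)
    list(id = row$id, contrast = row$contrast, decoder = row$decoder,
         auc = row$auc, cv_auc = row$cv_auc,
         p_empirical = row$p_empirical, p_wilcoxon = row$p_wilcoxon,
         significant = row$significant, n_perm = row$n_perm,
         selected = row$selected, perm_aucs = row$perm_aucs)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
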