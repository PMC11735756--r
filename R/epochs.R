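# eeg_epochs: the package's epoch container. A light S3 list holding a
# trials x channels x samples array plus tibble metadata; all decoding
# functions consume and return it or tibbles derived from it.

#' Construct an epoch set
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param times Numeric vector of sample times in seconds relative to the
#'   fifth-tone onset; length must match `dim(data)[3]`.
#' @param sfreq Sampling rate in Hz.
#' @param labels Tibble with one row per trial; must contain `global` and
#'   `local` columns with values `"standard"`/`"deviant"`.
#' @param channels Tibble of channel metadata (`name`, and `x`,`y`,`z` unit
#'   sphere positions when available).
#' @param log Character vector of provenance messages.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, sfreq, labels, channels = NULL,
                       log = character()) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3] == length(times),
            dim(data)[1] == nrow(labels),
            all(c("global", "local") %in% names(labels)))
  if (is.null(channels))
    channels <- tibble::tibble(name = sprintf("E%02d", seq_len(dim(data)[2])))
  stopifnot(nrow(channels) == dim(data)[2])
  structure(list(data = data, times = times, sfreq = sfreq,
                 labels = tibble::as_tibble(labels),
                 channels = tibble::as_tibble(channels),
                 log = log),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  time %g..%g s | global: %s | local: %s\n",
              min(x$times), max(x$times),
              paste(table(x$labels$global), collapse = "/"),
              paste(table(x$labels$local), collapse = "/")))
  invisible(x)
}

#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  x$data <- x$data[i, , , drop = FALSE]
  x$labels <- x$labels[i, , drop = FALSE]
  if (!is.null(x$gfp)) x$gfp <- x$gfp[i, , drop = FALSE]
  if (!is.null(x$mask)) x$mask <- x$mask[i, , drop = FALSE]
  x
}

n_trials <- function(x) dim(x$data)[1]

# Binary labels for a contrast: factor standard/deviant.
contrast_labels <- function(epochs, contrast = c("global", "local")) {
  contrast <- match.arg(contrast)
  factor(epochs$labels[[contrast]], levels = c("standard", "deviant"))
}

#' Stratified CV/test split of an epoch set
#'
#' Splits trials into a cross-validation set (default 80%) and a held-out
#' test set (20%), stratified by the chosen contrast label so class
#' proportions are preserved within one trial per class.
#'
#' @param epochs An [eeg_epochs] (or GFP-normalized) object.
#' @param cv_frac Fraction of trials in the CV set.
#' @param contrast `"global"` or `"local"`: which label stratifies the split.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with `cv` and `test` epoch sets.
#' @export
split_cv_test <- function(epochs, cv_frac = 0.8, contrast = "global",
                          seed = 1L) {
  y <- contrast_labels(epochs, contrast)
  counts <- table(y)
  if (any(counts < 5L))
    stop("each class needs at least 5 trials for an 80/20 split; got ",
         paste(counts, collapse = "/"))
  test_idx <- withr_seed(seed, {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      n_test <- round(length(idx) * (1 - cv_frac))
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(cv = epochs[setdiff(seq_along(y), test_idx)],
       test = epochs[test_idx])
}
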