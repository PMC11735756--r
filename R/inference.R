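# Significance of a recording's decoding: AUC, permutation null (labels
# shuffled before the CV/test split so selection bias is inside the null),
# empirical and Wilcoxon p-values.

#' Area under the ROC curve from decision scores
#'
#' The probability that a randomly drawn deviant trial outscores a randomly
#' drawn standard trial, with ties counted 1/2 (midranks); identical to the
#' Mann-Whitney U statistic divided by `n_dev * n_std`.
#'
#' @param scores Numeric decision values, higher = more deviant-like.
#' @param labels Factor or character with levels `standard` / `deviant`.
#' @return AUC in [0, 1].
#' @examples
#' compute_auc(c(0.9, 0.7, 0.3, 0.4),
#'             c("deviant", "standard", "standard", "deviant"))  # 0.75
#' @export
compute_auc <- function(scores, labels) {
  labels <- factor(labels, levels = c("standard", "deviant"))
  if (anyNA(labels)) stop("labels must be 'standard' or 'deviant'")
  n_dev <- sum(labels == "deviant"); n_std <- sum(labels == "standard")
  if (n_dev == 0L || n_std == 0L)
    stop("AUC needs both classes; got ", n_std, " standard / ", n_dev,
         " deviant")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels == "deviant"]) - n_dev * (n_dev + 1) / 2) / (n_dev * n_std)
}

#' Permutation null distribution of the test AUC
#'
#' For each permutation the trial labels on the chosen contrast are shuffled
#' across trials *before* the CV/test split, then the entire pipeline — split,
#' CV selection, refit, test AUC — is re-run, so the null distribution carries
#' the same selection optimism as the observed value.
#'
#' @param epochs GFP-normalized (for STTA) or raw epochs for the whole
#'   recording.
#' @param decoder `"stta"` or `"svm_concat"`.
#' @param config An [stta_config()] or [svm_config()].
#' @param contrast `"global"` or `"local"`.
#' @param n_perm Number of permutations (>= 100 per the analysis plan; tests
#'   may scale this down via `min_perm`).
#' @param cv_frac CV fraction for the split.
#' @param seed Integer seed.
#' @param min_perm Floor enforced on `n_perm` (default 100; lower it
#'   explicitly for scaled-down property checks).
#' @return Numeric vector of `n_perm` permutation AUCs.
#' @export
permutation_null <- function(epochs, decoder = c("stta", "svm_concat"),
                             config = NULL, contrast = "global",
                             n_perm = 100L, cv_frac = 0.8, seed = 1L,
                             min_perm = 100L) {
  decoder <- match.arg(decoder)
  if (n_perm < min_perm)
    stop("n_perm must be >= ", min_perm, " (pass min_perm to scale down)")
  if (is.null(config))
    config <- if (decoder == "stta") stta_config() else svm_config()
  n <- n_trials(epochs)
  purrr::map_dbl(seq_len(n_perm), function(p) {
    perm <- withr_seed(child_seed(seed, "perm", p), sample(n))
    shuffled <- epochs
    shuffled$labels[[contrast]] <- epochs$labels[[contrast]][perm]
    run_decoder(shuffled, decoder, config, contrast,
                cv_frac = cv_frac, seed = child_seed(seed, "permsplit", p))$auc
  })
}

# One full decode of a recording: split -> CV -> refit -> test AUC.
run_decoder <- function(epochs, decoder, config, contrast, cv_frac = 0.8,
                        seed = 1L) {
  sp <- split_cv_test(epochs, cv_frac = cv_frac, contrast = contrast,
                      seed = seed)
  if (decoder == "stta") decode_test_stta(sp$cv, sp$test, config, contrast)
  else decode_test_svm(sp$cv, sp$test, config, contrast)
}

#' Significance of an observed AUC against its permutation null
#'
#' Two complementary criteria are reported. The empirical permutation p-value
#' uses add-one smoothing, `(1 + #\{perm >= observed\}) / (n_perm + 1)`, so it
#' is never zero. The analysis plan's criterion is a one-sided Wilcoxon
#' signed-rank test of the permutation AUCs against the observed value
#' (observed greater); because a one-sample test of a whole null distribution
#' against a single offset is significant for almost any positive offset, the
#' `significant` flag defaults to the conjunction of both p-values at `alpha`
#' (`criterion = "both"`); `"empirical"` or `"wilcoxon"` select either alone.
#'
#' @param observed Observed test AUC.
#' @param perm_aucs Numeric vector of permutation AUCs (>= 100 unless
#'   `min_perm` is lowered).
#' @param alpha Significance level (default 0.05).
#' @param criterion `"both"`, `"empirical"`, or `"wilcoxon"`.
#' @param min_perm Floor on the permutation count.
#' @return A tibble: `p_empirical`, `p_wilcoxon`, `significant`, `n_perm`,
#'   `observed`.
#' @export
significance <- function(observed, perm_aucs, alpha = 0.05,
                         criterion = c("both", "empirical", "wilcoxon"),
                         min_perm = 100L) {
  criterion <- match.arg(criterion)
  n_perm <- length(perm_aucs)
  if (n_perm < min_perm)
    stop("need >= ", min_perm, " permutation AUCs; got ", n_perm)
  p_emp <- (1 + sum(perm_aucs >= observed)) / (n_perm + 1)
  diffs <- perm_aucs - observed
  p_wil <- if (all(diffs == 0)) 1 else
    suppressWarnings(stats::wilcox.test(diffs, alternative = "less",
                                        exact = n_perm <= 25)$p.value)
  sig <- switch(criterion,
                both = p_emp < alpha && p_wil < alpha,
                empirical = p_emp < alpha,
                wilcoxon = p_wil < alpha)
  tibble::tibble(p_empirical = p_emp, p_wilcoxon = p_wil,
                 significant = sig, n_perm = n_perm, observed = observed)
}
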