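# Single-trial topographical analysis (STTA): each condition's GFP-normalized
# voltage topographies are modelled by a mixture of Gaussians whose component
# means act as template maps; held-out trials are scored by the cumulative
# log-likelihood ratio of the two condition models over a discriminative time
# window selected (with the number of Gaussians) by cross-validation.

#' Fit a diagonal-covariance Gaussian mixture to topographies
#'
#' EM with `restarts` random initializations (k-means++-style seeding of the
#' means from data points); the best final log-likelihood wins. Covariances
#' are diagonal per component — with many channels and comparatively few
#' trials, full covariances are rank-deficient; a full-covariance variant is
#' not provided. Components whose variance collapses below `var_floor` have
#' it clamped; a restart that still degenerates is discarded.
#'
#' @param x Numeric matrix, points x channels (topographies as rows).
#' @param k Number of mixture components (>= 1; needs `nrow(x) >= 10 * k`).
#' @param seed Integer seed (fits are deterministic given the seed).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param restarts Number of random initializations.
#' @param var_floor Lower clamp on per-dimension variances.
#' @return A list of class `gmm_model`: `weights`, `means` (k x channels
#'   template maps), `vars` (k x channels), `loglik`, `loglik_trace`,
#'   `iterations`, `k`.
#' @export
fit_gmm <- function(x, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                    restarts = 3L, var_floor = 1e-8) {
  stopifnot(is.matrix(x), k >= 1L)
  n <- nrow(x)
  if (n < 10L * k)
    stop("need at least 10*k = ", 10L * k, " points to fit k = ", k,
         " components; got ", n)
  if (k == 1L) {
    mu <- colMeans(x)
    v <- pmax(colMeans(sweep(x, 2, mu)^2), var_floor)  # MLE (1/n) variances
    ll <- sum(dmvnorm_diag_log(x, mu, v))
    return(structure(list(weights = 1, means = matrix(mu, 1),
                          vars = matrix(v, 1), loglik = ll,
                          loglik_trace = ll, iterations = 0L, k = 1L),
                     class = "gmm_model"))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr_seed(child_seed(seed, "gmm", r),
                      em_diag_gmm(x, k, max_iter, tol, var_floor))
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all ", restarts, " GMM restarts degenerated (variance collapse)")
  structure(c(best, list(k = k)), class = "gmm_model")
}

# log density of rows of x under N(mu, diag(v))
dmvnorm_diag_log <- function(x, mu, v) {
  z2 <- sweep(sweep(x, 2, mu), 2, sqrt(v), "/")^2
  -0.5 * (rowSums(z2) + sum(log(2 * pi * v)))
}

em_diag_gmm <- function(x, k, max_iter, tol, var_floor) {
  n <- nrow(x); d <- ncol(x)
  # k-means++ style seeding
  centers <- matrix(0, k, d)
  centers[1, ] <- x[sample(n, 1L), ]
  for (j in seq_len(k - 1L)) {
    d2 <- Reduce(pmin, lapply(seq_len(j), function(m)
      rowSums(sweep(x, 2, centers[m, ])^2)))
    p <- d2 / sum(d2)
    centers[j + 1L, ] <- x[sample(n, 1L, prob = p), ]
  }
  w <- rep(1 / k, k)
  v <- matrix(rep(pmax(apply(x, 2, stats::var), var_floor), each = k), k,
              byrow = FALSE)
  mu <- centers
  ll_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    logd <- sapply(seq_len(k), function(j)
      log(w[j]) + dmvnorm_diag_log(x, mu[j, ], v[j, ]))   # n x k
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)                                # n x k
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)                      # empty component
    w <- nk / n
    mu <- crossprod(resp, x) / nk
    for (j in seq_len(k)) {
      diff2 <- sweep(x, 2, mu[j, ])^2
      v[j, ] <- pmax(colSums(resp[, j] * diff2) / nk[j], var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = w, means = mu, vars = v, loglik = ll,
       loglik_trace = trace, iterations = it)
}

# log mixture density of rows of x under a gmm_model
gmm_logdens <- function(model, x) {
  k <- model$k
  logd <- sapply(seq_len(k), function(j)
    log(model$weights[j]) +
      dmvnorm_diag_log(x, model$means[j, ], model$vars[j, ]))
  if (k == 1L) return(as.numeric(logd))
  m <- apply(logd, 1, max)
  m + log(rowSums(exp(logd - m)))
}

#' Per-trial log-likelihood-ratio decision score
#'
#' Score of one or more trials: the sum over unmasked time-points in the
#' window of `log p(topography | deviant model) - log p(topography | standard
#' model)`. Higher means more deviant-like. Swapping the two models negates
#' the score.
#'
#' @param epochs A GFP-normalized epoch set (`eeg_epochs_norm`).
#' @param model_dev,model_std Fitted `gmm_model`s for the two conditions.
#' @param window Length-2 numeric, scoring window in seconds (half-open).
#' @return Numeric vector of scores, one per trial.
#' @export
trial_llr <- function(epochs, model_dev, model_std, window) {
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) stop("scoring window contains no samples")
  llr <- llr_matrix(epochs, model_dev, model_std)
  scores <- rowSums(llr[, sel, drop = FALSE])
  if (any(rowSums(epochs$mask[, sel, drop = FALSE]) == 0))
    stop("a trial has every time-point masked inside the scoring window")
  scores
}

# trials x samples matrix of per-timepoint log-density differences,
# 0 at masked points.
llr_matrix <- function(epochs, model_dev, model_std) {
  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  flat <- matrix(aperm(d, c(1, 3, 2)), n_tr * n_s, n_ch)  # (trial,sample) rows
  ld <- gmm_logdens(model_dev, flat) - gmm_logdens(model_std, flat)
  out <- matrix(ld, n_tr, n_s)
  out[!epochs$mask] <- 0
  out
}

#' STTA configuration
#'
#' @param k_values Candidate numbers of Gaussians per condition model.
#' @param windows List of candidate scoring windows in seconds; `NULL` builds
#'   a grid over the post-onset period `[0, 0.5)` with starts every
#'   `window_step_s` and lengths from `min_length_s` up.
#' @param window_step_s,min_length_s Grid parameters (defaults 0.1 s / 0.1 s;
#'   at the protocol scale a 10 ms grid is available by setting these).
#' @param n_folds Stratified CV folds inside the CV set (default 5).
#' @param restarts,max_iter,tol EM controls passed to [fit_gmm()].
#' @param seed Integer seed for fold assignment and EM restarts.
#' @return A list of class `stta_config`.
#' @export
stta_config <- function(k_values = 1:6, windows = NULL,
                        window_step_s = 0.1, min_length_s = 0.1,
                        n_folds = 5L, restarts = 3L, max_iter = 200L,
                        tol = 1e-6, seed = 1L) {
  stopifnot(all(k_values >= 1L))
  if (is.null(windows)) {
    starts <- seq(0, 0.5 - min_length_s, by = window_step_s)
    windows <- list()
    for (s in starts)
      for (e in seq(s + min_length_s, 0.5, by = window_step_s))
        windows <- c(windows, list(c(s, e)))
  }
  structure(list(k_values = as.integer(k_values), windows = windows,
                 n_folds = as.integer(n_folds), restarts = restarts,
                 max_iter = max_iter, tol = tol, seed = seed),
            class = "stta_config")
}

# Pool unmasked post-onset topographies of the selected trials into a matrix.
pool_topographies <- function(epochs, trials, t_sel) {
  d <- epochs$data[trials, , t_sel, drop = FALSE]
  msk <- epochs$mask[trials, t_sel, drop = FALSE]
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  flat <- matrix(aperm(d, c(1, 3, 2)), n_tr * n_s, n_ch)
  flat[as.vector(msk), , drop = FALSE]
}

# Stratified fold assignment.
make_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  withr_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validate the STTA decoder
#'
#' Grid search over `(k, window)` candidates by stratified k-fold CV inside
#' the CV set. For each fold and each k, one GMM per condition is fitted on
#' the training trials' pooled post-onset topographies; every candidate
#' window is then scored on the held-out fold by the windowed
#' log-likelihood-ratio AUC. The selected candidate maximizes the mean
#' held-out AUC; ties break to the earliest window start, then the shortest
#' window, then the smallest k.
#'
#' @param cv_epochs GFP-normalized CV set.
#' @param config An [stta_config()].
#' @param contrast `"global"` or `"local"`.
#' @return A list: `k`, `window`, `cv_auc`, and `grid` (tibble of all
#'   candidates with mean CV AUC).
#' @export
cross_validate_stta <- function(cv_epochs, config = stta_config(),
                                contrast = "global") {
  y <- contrast_labels(cv_epochs, contrast)
  if (length(config$windows) == 0L || length(config$k_values) == 0L)
    stop("no (k, window) candidates to evaluate")
  if (length(config$windows) == 1L && length(config$k_values) == 1L) {
    return(list(k = config$k_values[1], window = config$windows[[1]],
                cv_auc = NA_real_, grid = NULL))
  }
  fold <- make_folds(y, config$n_folds, child_seed(config$seed, "folds"))
  t_fit <- cv_epochs$times >= 0 & cv_epochs$times < 0.5
  win_sel <- lapply(config$windows, function(w)
    which(cv_epochs$times >= w[1] & cv_epochs$times < w[2]))

  auc_acc <- matrix(0, length(config$k_values), length(config$windows))
  n_folds_used <- 0L
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); va <- which(fold == f)
    if (length(unique(y[va])) < 2L) next
    n_folds_used <- n_folds_used + 1L
    for (ki in seq_along(config$k_values)) {
      k <- config$k_values[ki]
      mdl <- fit_condition_models(cv_epochs, tr, y, t_fit, k, config,
                                  tag = paste0("f", f))
      llr <- llr_matrix(cv_epochs[va], mdl$dev, mdl$std)
      for (wi in seq_along(win_sel)) {
        sc <- rowSums(llr[, win_sel[[wi]], drop = FALSE])
        auc_acc[ki, wi] <- auc_acc[ki, wi] + compute_auc(sc, y[va])
      }
    }
  }
  if (n_folds_used == 0L) stop("no fold contained both classes")
  auc_mean <- auc_acc / n_folds_used

  grid <- tidyr::expand_grid(ki = seq_along(config$k_values),
                             wi = seq_along(config$windows))
  grid$k <- config$k_values[grid$ki]
  grid$window_start <- purrr::map_dbl(config$windows[grid$wi], 1)
  grid$window_end <- purrr::map_dbl(config$windows[grid$wi], 2)
  grid$cv_auc <- auc_mean[cbind(grid$ki, grid$wi)]
  # tie-break: max AUC, earliest start, shortest, smallest k
  ord <- order(-grid$cv_auc, grid$window_start,
               grid$window_end - grid$window_start, grid$k)
  sel <- grid[ord[1L], ]
  list(k = sel$k, window = c(sel$window_start, sel$window_end),
       cv_auc = sel$cv_auc,
       grid = tibble::as_tibble(grid[, c("k", "window_start", "window_end",
                                         "cv_auc")]))
}

fit_condition_models <- function(epochs, trials, y, t_fit, k, config, tag) {
  dev_tr <- trials[y[trials] == "deviant"]
  std_tr <- trials[y[trials] == "standard"]
  list(
    dev = fit_gmm(pool_topographies(epochs, dev_tr, t_fit), k,
                  seed = child_seed(config$seed, tag, "dev", k),
                  max_iter = config$max_iter, tol = config$tol,
                  restarts = config$restarts),
    std = fit_gmm(pool_topographies(epochs, std_tr, t_fit), k,
                  seed = child_seed(config$seed, tag, "std", k),
                  max_iter = config$max_iter, tol = config$tol,
                  restarts = config$restarts)
  )
}

#' Fit STTA on the CV set and score the held-out test set
#'
#' Runs [cross_validate_stta()] on the CV set, refits the two condition
#' models with the selected k on all CV trials, and computes the test AUC
#' from the windowed log-likelihood-ratio scores of the test trials only.
#'
#' @param cv,test Disjoint GFP-normalized epoch sets from [split_cv_test()].
#' @param config An [stta_config()].
#' @param contrast `"global"` or `"local"`.
#' @return A list of class `stta_result`: `decoder = "stta"`, `k`, `window`,
#'   `cv_auc`, `auc` (test AUC), `scores` (test trials), `labels`.
#' @export
decode_test_stta <- function(cv, test, config = stta_config(),
                             contrast = "global") {
  sel <- cross_validate_stta(cv, config, contrast)
  y_cv <- contrast_labels(cv, contrast)
  t_fit <- cv$times >= 0 & cv$times < 0.5
  mdl <- fit_condition_models(cv, seq_along(y_cv), y_cv, t_fit, sel$k,
                              config, tag = "final")
  y_test <- contrast_labels(test, contrast)
  scores <- trial_llr(test, mdl$dev, mdl$std, sel$window)
  structure(list(decoder = "stta", contrast = contrast,
                 k = sel$k, window = sel$window, cv_auc = sel$cv_auc,
                 auc = compute_auc(scores, y_test),
                 scores = scores, labels = y_test,
                 models = mdl, grid = sel$grid),
            class = "stta_result")
}
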