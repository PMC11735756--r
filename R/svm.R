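# SVM decoding: concatenated channel x time feature vectors, per-time-point
# decoding, hyperparameter grid search by stratified CV, and sub-averaging of
# single trials. Model fitting is delegated to e1071::svm; features are
# z-scored with CV-set statistics only.

#' Concatenate epochs into a trial x features matrix
#'
#' Feature order is channel-major: features `1..n_samples` are channel 1's
#' time series, the next `n_samples` channel 2's, and so on, giving
#' `n_channels * n_samples` features per trial. Row order preserves trial
#' order. [features_to_epochs()] inverts the layout.
#'
#' @param epochs An [eeg_epochs].
#' @return Numeric matrix, trials x (channels * samples).
#' @export
build_features_concat <- function(epochs) {
  d <- epochs$data
  if (anyNA(d)) stop("epochs contain NaN/NA; clean before building features")
  n_tr <- dim(d)[1]
  # row tr = as.vector(t(d[tr,,])) = channel-major
  m <- matrix(aperm(d, c(3, 2, 1)), nrow = n_tr, byrow = TRUE)
  m
}

#' @rdname build_features_concat
#' @param features Matrix from [build_features_concat()].
#' @param n_channels,n_samples Original epoch dimensions.
#' @export
features_to_epochs <- function(features, n_channels, n_samples) {
  stopifnot(ncol(features) == n_channels * n_samples)
  arr <- array(0, dim = c(nrow(features), n_channels, n_samples))
  for (tr in seq_len(nrow(features)))
    arr[tr, , ] <- matrix(features[tr, ], n_channels, n_samples, byrow = TRUE)
  arr
}

#' SVM decoder configuration
#'
#' @param kernels Kernels to search (`"linear"`, `"radial"`).
#' @param cost C grid (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param gamma Radial-width grid; `NULL` uses `1/(d * var(features))` plus
#'   `c(0.01, 0.1, 1)` at fit time. Ignored for the linear kernel.
#' @param n_folds Stratified CV folds (default 5).
#' @param standardize Z-score features with CV-set statistics (default TRUE).
#' @param class_weights Inverse-frequency class weights (default TRUE),
#'   guarding against trivial majority solutions at the paradigm's 5:1
#'   imbalance.
#' @param seed Integer seed for fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernels = c("linear", "radial"),
                       cost = c(0.01, 0.1, 1, 10, 100),
                       gamma = NULL, n_folds = 5L, standardize = TRUE,
                       class_weights = TRUE, seed = 1L) {
  stopifnot(all(kernels %in% c("linear", "radial")), all(cost > 0))
  if (!is.null(gamma)) stopifnot(all(gamma > 0))
  structure(list(kernels = kernels, cost = cost, gamma = gamma,
                 n_folds = as.integer(n_folds), standardize = standardize,
                 class_weights = class_weights, seed = seed),
            class = "svm_config")
}

svm_grid <- function(config, features) {
  gamma <- config$gamma %||% unique(c(1 / (ncol(features) *
                                             max(stats::var(as.vector(features)),
                                                 1e-12)),
                                      0.01, 0.1, 1))
  g <- list()
  for (kn in config$kernels) {
    if (kn == "linear") {
      for (C in config$cost) g <- c(g, list(list(kernel = kn, cost = C,
                                                 gamma = NA_real_)))
    } else {
      for (C in config$cost) for (gm in gamma)
        g <- c(g, list(list(kernel = kn, cost = C, gamma = gm)))
    }
  }
  g
}

# Fit an SVM and return decision scores oriented so higher = deviant.
svm_scores <- function(x_train, y_train, x_new, kernel, cost, gamma,
                       class_weights) {
  cw <- if (class_weights) {
    tab <- table(y_train)
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else NULL
  args <- list(x = x_train, y = y_train, kernel = kernel, cost = cost,
               scale = FALSE, probability = FALSE)
  if (kernel == "radial") args$gamma <- gamma
  if (!is.null(cw)) args$class.weights <- cw
  fit <- do.call(e1071::svm, args)
  dv <- attr(stats::predict(fit, x_new, decision.values = TRUE),
             "decision.values")
  sc <- as.numeric(dv[, 1])
  # e1071 orients the decision value toward the first label it encountered
  pos <- sub("/.*", "", colnames(dv)[1])
  if (pos == "deviant") sc else -sc
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(apply = function(m) sweep(sweep(m, 2, mu), 2, sd, "/"))
}

#' Select SVM hyperparameters by cross-validation
#'
#' Grid search over kernel, C (and gamma for the radial kernel) maximizing
#' the mean held-out-fold AUC of decision-function margins. Standardization
#' statistics are computed on each fold's training split only.
#'
#' @param cv GFP-normalized or raw [eeg_epochs] CV set.
#' @param config An [svm_config()].
#' @param contrast `"global"` or `"local"`.
#' @return A list: `kernel`, `cost`, `gamma`, `cv_auc`, `grid` (tibble).
#' @export
cv_select_svm <- function(cv, config = svm_config(), contrast = "global") {
  y <- contrast_labels(cv, contrast)
  x <- build_features_concat(cv)
  grid <- svm_grid(config, x)
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  if (length(grid) == 1L) {
    g <- grid[[1]]
    return(list(kernel = g$kernel, cost = g$cost, gamma = g$gamma,
                cv_auc = NA_real_, grid = NULL))
  }
  fold <- make_folds(y, config$n_folds, child_seed(config$seed, "svmfolds"))
  aucs <- matrix(0, length(grid), 0)
  acc <- numeric(length(grid)); used <- 0L
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); va <- which(fold == f)
    if (length(unique(y[va])) < 2L) next
    used <- used + 1L
    xs <- x
    if (config$standardize) {
      st <- standardizer(x[tr, , drop = FALSE])
      xs <- st$apply(x)
    }
    for (gi in seq_along(grid)) {
      g <- grid[[gi]]
      sc <- svm_scores(xs[tr, , drop = FALSE], y[tr], xs[va, , drop = FALSE],
                       g$kernel, g$cost, g$gamma, config$class_weights)
      acc[gi] <- acc[gi] + compute_auc(sc, y[va])
    }
  }
  if (used == 0L) stop("no fold contained both classes")
  cv_auc <- acc / used
  gt <- tibble::tibble(
    kernel = purrr::map_chr(grid, "kernel"),
    cost = purrr::map_dbl(grid, "cost"),
    gamma = purrr::map_dbl(grid, "gamma"),
    cv_auc = cv_auc
  )
  best <- which.max(cv_auc)
  g <- grid[[best]]
  list(kernel = g$kernel, cost = g$cost, gamma = g$gamma,
       cv_auc = cv_auc[best], grid = gt)
}

#' Fit the selected SVM on the CV set and score the test set
#'
#' Refits on all CV trials with the selected hyperparameters and computes the
#' test AUC from signed margins of test trials. Standardization uses CV-set
#' statistics applied unchanged to the test set.
#'
#' @param cv,test Disjoint epoch sets from [split_cv_test()].
#' @param config An [svm_config()].
#' @param contrast `"global"` or `"local"`.
#' @param selection Optional result of [cv_select_svm()]; computed if `NULL`.
#' @return A list of class `svm_result`: `decoder = "svm_concat"`, selected
#'   hyperparameters, `cv_auc`, `auc`, `scores`, `labels`.
#' @export
decode_test_svm <- function(cv, test, config = svm_config(),
                            contrast = "global", selection = NULL) {
  sel <- selection %||% cv_select_svm(cv, config, contrast)
  y_cv <- contrast_labels(cv, contrast)
  y_test <- contrast_labels(test, contrast)
  x_cv <- build_features_concat(cv)
  x_test <- build_features_concat(test)
  if (config$standardize) {
    st <- standardizer(x_cv)
    x_cv <- st$apply(x_cv); x_test <- st$apply(x_test)
  }
  scores <- svm_scores(x_cv, y_cv, x_test, sel$kernel, sel$cost, sel$gamma,
                       config$class_weights)
  structure(list(decoder = "svm_concat", contrast = contrast,
                 kernel = sel$kernel, cost = sel$cost, gamma = sel$gamma,
                 cv_auc = sel$cv_auc, auc = compute_auc(scores, y_test),
                 scores = scores, labels = y_test, grid = sel$grid),
            class = "svm_result")
}

#' Time-resolved decoding: one classifier per time-point
#'
#' Fits an independent SVM on the channel vector at each sample (CV trials)
#' and scores the test trials, returning an AUC time-course. Latencies
#' carrying a planted or physiological effect show elevated AUC; baseline
#' samples stay near 0.5.
#'
#' @param cv,test Disjoint epoch sets.
#' @param config An [svm_config()]; the grid is not searched per time-point —
#'   the first kernel and cost (and gamma) are used throughout, since a full
#'   search at every sample would be disproportionate.
#' @param contrast `"global"` or `"local"`.
#' @return A tibble of class `timepoint_auc`: `time`, `auc`.
#' @export
timepoint_decode <- function(cv, test, config = svm_config(kernels = "linear",
                                                           cost = 1),
                             contrast = "global") {
  y_cv <- contrast_labels(cv, contrast)
  y_test <- contrast_labels(test, contrast)
  g <- svm_grid(config, matrix(cv$data, nrow = dim(cv$data)[1]))[[1]]
  auc <- purrr::map_dbl(seq_along(cv$times), function(si) {
    x_cv <- cv$data[, , si]
    x_test <- test$data[, , si, drop = TRUE]
    if (config$standardize) {
      st <- standardizer(x_cv)
      x_cv <- st$apply(x_cv); x_test <- st$apply(x_test)
    }
    sc <- svm_scores(x_cv, y_cv, x_test, g$kernel, g$cost, g$gamma,
                     config$class_weights)
    compute_auc(sc, y_test)
  })
  structure(tibble::tibble(time = cv$times, auc = auc),
            class = c("timepoint_auc", class(tibble::tibble())))
}

#' Sub-average single trials into pseudo-trials
#'
#' Within each class (on both label dimensions jointly), trials are randomly
#' partitioned into non-overlapping groups of `group_size` (2 or 3) and
#' averaged; leftover trials are discarded. Pseudo-trial counts are
#' `floor(n_class / group_size)` per class; labels are preserved.
#'
#' @param epochs An [eeg_epochs].
#' @param group_size 2 or 3.
#' @param seed Integer seed for the random grouping.
#' @return An [eeg_epochs] of pseudo-trials.
#' @export
subaverage <- function(epochs, group_size = 2L, seed = 1L) {
  stopifnot(group_size %in% c(2L, 3L))
  cls <- interaction(epochs$labels$global, epochs$labels$local, drop = TRUE)
  if (any(table(cls) < group_size))
    stop("a class has fewer than ", group_size, " trials")
  groups <- withr_seed(seed, {
    out <- list()
    for (lv in levels(cls)) {
      idx <- sample(which(cls == lv))
      n_keep <- (length(idx) %/% group_size) * group_size
      idx <- idx[seq_len(n_keep)]
      out <- c(out, split(idx, rep(seq_len(n_keep / group_size),
                                   each = group_size)))
    }
    out
  })
  d <- epochs$data
  new_data <- array(0, dim = c(length(groups), dim(d)[2], dim(d)[3]))
  for (j in seq_along(groups))
    new_data[j, , ] <- apply(d[groups[[j]], , , drop = FALSE], c(2, 3), mean)
  first <- purrr::map_int(groups, 1)
  out <- epochs
  out$data <- new_data
  out$labels <- epochs$labels[first, , drop = FALSE]
  out$gfp <- NULL; out$mask <- NULL
  class(out) <- "eeg_epochs"
  out$log <- c(out$log, sprintf("sub-averaged in groups of %d: %d pseudo-trials",
                                group_size, length(groups)))
  out
}
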