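# Feature construction, SVM hyperparameter selection, time-resolved decoding,
# sub-averaging.

test_that("feature concatenation is channel-major and invertible", {
  d <- array(0, dim = c(2, 2, 3))
  d[1, 1, ] <- c(1, 2, 3); d[1, 2, ] <- c(4, 5, 6)
  d[2, 1, ] <- c(7, 8, 9); d[2, 2, ] <- c(10, 11, 12)
  ep <- eeg_epochs(d, times = c(0, 0.1, 0.2), sfreq = 10,
                   labels = tibble::tibble(global = c("standard", "deviant"),
                                           local = c("standard", "standard")))
  x <- build_features_concat(ep)
  expect_equal(x[1, ], c(1, 2, 3, 4, 5, 6))
  expect_equal(x[2, ], c(7, 8, 9, 10, 11, 12))
  expect_equal(features_to_epochs(x, 2, 3), d)

  ep$data[1, 1, 1] <- NA
  expect_error(build_features_concat(ep), "NaN")

  big <- fx_recording()
  xb <- build_features_concat(big)
  expect_equal(dim(xb), c(144, 16 * 60))
})

test_that("grid search finds a separating classifier on separable data", {
  set.seed(81)
  n <- 60
  d <- array(rnorm(2 * n * 4 * 5, sd = 0.1), dim = c(2 * n, 4, 5))
  d[(n + 1):(2 * n), 1, ] <- d[(n + 1):(2 * n), 1, ] + 3  # shifted class
  ep <- eeg_epochs(d, times = seq(0, 0.4, 0.1), sfreq = 10,
                   labels = tibble::tibble(
                     global = rep(c("standard", "deviant"), each = n),
                     local = "standard"))
  sel <- cv_select_svm(ep, svm_config(n_folds = 3, seed = 1))
  expect_gt(sel$cv_auc, 0.99)
  expect_true(sel$kernel %in% c("linear", "radial"))
  expect_s3_class(sel$grid, "tbl_df")

  one <- cv_select_svm(ep, svm_config(kernels = "linear", cost = 1))
  expect_equal(one$cost, 1)
  expect_true(is.na(one$cv_auc))  # single candidate: no selection freedom
})

test_that("test decoding is accurate at high SNR and flips under label inversion", {
  ep <- baseline_correct(fx_recording(amp = 3))
  sp <- split_cv_test(ep, seed = 4)
  res <- decode_test_svm(sp$cv, sp$test, fast_svm())
  expect_gt(res$auc, 0.9)

  # the same margins scored against inverted labels complement the AUC
  y_test <- sp$test$labels$global
  swapped <- ifelse(y_test == "deviant", "standard", "deviant")
  expect_equal(compute_auc(res$scores, swapped), 1 - res$auc,
               tolerance = 1e-12)
})

test_that("time-resolved decoding localizes the planted effect", {
  ep <- baseline_correct(fx_recording(amp = 3))
  sp <- split_cv_test(ep, seed = 4)
  tc <- timepoint_decode(sp$cv, sp$test)
  expect_s3_class(tc, "timepoint_auc")
  expect_equal(nrow(tc), 60)
  peak_t <- tc$time[which.max(tc$auc)]
  expect_gte(peak_t, 0.3)
  expect_lt(peak_t, 0.5)
  # baseline samples carry no information
  expect_lt(abs(mean(tc$auc[tc$time < 0]) - 0.5), 0.15)
})

test_that("sub-averaging conserves counts, preserves labels and raises SNR", {
  ep10 <- fx_labeled_epochs(10, 10)
  sa <- subaverage(ep10, group_size = 3, seed = 1)
  expect_equal(as.vector(table(sa$labels$global)), c(3, 3))  # 1 discarded each

  ep <- fx_recording(amp = 1.2, seed = 55)
  sa2 <- subaverage(ep, group_size = 2, seed = 2)
  # counts: groups within (global x local) classes, floor(n/2) each
  cls <- interaction(ep$labels$global, ep$labels$local)
  expect_equal(nrow(sa2$labels), sum(table(cls) %/% 2))
  expect_equal(as.vector(table(sa2$labels$global)),
               as.vector(table(ep$labels$global) %/% 2))

  expect_error(subaverage(fx_labeled_epochs(5, 1), group_size = 2), "fewer")

  # paired over seeds, pseudo-trials decode better than single trials
  diff <- sapply(1:6, function(s) {
    e <- simulate_recording(fx_schedule(), fx_head(),
                            effects = list(effect_spec("global", 1.2)),
                            noise_sd = 1, sfreq = 100, seed = 400 + s)
    e <- baseline_correct(e)
    cfg <- svm_config(kernels = "linear", cost = 1)
    single <- decode_test_svm(split_cv_test(e, seed = s)$cv,
                              split_cv_test(e, seed = s)$test, cfg)$auc
    sa <- subaverage(e, 2, seed = s)
    sub <- decode_test_svm(split_cv_test(sa, seed = s)$cv,
                           split_cv_test(sa, seed = s)$test, cfg)$auc
    sub - single
  })
  expect_gt(mean(diff), 0)
})

test_that("standardization statistics come from the training data only", {
  set.seed(91)
  x_tr <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4)
  st <- localglobal:::standardizer(x_tr)
  z <- st$apply(x_tr)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12)
  x_te <- matrix(rnorm(40, mean = 50), 10, 4)
  z_te <- st$apply(x_te)
  # test data standardized with training stats keeps its shift
  expect_gt(min(colMeans(z_te)), 10)
})
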