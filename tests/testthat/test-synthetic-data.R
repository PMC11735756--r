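# Synthetic EEG generator and synthetic cohorts.

test_that("head model topographies are average-referenced and unit-norm", {
  hm <- head_model(n_channels = 24, n_components = 3, seed = 9)
  expect_equal(dim(hm$topographies), c(24, 3))
  expect_equal(colMeans(hm$topographies), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(hm$topographies^2), rep(1, 3), tolerance = 1e-12)
  r <- with(hm$positions, sqrt(x^2 + y^2 + z^2))
  expect_equal(r, rep(1, 24), tolerance = 1e-9)
  expect_error(head_model(n_channels = 1), ">= 2")
})

test_that("epoch geometry follows the sampling rate", {
  sched <- build_session(2, n_standard = 9, n_deviant = 3, n_blocks = 4)
  hm <- head_model(8, seed = 1)
  ep <- simulate_recording(sched, hm, sfreq = 1200, seed = 4)
  expect_equal(dim(ep$data)[3], 720)  # 0.6 s x 1200 Hz
  expect_equal(min(ep$times), -0.1)
  expect_lt(max(ep$times), 0.5)
  ep2 <- simulate_recording(sched, hm, sfreq = 100, seed = 4)
  expect_equal(dim(ep2$data)[3], 60)
  expect_error(
    simulate_recording(sched, hm, sfreq = 1, seed = 4),
    "inconsistent")
})

test_that("the generator is deterministic and adds effects only where labelled", {
  sched <- fx_schedule()
  hm <- fx_head()
  base <- simulate_recording(sched, hm, effects = list(), noise_sd = 1,
                             sfreq = 100, seed = 13)
  again <- simulate_recording(sched, hm, effects = list(), noise_sd = 1,
                              sfreq = 100, seed = 13)
  expect_identical(base$data, again$data)

  amp <- 2.5
  eff <- effect_spec("global", amplitude = amp)
  with_eff <- simulate_recording(sched, hm, effects = list(eff), noise_sd = 1,
                                 sfreq = 100, seed = 13)
  is_dev <- base$labels$global == "deviant"
  # standards untouched
  expect_identical(with_eff$data[!is_dev, , ], base$data[!is_dev, , ])
  # deviants receive exactly amplitude x topography x half-cosine bump
  diff <- with_eff$data[which(is_dev)[1], , ] - base$data[which(is_dev)[1], , ]
  inside <- base$times * 1000 >= 300 & base$times * 1000 < 500
  expect_equal(max(abs(diff[, !inside])), 0)
  u <- (base$times[inside] * 1000 - 300) / 200
  expected <- outer(hm$topographies[, 2], amp * sin(pi * u))
  expect_equal(diff[, inside], expected, tolerance = 1e-12)
  # a local effect keys on the local label instead
  with_loc <- simulate_recording(sched, hm,
                                 effects = list(effect_spec("local", amplitude = 1)),
                                 noise_sd = 1, sfreq = 100, seed = 13)
  is_ldev <- base$labels$local == "deviant"
  expect_identical(with_loc$data[!is_ldev, , ], base$data[!is_ldev, , ])
  expect_gt(max(abs(with_loc$data[is_ldev, , ] - base$data[is_ldev, , ])), 0)
})

test_that("an effect window outside the epoch errors", {
  sched <- fx_schedule()
  expect_error(
    simulate_recording(sched, fx_head(),
                       effects = list(effect_spec("global", 1,
                                                  window_ms = c(900, 1000))),
                       sfreq = 100, seed = 1),
    "outside the epoch")
})

test_that("test AUC is monotone in the planted global amplitude", {
  cfg <- null_stta()
  mean_auc <- sapply(c(0.5, 4), function(amp) {
    mean(sapply(1:3, function(s) {
      ep <- simulate_recording(fx_schedule(), fx_head(),
                               effects = list(effect_spec("global", amp)),
                               noise_sd = 1, sfreq = 100, seed = 20 + s)
      nm <- gfp_normalize(baseline_correct(ep))
      sp <- split_cv_test(nm, seed = s)
      decode_test_stta(sp$cv, sp$test, cfg)$auc
    }))
  })
  expect_gt(mean_auc[2], mean_auc[1])
  expect_gt(mean_auc[2], 0.8)
})

test_that("cohort simulation links covariates as configured", {
  co <- simulate_cohort(n_patients = 40, slope_four = 0.2, seed = 21)
  expect_s3_class(co$table, "cohort_table")
  expect_equal(nrow(co$table), 40)
  expect_true(all(co$table$four >= 0 & co$table$four <= 16))
  expect_true(all(co$table$cpc %in% 1:5))
  expect_identical(co$table$outcome == "favourable", co$table$cpc <= 2)
  expect_gt(cor(co$table$amplitude, co$table$four), 0)

  null_co <- simulate_cohort(n_patients = 40, slope_four = 0, seed = 22)
  ct <- cor.test(null_co$table$amplitude, null_co$table$four)
  expect_gt(ct$p.value, 0.01)

  expect_identical(simulate_cohort(n_patients = 10, seed = 5)$table,
                   simulate_cohort(n_patients = 10, seed = 5)$table)
  expect_error(simulate_cohort(n_patients = 1), ">= 2")
})

test_that("cohort simulation can emit scaled recordings consistent with the table", {
  co <- simulate_cohort(n_patients = 2, simulate_epochs = TRUE, seed = 30,
                        recording_args = list(n_channels = 8, n_blocks = 4))
  expect_length(co$recordings, 2)
  expect_s3_class(co$recordings[[1]], "eeg_epochs")
  expect_equal(dim(co$recordings[[1]]$data)[2], 8)
  expect_true(all(is.na(co$table$auc)))
})
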