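# Filtering, epoching, artifact rejection, GFP normalization, splitting.

test_that("band-pass removes DC, keeps the mid-band, attenuates out-of-band", {
  sf <- 500
  t <- seq(0, 10, by = 1 / sf)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))

  const <- bandpass(rep(5, length(t)), 0.1, 40, sfreq = sf)
  expect_lt(abs(mean(const[mid])), 0.05)

  f10 <- bandpass(sin(2 * pi * 10 * t), 0.1, 40, sfreq = sf)
  expect_equal(max(abs(f10[mid])), 1, tolerance = 0.05)

  f60 <- bandpass(sin(2 * pi * 60 * t), 0.1, 40, sfreq = sf)
  expect_lt(max(abs(f60[mid])), 0.1)  # >= 90% attenuation

  expect_error(bandpass(rnorm(100), 40, 0.1, sfreq = sf), "invalid band")
  expect_error(bandpass(rnorm(100), 0.1, 300, sfreq = sf), "invalid band")
})

test_that("band-pass stays stable at the acquisition rate and filters epochs in place", {
  t <- seq(0, 3, by = 1 / 1200)
  y <- bandpass(sin(2 * pi * 10 * t), 0.1, 40, sfreq = 1200)
  expect_true(all(is.finite(y)))
  expect_equal(max(abs(y[1000:2600])), 1, tolerance = 0.05)

  ep <- fx_recording()
  f <- bandpass(ep, 0.1, 40)
  expect_s3_class(f, "eeg_epochs")
  expect_equal(dim(f$data), dim(ep$data))
  expect_match(tail(f$log, 1), "bandpass")
})

test_that("epoch extraction is index-exact with the documented sample counts", {
  sf <- 1200
  cont <- matrix(rnorm(2 * 6 * sf), nrow = 2)  # 2 channels, 6 s
  onsets <- c(1.0, 2.5, 4.0)
  labels <- tibble::tibble(global = c("standard", "deviant", "standard"),
                           local = rep("standard", 3))
  ep <- extract_epochs(cont, sf, onsets, labels)
  expect_equal(dim(ep$data), c(3, 2, 720))
  # bit-for-bit reconstruction from the continuous array
  s0 <- round(1.0 * sf) + round(-0.1 * sf) + 1
  expect_identical(ep$data[1, , ], cont[, s0:(s0 + 719)])

  ep500 <- extract_epochs(matrix(rnorm(2 * 6 * 500), 2), 500, onsets, labels)
  expect_equal(dim(ep500$data)[3], 300)

  # event too close to the start is dropped and counted
  expect_warning(
    ep_edge <- extract_epochs(cont, sf, c(0.05, 2.5), labels[1:2, ]),
    "dropped")
  expect_equal(dim(ep_edge$data)[1], 1)
  expect_equal(attr(ep_edge, "n_dropped"), 1)
})

test_that("artifact rejection flags planted defects and keeps counts conserved", {
  ep <- fx_recording(amp = 0, seed = 41, noise_sd = 1)

  clean <- reject_and_interpolate(ep, amp_thresh = 100)
  expect_equal(clean$report$n_dropped, 0)
  expect_equal(clean$report$n_retained, nrow(ep$labels))
  expect_length(clean$report$bad_channels[[1]], 0)

  # one globally noisy channel -> interpolated, no epochs lost
  bad <- ep
  bad$data[, 3, ] <- bad$data[, 3, ] * 100
  fixed <- reject_and_interpolate(bad, amp_thresh = 100)
  expect_identical(fixed$report$bad_channels[[1]], ep$channels$name[3])
  expect_equal(fixed$report$n_dropped, 0)
  expect_lt(max(abs(fixed$epochs$data[, 3, ])), 100)

  # one spiking epoch -> exactly that epoch dropped
  spike <- ep
  spike$data[17, 5, 10] <- 500
  cleaned <- reject_and_interpolate(spike, amp_thresh = 100)
  expect_equal(cleaned$report$n_dropped, 1)
  expect_equal(cleaned$report$n_retained + cleaned$report$n_dropped,
               cleaned$report$n_input)
  expect_identical(cleaned$epochs$labels,
                   spike$labels[-17, ])

  # everything rejected -> advisory error
  expect_error(reject_and_interpolate(ep, amp_thresh = 1e-6,
                                      bad_channel_frac = 2),
               "threshold")
})

test_that("GFP normalization yields unit-GFP topographies and masks degenerate points", {
  # hand-checkable 2-channel cases packed as 1 trial x 2 channels x 3 samples
  d <- array(0, dim = c(1, 2, 3))
  d[1, , 1] <- c(1, -1)   # already average-referenced, GFP 1
  d[1, , 2] <- c(2, 0)    # -> (1, -1)
  d[1, , 3] <- c(5, 5)    # flat -> masked
  ep <- eeg_epochs(d, times = c(0, 0.1, 0.2), sfreq = 10,
                   labels = tibble::tibble(global = "standard",
                                           local = "standard"))
  nm <- gfp_normalize(ep)
  expect_equal(nm$data[1, , 1], c(1, -1))
  expect_equal(nm$data[1, , 2], c(1, -1))
  expect_false(nm$mask[1, 3])
  expect_true(all(nm$mask[1, 1:2]))
  expect_equal(nm$gfp[1, 1:2], c(1, 1))

  # property: every unmasked topography has GFP 1 +- 1e-9
  big <- gfp_normalize(fx_recording())
  gfp_after <- sqrt(apply(big$data^2, c(1, 3), mean))
  expect_lt(max(abs(gfp_after[big$mask] - 1)), 1e-9)

  one_ch <- eeg_epochs(array(1, c(1, 1, 2)), c(0, 0.1), 10,
                       tibble::tibble(global = "standard", local = "standard"))
  expect_error(gfp_normalize(one_ch), ">= 2 channels")
})

test_that("baseline correction zeroes the pre-stimulus mean per trial and channel", {
  ep <- fx_recording(amp = 0, seed = 44)
  bc <- baseline_correct(ep)
  sel <- bc$times >= -0.1 & bc$times < 0
  bl <- apply(bc$data[, , sel], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-12)
})

test_that("the CV/test split is stratified, disjoint and deterministic", {
  ep <- fx_labeled_epochs(800, 160)
  sp <- split_cv_test(ep, seed = 10)
  expect_equal(sum(sp$test$labels$global == "standard"), 160)
  expect_equal(sum(sp$test$labels$global == "deviant"), 32)
  expect_equal(nrow(sp$cv$labels) + nrow(sp$test$labels), 960)

  small <- fx_labeled_epochs(10, 10)
  sp2 <- split_cv_test(small, seed = 1)
  expect_equal(as.vector(table(sp2$test$labels$global)), c(2, 2))

  sp3 <- split_cv_test(ep, seed = 10)
  expect_identical(sp$test$data, sp3$test$data)

  expect_error(split_cv_test(fx_labeled_epochs(20, 4), seed = 1),
               "at least 5")
})
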