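# Synthetic multichannel EEG epochs and synthetic clinical cohorts.
#
# The generator emulates the study conditions of the registered protocol:
# 63-channel epochs at 1200 Hz, -100..500 ms around the fifth-tone onset, a
# late (>= 300 ms) global-effect topography and an earlier local-effect
# topography, spatially correlated AR(1)-smoothed Gaussian noise, and cohort
# covariates (FOUR, CPC, sedative infusion rates) with configurable links to
# the per-patient effect amplitude.

#' Spherical head model with component topographies
#'
#' Channel positions are laid out on a unit sphere (Fibonacci lattice,
#' upper-biased like an EEG montage). Each component topography is a smooth
#' random channel pattern (a mixture of a few spatial Gaussians on the
#' sphere), average-referenced (zero channel mean) and unit-norm.
#'
#' @param n_channels Number of channels (default 63).
#' @param n_components Number of ERP component topographies (default 2:
#'   one local, one global).
#' @param seed Integer seed.
#' @return A list of class `head_model`: `positions` (n_channels x 3 tibble
#'   with `name`, `x`, `y`, `z`) and `topographies` (n_channels x
#'   n_components matrix).
#' @export
head_model <- function(n_channels = 63L, n_components = 2L, seed = 1L) {
  stopifnot(n_channels >= 2L, n_components >= 1L)
  i <- seq_len(n_channels) - 0.5
  phi <- acos(1 - i / n_channels)          # upper hemisphere bias
  theta <- pi * (1 + sqrt(5)) * i
  pos <- cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta),
               z = cos(phi))
  topo <- withr_seed(seed, {
    sapply(seq_len(n_components), function(k) {
      centers <- sample(n_channels, 3L)
      w <- stats::rnorm(3L)
      v <- rowSums(sapply(seq_along(centers), function(j) {
        d2 <- rowSums((pos - matrix(pos[centers[j], ], n_channels, 3,
                                    byrow = TRUE))^2)
        w[j] * exp(-d2 / 0.5)
      }))
      v <- v - mean(v)
      v / sqrt(sum(v^2))
    })
  })
  structure(list(
    positions = tibble::tibble(name = sprintf("E%02d", seq_len(n_channels)),
                               x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    topographies = topo
  ), class = "head_model")
}

#' Effect specification for the simulator
#'
#' @param component `"local"` or `"global"`; picks the default latency window
#'   (local 100-250 ms, global 300-500 ms after fifth-tone onset) and the
#'   head-model topography used, and decides which label dimension the effect
#'   keys on.
#' @param amplitude Peak amplitude in microvolts (>= 0).
#' @param window_ms Length-2 latency window in ms; `NULL` uses the component
#'   default.
#' @param topography_index Column of the head model's topography matrix;
#'   defaults to 1 for local, 2 for global.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(component = c("global", "local"), amplitude,
                        window_ms = NULL, topography_index = NULL) {
  component <- match.arg(component)
  stopifnot(amplitude >= 0)
  if (is.null(window_ms))
    window_ms <- if (component == "global") c(300, 500) else c(100, 250)
  if (is.null(topography_index))
    topography_index <- if (component == "global") 2L else 1L
  structure(list(component = component, amplitude = amplitude,
                 window_ms = window_ms, topography_index = topography_index),
            class = "effect_spec")
}

#' Simulate one EEG recording as an epoch set
#'
#' Produces one epoch per series of the schedule, shape
#' `(n_series, n_channels, n_samples)`. Noise is Gaussian white noise mixed by
#' a full-rank channel matrix (spatial correlation) and AR(1)-smoothed in time.
#' Each effect adds `amplitude x topography x half-cosine bump` inside its
#' latency window to the epochs whose label on the matching dimension is
#' `"deviant"` (global effects key on the global label, local effects on the
#' local label).
#'
#' @param schedule A `stimulus_schedule` (only labels/ordering are used; epochs
#'   are generated directly in epoch time).
#' @param head A `head_model`.
#' @param effects List of `effect_spec`s.
#' @param noise_sd Noise standard deviation before mixing, microvolts (> 0).
#' @param spatial_mixing Channel x channel mixing matrix; `NULL` draws a random
#'   full-rank matrix close to identity (I + 0.3 G, G gaussian).
#' @param ar_coef AR(1) temporal smoothing coefficient in [0, 1).
#' @param sfreq Sampling rate, Hz (default 1200).
#' @param epoch_window_ms Half-open epoch window around the fifth-tone onset,
#'   ms (default c(-100, 500)).
#' @param seed Integer seed; identical params + seed give identical arrays.
#' @return An [eeg_epochs] object.
#' @examples
#' sched <- build_session(1, n_standard = 15, n_deviant = 3, n_blocks = 4)
#' hm <- head_model(n_channels = 8, seed = 2)
#' ep <- simulate_recording(sched, hm,
#'   effects = list(effect_spec("global", amplitude = 4)),
#'   noise_sd = 1, sfreq = 100, seed = 3)
#' dim(ep$data)
#' @export
simulate_recording <- function(schedule, head,
                               effects = list(),
                               noise_sd = 1,
                               spatial_mixing = NULL,
                               ar_coef = 0.3,
                               sfreq = 1200,
                               epoch_window_ms = c(-100, 500),
                               seed = 1L) {
  stopifnot(noise_sd > 0, ar_coef >= 0, ar_coef < 1)
  n_ch <- nrow(head$positions)
  n_samp <- round(diff(epoch_window_ms) / 1000 * sfreq)
  if (n_samp < 2L)
    stop("epoch window ", paste(epoch_window_ms, collapse = ".."),
         " ms is inconsistent with sfreq = ", sfreq, " Hz")
  times <- epoch_window_ms[1] / 1000 + (seq_len(n_samp) - 1L) / sfreq
  n_trials <- nrow(schedule)

  labs <- label_series(schedule)

  data <- withr_seed(seed, {
    mix <- spatial_mixing %||%
      (diag(n_ch) + 0.3 * matrix(stats::rnorm(n_ch^2), n_ch) / sqrt(n_ch))
    arr <- array(0, dim = c(n_trials, n_ch, n_samp))
    innov_sd <- noise_sd * sqrt(1 - ar_coef^2)  # stationary variance noise_sd^2
    for (tr in seq_len(n_trials)) {
      w <- matrix(stats::rnorm(n_ch * n_samp, sd = noise_sd), n_ch, n_samp)
      if (ar_coef > 0) {
        w[, 1] <- w[, 1]
        for (s in 2:n_samp)
          w[, s] <- ar_coef * w[, s - 1] + (innov_sd / noise_sd) * w[, s]
      }
      arr[tr, , ] <- mix %*% w
    }
    arr
  })

  for (ef in effects) {
    if (ef$amplitude == 0) next
    key <- if (ef$component == "global") labs$global_label else labs$local_label
    idx <- which(key == "deviant")
    inside <- times * 1000 >= ef$window_ms[1] & times * 1000 < ef$window_ms[2]
    if (!any(inside))
      stop("effect window ", paste(ef$window_ms, collapse = ".."),
           " ms lies outside the epoch")
    bump <- numeric(n_samp)
    u <- (times[inside] * 1000 - ef$window_ms[1]) / diff(ef$window_ms)
    bump[inside] <- sin(pi * u)             # half-cosine (raised half-sine) ramp
    pattern <- outer(head$topographies[, ef$topography_index],
                     ef$amplitude * bump)   # channels x samples
    for (tr in idx) data[tr, , ] <- data[tr, , ] + pattern
  }

  eeg_epochs(data = data, times = times, sfreq = sfreq,
             labels = tibble::tibble(global = labs$global_label,
                                     local = labs$local_label,
                                     block = schedule$block %||% 1L,
                                     series_kind = labs$series_kind),
             channels = head$positions,
             log = sprintf("simulated: %d trials, %d ch, %g Hz, seed %d",
                           n_trials, n_ch, sfreq, seed))
}

#' Simulate a clinical cohort with structured covariates
#'
#' For each patient: FOUR score (0-16) and sedative infusion rates are drawn;
#' the latent global-effect amplitude is
#' `base + slope_four * FOUR + sum(sedation_effects * rate) + noise`,
#' truncated at 0; outcome CPC is drawn from a logistic link on the amplitude
#' (higher amplitude -> more favourable); the dichotomized outcome is
#' favourable iff CPC is 1-2.
#'
#' The per-recording `auc` column is produced either by decoding each
#' simulated recording through the full pipeline (`simulate_epochs = TRUE`,
#' exact but slow) or, by default, from a saturating monotone amplitude->AUC
#' link `0.5 + 0.5 * amp / (amp + 2)` plus Gaussian noise (sd `auc_noise_sd`),
#' clipped to [0.5 - eps, 1]. The `significant` flag thresholds the AUC at
#' `sig_threshold`.
#'
#' @param n_patients Number of recordings (>= 2).
#' @param base_amplitude Baseline effect amplitude, microvolts.
#' @param slope_four Amplitude change per FOUR point.
#' @param sedation_effects Named numeric: amplitude change per unit infusion
#'   rate for `propofol`, `fentanyl`, `midazolam`.
#' @param amp_noise_sd SD of the amplitude noise.
#' @param auc_noise_sd SD of the surrogate AUC noise.
#' @param sig_threshold AUC above this is flagged significant in the table.
#' @param day Recording day label (1 or 2) for the whole cohort.
#' @param simulate_epochs If `TRUE`, also return scaled-down recordings (see
#'   `recording_args`) and leave `auc` as `NA` for [run_cohort()] to fill by
#'   decoding.
#' @param recording_args List of arguments passed to [simulate_recording()]
#'   scaffolding when `simulate_epochs = TRUE` (`n_channels`, `sfreq`,
#'   `n_standard`, `n_deviant`, `noise_sd`).
#' @param seed Integer seed.
#' @return A list with `table` (a `cohort_table` tibble: `id`, `day`, `auc`,
#'   `significant`, `four`, `cpc`, `outcome`, `propofol`, `fentanyl`,
#'   `midazolam`, `temperature`, `age`, `sex`, `amplitude`) and `recordings`
#'   (list of [eeg_epochs] or `NULL`).
#' @export
simulate_cohort <- function(n_patients = 30L,
                            base_amplitude = 1,
                            slope_four = 0,
                            sedation_effects = c(propofol = 0, fentanyl = 0,
                                                 midazolam = 0),
                            amp_noise_sd = 0.25,
                            auc_noise_sd = 0.05,
                            sig_threshold = 0.6,
                            day = 1L,
                            simulate_epochs = FALSE,
                            recording_args = list(),
                            seed = 1L) {
  if (n_patients < 2L) stop("`n_patients` must be >= 2")
  stopifnot(all(names(sedation_effects) %in%
                  c("propofol", "fentanyl", "midazolam")))
  sed <- c(propofol = 0, fentanyl = 0, midazolam = 0)
  sed[names(sedation_effects)] <- sedation_effects

  tab <- withr_seed(seed, {
    four <- sample(0:16, n_patients, replace = TRUE,
                   prob = stats::dbinom(0:16, 16, 0.35))
    rates <- cbind(propofol = stats::rgamma(n_patients, 2, 1),
                   fentanyl = stats::rgamma(n_patients, 2, 2),
                   midazolam = stats::rbinom(n_patients, 1, 0.4) *
                     stats::rgamma(n_patients, 2, 4))
    amp <- pmax(0, base_amplitude + slope_four * four +
                  rates %*% sed + stats::rnorm(n_patients, 0, amp_noise_sd))
    amp <- as.numeric(amp)
    p_fav <- stats::plogis(-1 + 1.2 * amp)
    fav <- stats::rbinom(n_patients, 1, p_fav) == 1
    cpc <- ifelse(fav, sample(1:2, n_patients, TRUE),
                  sample(3:5, n_patients, TRUE))
    auc <- pmin(1, pmax(0.35,
      0.5 + 0.5 * amp / (amp + 2) + stats::rnorm(n_patients, 0, auc_noise_sd)))
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n_patients)),
      day = as.integer(day),
      auc = if (simulate_epochs) NA_real_ else auc,
      significant = if (simulate_epochs) NA else auc > sig_threshold,
      four = as.integer(four),
      cpc = as.integer(cpc),
      outcome = ifelse(cpc <= 2, "favourable", "unfavourable"),
      propofol = rates[, "propofol"],
      fentanyl = rates[, "fentanyl"],
      midazolam = rates[, "midazolam"],
      temperature = stats::rnorm(n_patients, 36.4, 0.4),
      age = sample(50:62, n_patients, TRUE),
      sex = sample(c("F", "M"), n_patients, TRUE),
      amplitude = amp
    )
  })
  class(tab) <- c("cohort_table", class(tab))

  recordings <- NULL
  if (simulate_epochs) {
    ra <- utils::modifyList(list(n_channels = 16L, sfreq = 100,
                                 n_standard = 15L, n_deviant = 3L,
                                 n_blocks = 8L, noise_sd = 1), recording_args)
    hm <- head_model(ra$n_channels, seed = child_seed(seed, "head"))
    recordings <- purrr::map(seq_len(n_patients), function(i) {
      sch <- build_session(child_seed(seed, "sched", i),
                           n_standard = ra$n_standard,
                           n_deviant = ra$n_deviant, n_blocks = ra$n_blocks)
      simulate_recording(sch, hm,
                         effects = list(effect_spec("global",
                                                    amplitude = tab$amplitude[i])),
                         noise_sd = ra$noise_sd, sfreq = ra$sfreq,
                         seed = child_seed(seed, "rec", i))
    })
  }
  list(table = tab, recordings = recordings)
}

# Deterministic child seed from a parent seed and stage labels (kept < 2^31).
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(parts)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}
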