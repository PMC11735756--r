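# Shared scaled-down fixtures: 16 channels, 144 trials (120 standard / 24
# deviant), 100 Hz. All built in code, memoized per session.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fx_cache)) assign(key, force(expr), .fx_cache)
  get(key, .fx_cache)
}

fx_schedule <- function(seed = 1L) {
  memo(paste0("sched", seed),
       build_session(seed, n_standard = 15L, n_deviant = 3L, n_blocks = 8L))
}

fx_head <- function(n_channels = 16L) {
  memo(paste0("head", n_channels), head_model(n_channels, seed = 2L))
}

fx_recording <- function(amp = 3, seed = 3L, noise_sd = 1) {
  memo(sprintf("rec_%g_%d_%g", amp, seed, noise_sd), {
    eff <- if (amp > 0) list(effect_spec("global", amplitude = amp)) else list()
    simulate_recording(fx_schedule(), fx_head(), effects = eff,
                       noise_sd = noise_sd, sfreq = 100, seed = seed)
  })
}

fx_norm <- function(amp = 3, seed = 3L) {
  memo(sprintf("norm_%g_%d", amp, seed),
       gfp_normalize(baseline_correct(fx_recording(amp, seed))))
}

# Small-but-searching STTA config for planted-effect checks.
fast_stta <- function(seed = 5L) {
  stta_config(k_values = 1:2, n_folds = 3L, restarts = 2L, seed = seed)
}

# Single-candidate STTA config for permutation-heavy null checks.
null_stta <- function() stta_config(k_values = 1L, windows = list(c(0, 0.5)))

fast_svm <- function(seed = 6L) {
  svm_config(kernels = "linear", cost = c(0.1, 1), n_folds = 3L, seed = seed)
}

# Exhaustive pair-counting AUC oracle (ties count 1/2).
oracle_auc <- function(scores, labels) {
  dev <- scores[labels == "deviant"]
  std <- scores[labels == "standard"]
  tot <- 0
  for (d in dev) for (s in std)
    tot <- tot + if (d > s) 1 else if (d == s) 0.5 else 0
  tot / (length(dev) * length(std))
}

# Labeled epochs with arbitrary label counts, minimal geometry (for split
# bookkeeping tests).
fx_labeled_epochs <- function(n_std, n_dev) {
  n <- n_std + n_dev
  eeg_epochs(array(stats::rnorm(n * 2 * 3), dim = c(n, 2, 3)),
             times = c(0, 0.1, 0.2), sfreq = 10,
             labels = tibble::tibble(
               global = rep(c("standard", "deviant"), c(n_std, n_dev)),
               local = rep("standard", n)))
}
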