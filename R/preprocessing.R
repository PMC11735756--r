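# Preprocessing: zero-phase band-pass, epoching of continuous data, artifact
# rejection with channel interpolation, baseline correction and GFP
# normalization.

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass realized as a cascade of a 2nd-order high-pass at
#' `low` and a 4th-order low-pass at `high`, each applied forward and
#' backward (zero phase, squared magnitude response). The cascade keeps the
#' high-pass numerically stable at drift-removal edges (0.1 Hz) even at high
#' sampling rates, where a single narrow-band band-pass design is
#' ill-conditioned. Signals are reflection-padded at both ends before
#' filtering to suppress edge transients. The DC component is removed and the
#' mid-passband gain is ~1.
#'
#' @param x Numeric vector, a channels x samples matrix, or an [eeg_epochs]
#'   object (filtered per trial and channel).
#' @param low,high Band edges in Hz, `0 < low < high < sfreq/2`.
#' @param sfreq Sampling rate, Hz (taken from the object for [eeg_epochs]).
#' @param order Butterworth order of the low-pass stage (default 4); the
#'   high-pass stage is order 2.
#' @return Same shape/class as `x`.
#' @export
bandpass <- function(x, low = 0.1, high = 40, sfreq = NULL, order = 4L) {
  if (inherits(x, "eeg_epochs")) {
    sfreq <- x$sfreq
    check_band(low, high, sfreq)
    flt <- design_bandpass(low, high, sfreq, order)
    d <- x$data
    for (tr in seq_len(dim(d)[1]))
      d[tr, , ] <- t(apply(d[tr, , , drop = TRUE], 1, filtfilt_padded, flt = flt))
    x$data <- d
    x$log <- c(x$log, sprintf("bandpass %g-%g Hz (butterworth order %d, zero-phase)",
                              low, high, order))
    return(x)
  }
  if (is.null(sfreq)) stop("`sfreq` is required for plain numeric input")
  check_band(low, high, sfreq)
  flt <- design_bandpass(low, high, sfreq, order)
  if (is.matrix(x)) t(apply(x, 1, filtfilt_padded, flt = flt))
  else filtfilt_padded(x, flt)
}

check_band <- function(low, high, sfreq) {
  if (!(low > 0 && low < high && high < sfreq / 2))
    stop("invalid band: need 0 < low < high < sfreq/2, got (",
         low, ", ", high, ") at sfreq ", sfreq)
}

design_bandpass <- function(low, high, sfreq, order) {
  list(hp = signal::butter(2, low / (sfreq / 2), type = "high"),
       lp = signal::butter(order, high / (sfreq / 2), type = "low"))
}

filtfilt_padded <- function(v, flt) {
  n <- length(v)
  np <- min(n - 1L, 3L * max(32L, round(n / 3)))
  pad_head <- 2 * v[1] - v[seq(np + 1L, 2L)]
  pad_tail <- 2 * v[n] - v[seq(n - 1L, n - np)]
  out <- c(pad_head, v, pad_tail)
  out <- signal::filtfilt(flt$hp, out)
  out <- signal::filtfilt(flt$lp, out)
  out[(np + 1L):(np + n)]
}

#' Extract epochs from continuous EEG
#'
#' Cuts one epoch per event, aligned to the event onset (the fifth-tone onset
#' in this paradigm), over a half-open window (default -100..500 ms), so the
#' sample count is `round(window_s * sfreq)` (720 at 1200 Hz). Events too
#' close to the recording edges are dropped with a warning and counted in the
#' provenance log.
#'
#' @param continuous Channels x samples numeric matrix.
#' @param sfreq Sampling rate, Hz.
#' @param onsets Event onsets in seconds (e.g. `schedule$fifth_onset`).
#' @param labels Tibble with one row per event (`global`, `local`, ...).
#' @param window_ms Half-open epoch window in ms.
#' @param channels Optional channel metadata tibble.
#' @return An [eeg_epochs]; attribute `n_dropped` counts edge-dropped events.
#' @export
extract_epochs <- function(continuous, sfreq, onsets, labels,
                           window_ms = c(-100, 500), channels = NULL) {
  stopifnot(is.matrix(continuous), nrow(labels) == length(onsets))
  n_samp <- round(diff(window_ms) / 1000 * sfreq)
  first_off <- round(window_ms[1] / 1000 * sfreq)
  start <- round(onsets * sfreq) + first_off + 1L  # 1-based first sample
  ok <- start >= 1L & (start + n_samp - 1L) <= ncol(continuous)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge were dropped")
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(continuous), n_samp))
  for (j in seq_along(keep)) {
    s <- start[keep[j]]
    data[j, , ] <- continuous[, s:(s + n_samp - 1L)]
  }
  times <- window_ms[1] / 1000 + (seq_len(n_samp) - 1L) / sfreq
  ep <- eeg_epochs(data, times, sfreq, labels[keep, , drop = FALSE], channels,
                   log = sprintf("epoched: %d kept, %d dropped at edges",
                                 length(keep), sum(!ok)))
  attr(ep, "n_dropped") <- sum(!ok)
  ep
}

#' Artifact rejection and bad-channel interpolation
#'
#' Two-stage semi-automated cleaning: (1) channels whose peak absolute
#' amplitude exceeds `amp_thresh` in more than `bad_channel_frac` of epochs
#' are interpolated everywhere from their neighbours (inverse-distance
#' weights on the unit-sphere channel positions); (2) epochs that still
#' contain any excursion beyond `amp_thresh` are dropped. The report counts
#' satisfy `retained + dropped = input`.
#'
#' @param epochs An [eeg_epochs] with channel positions.
#' @param amp_thresh Absolute amplitude threshold, microvolts (> 0).
#' @param bad_channel_frac Fraction of epochs over threshold above which a
#'   channel is declared bad (> 0).
#' @return A list: `epochs` (cleaned), `report` (tibble with
#'   `n_input`, `n_retained`, `n_dropped`, `bad_channels` list-column).
#' @export
reject_and_interpolate <- function(epochs, amp_thresh = 100,
                                   bad_channel_frac = 0.2) {
  stopifnot(amp_thresh > 0, bad_channel_frac > 0)
  d <- epochs$data
  n_ep <- dim(d)[1]; n_ch <- dim(d)[2]
  peak <- apply(abs(d), c(1, 2), max)              # epochs x channels
  bad_ch <- which(colMeans(peak > amp_thresh) > bad_channel_frac)

  if (length(bad_ch) > 0) {
    pos <- as.matrix(epochs$channels[, c("x", "y", "z")])
    for (bc in bad_ch) {
      others <- setdiff(seq_len(n_ch), bad_ch)
      dist <- sqrt(rowSums((pos[others, , drop = FALSE] -
                            matrix(pos[bc, ], length(others), 3, byrow = TRUE))^2))
      w <- 1 / pmax(dist, 1e-6); w <- w / sum(w)
      for (tr in seq_len(n_ep))
        d[tr, bc, ] <- crossprod(w, d[tr, others, , drop = TRUE])
    }
    peak <- apply(abs(d), c(1, 2), max)
  }

  keep <- which(apply(peak, 1, max) <= amp_thresh)
  if (length(keep) == 0)
    stop("all epochs exceed ", amp_thresh,
         " uV after interpolation; review the rejection threshold")
  out <- epochs
  out$data <- d
  out <- out[keep]
  out$log <- c(out$log, sprintf(
    "cleaned: %d/%d epochs retained, %d channel(s) interpolated",
    length(keep), n_ep, length(bad_ch)))
  report <- tibble::tibble(
    n_input = n_ep, n_retained = length(keep),
    n_dropped = n_ep - length(keep),
    bad_channels = list(epochs$channels$name[bad_ch])
  )
  list(epochs = out, report = report)
}

#' Baseline-correct epochs
#'
#' Subtracts the per-epoch, per-channel mean of the baseline interval
#' (default -100..0 ms) from every sample.
#'
#' @param epochs An [eeg_epochs].
#' @param interval Length-2 baseline interval in seconds.
#' @return The corrected [eeg_epochs].
#' @export
baseline_correct <- function(epochs, interval = c(-0.1, 0)) {
  sel <- epochs$times >= interval[1] & epochs$times < interval[2]
  if (!any(sel)) stop("baseline interval contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over 3rd dim
  epochs$log <- c(epochs$log, sprintf("baseline corrected on [%g, %g) s",
                                      interval[1], interval[2]))
  epochs
}

#' Global-field-power normalization of topographies
#'
#' Every time-point topography is average-referenced (channel mean removed)
#' and divided by its instantaneous global field power — the root-mean-square
#' of the average-referenced potentials across channels. Time-points with
#' GFP below `eps` (e.g. flat topographies) are masked and never divided;
#' masked points are excluded from GMM fitting and likelihood scoring.
#'
#' @param epochs An [eeg_epochs] with >= 2 channels.
#' @param eps GFP floor below which a time-point is masked.
#' @return An object of class `c("eeg_epochs_norm", "eeg_epochs")` with extra
#'   fields `gfp` (trials x samples) and `mask` (trials x samples logical,
#'   `TRUE` = usable).
#' @export
gfp_normalize <- function(epochs, eps = 1e-12) {
  d <- epochs$data
  n_ch <- dim(d)[2]
  if (n_ch < 2L) stop("GFP normalization needs >= 2 channels")
  chan_mean <- apply(d, c(1, 3), mean)             # trials x samples
  for (ch in seq_len(n_ch)) d[, ch, ] <- d[, ch, ] - chan_mean
  gfp <- sqrt(apply(d^2, c(1, 3), mean))
  mask <- gfp > eps
  gfp_safe <- ifelse(mask, gfp, 1)
  for (ch in seq_len(n_ch)) d[, ch, ] <- d[, ch, ] / gfp_safe
  out <- epochs
  out$data <- d
  out$gfp <- gfp
  out$mask <- mask
  out$log <- c(out$log, sprintf("GFP-normalized (%d/%d points masked)",
                                sum(!mask), length(mask)))
  class(out) <- c("eeg_epochs_norm", class(epochs))
  out
}
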