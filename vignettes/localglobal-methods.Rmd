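---
title: "Models and design choices in localglobal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in localglobal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The paradigm and its labels

Each five-tone series carries two independent condition labels. The *local*
label depends only on the series kind: AAAAB and BBBBA violate the single-tone
repetition. The *global* label depends on the block: the series type presented
100 times per block is the global standard, the one presented 20 times the
global deviant. Block type 1 uses AAAAB as the global standard (so its global
standards are local deviants), block type 2 reverses the assignment, and
block types 3 and 4 repeat the pair with the tone roles swapped. The protocol
text describing block 2 contains a parenthetical that repeats block 1's
assignment while calling it "reversed"; we implement the reversal, which is
the only reading under which the four block types cover all four
(global, local) label combinations.

Where the protocol fixes only counts and ranges, the generator makes these
choices:

- **Deviant placement** (counts only are specified): uniformly random
  positions subject to no two adjacent deviants and a deviant-free lead-in of
  10 series (capped for small blocks), so the global regularity is
  established before it is violated. Both constraints are standard for this
  paradigm and configurable.
- **Block order** ("semi-randomized"): a uniform random permutation of the
  eight blocks, rejected until no two repetitions of the same type are
  adjacent — the minimal reading of semi-randomization.
- **ITI sampling** (only the 1450–1800 ms range is specified): uniform,
  measured from the fifth-tone onset of one series to the first-tone onset of
  the next.

## What the synthetic EEG emulates — and what it does not

`simulate_recording()` produces one epoch per series over −100–500 ms around
the fifth-tone onset (720 samples at the protocol's 1200 Hz). Noise is
Gaussian white noise mixed across channels by a random full-rank matrix
(near-identity, `I + 0.3G/sqrt(n)`) and AR(1)-smoothed over time
(coefficient 0.3, stationary variance preserved). This is the simplest
structure that makes GFP normalization and spatial decoding non-trivial:
channels are correlated, so single-channel thresholds and multivariate
decoders behave differently.

Deviant epochs (on the label dimension the effect keys on) additionally
receive `amplitude × topography × half-cosine bump` inside the effect window
— by default 300–500 ms for the global effect and 100–250 ms for the local
one, reflecting the late latency at which global-deviance responses are
typically observed. The smooth bump avoids the ringing a rectangular pulse
would produce after band-pass filtering. Topographies are smooth random
unit-norm, zero-mean channel patterns on a spherical montage.

The generator deliberately omits 1/f background spectra, blinks, ECG and
electrode drifts, non-stationarity across blocks, and any biophysical forward
model. Consequently, passing tests show that the *pipeline* is correct and
calibrated (type-I error, parameter recovery, monotonicity in effect size) —
they do not show that real coma EEG is decodable, which is exactly the
question the eventual recordings must answer.

Synthetic cohorts draw FOUR scores (binomial shape over 0–16), gamma-
distributed sedative infusion rates (zero-inflated for midazolam), and set
each patient's latent global-effect amplitude to
`base + slope_four · FOUR + Σ β_sedative · rate + noise`, truncated at zero.
Outcome CPC is drawn through a logistic link on the amplitude; the
favourable/unfavourable dichotomy is CPC 1–2 vs 3–5. All links are explicit
arguments defaulting to "off" (zero slopes), so a null cohort is the default.
The per-recording AUC column can be produced two ways: decoding every
simulated recording (exact, used in the integration test) or a saturating
monotone surrogate `0.5 + 0.5·amp/(amp + 2)` plus Gaussian noise
(sd 0.05, clipped), which preserves the monotone amplitude→AUC relationship
the statistics consume at a fraction of the cost and is the default for
cohort-level work.

## Preprocessing

- **Band-pass 0.1–40 Hz**: Butterworth applied forward–backward (zero phase),
  realized as a 2nd-order high-pass at 0.1 Hz cascaded with a 4th-order
  low-pass at 40 Hz, with reflection padding. The cascade was chosen because
  a single band-pass with a 0.1 Hz edge is numerically ill-conditioned at
  1200 Hz (the normalized cutoff is ~1.7e-4), while an FIR design flat to
  0.1 Hz needs tens of thousands of taps — longer than an epoch. Measured
  response: DC removed, mid-band gain within 5% of unity, 60 Hz attenuated by
  more than 96%.
- **Artifact handling**: channels exceeding the amplitude threshold in more
  than a configurable fraction of epochs are interpolated from neighbours
  with inverse-distance weights on the spherical montage; epochs with any
  remaining excursion are dropped, and the report satisfies
  `retained + dropped = input`. ICA-based cleaning is out of scope — the
  synthetic data contain no blink/ECG components — but externally cleaned
  epochs enter the pipeline unchanged.
- **Baseline correction** (convention, protocol silent): per-epoch,
  per-channel mean of −100–0 ms subtracted; can be switched off.
- **GFP normalization**: each topography is average-referenced and divided by
  its instantaneous global field power, computed as the root-mean-square of
  the average-referenced potentials across channels (the Lehmann–Skrandies
  definition; equal to the population SD across channels). Time-points with
  GFP below 1e-12 are masked, never divided, and excluded from model fitting
  and scoring.

## The topographic decoder

Per condition (standard, deviant), the pooled GFP-normalized topographies of
all post-onset latencies and all training trials are modelled by a mixture of
`k` Gaussians with **diagonal** covariances; the component means are the
template maps. Diagonal covariance is forced by the regime — 63 channels
against a few hundred trials makes full covariances rank-deficient — and is
the reason no full-covariance option is exposed. The EM uses k-means++-style
seeding, multiple restarts, a variance floor of 1e-8, and a relative
log-likelihood tolerance of 1e-6; the log-likelihood trace is retained and
tested for monotonicity. We fit one mixture per condition rather than a
shared mixture with per-condition posteriors; this is the most direct reading
of per-condition template maps, and it makes the decision statistic a proper
likelihood ratio.

A trial's decision score is the cumulative log-likelihood ratio
`Σ_t [log p(x_t | deviant) − log p(x_t | standard)]` over unmasked
time-points in the scoring window — the protocol describes template maps and
a discriminative period but no scoring formula, and the cumulative LLR is the
standard likelihood-based reading. Scores are antisymmetric under model swap
and zero for identical models, both unit-tested.

The number of Gaussians and the scoring window are selected by stratified
k-fold cross-validation (default 5-fold; 3-fold in the scaled test profile)
inside the 80% CV partition, maximizing the mean held-out-fold AUC. Window
candidates live on a post-onset grid in `[0, 0.5)` s — the baseline is
excluded because effects are post-stimulus. Ties break to the earliest start,
then the shortest window, then the smallest `k` (parsimony, determinism).
The 80/20 split is stratified by class; with the paradigm's 5:1 imbalance the
AUC (rank-based) needs no resampling. The test partition is never touched
during selection; models are refitted on the full CV set before test scoring.

## The SVM decoder

Concatenated features are channel-major (`n_channels × n_samples` per trial).
Hyperparameters (kernel ∈ {linear, RBF}, C, γ) are grid-searched by
stratified CV on margin-score AUC; per-feature z-scoring uses CV statistics
only, applied unchanged to the test set (leakage-tested). Inverse-frequency
class weights guard against trivial majority solutions; margins, not class
predictions, feed the AUC. Sub-averaging groups 2 or 3 same-class trials at
random without overlap, discarding leftovers; the sub-average analysis re-runs
selection on the pseudo-trials rather than reusing single-trial
hyperparameters, since the feature distribution changes with the noise level.
Time-resolved decoding fits one classifier per sample with fixed
hyperparameters — a full grid search at every sample would be
disproportionate for a localization curve.

## Significance

The permutation null shuffles the contrast labels **before** the CV/test
split and re-runs the entire pipeline, so selection optimism is inside the
null. The empirical p-value uses add-one smoothing,
`(1 + #{perm ≥ observed}) / (n_perm + 1)`, and is therefore never zero. The
analysis plan's criterion — a Wilcoxon signed-rank test of the permutation
AUCs against the observed value — is also computed (one-sided, exact for
n ≤ 25, normal approximation with continuity correction above), but a
one-sample test of a whole distribution against a point is significant for
almost any positive offset, so the default `significant` flag is the
conjunction of both criteria at α = 0.05; either criterion alone is a
configuration switch. Sidedness is not stated in the plan; one-sided
(observed greater) is implemented and both p-values are always reported.

## Cohort statistics

The power simulation draws `K' ~ Binomial(N, p)` success counts and declares
a draw significant when the count could not arise under `H0: p = 0`, i.e.
`K' ≥ 1`; the phrase "up to K' successes" in the protocol would make the null
probability identically 1, and the at-least reading is the only one that
reproduces the published operating point (N = 13 at p = 0.21, mean success
count 2.7). The closed form `1 − (1 − p)^N` is carried alongside as the
oracle, and the Monte-Carlo estimate is tested to stay within 3 SE of it at
every N. For the healthy-control prior p = 0.20 the closed form gives
`1 − 0.8^13 ≈ 0.945`, marginally below 0.95 — a rounding-level discrepancy
with the published control sample size; we do not treat it as a target.

Outcome, consciousness-level and clinical-feature tests are the standard
implementations (exact hypergeometric Fisher, Pearson with t-distributed
two-sided p, Kruskal–Wallis with tie correction), each validated against
hand computations and brute-force enumerations in the test suite.

Forward selection over sedative covariates orders candidates by adjusted R²
gain and stops on the information criterion, with interactions eligible only
after both main effects. The stopping criterion is **AICc**, not plain AIC:
at this design's scale (30 recordings, three candidate sedatives) plain AIC
admits a spurious covariate in more than half of null cohorts — the required
R² gain is only ~6%, giving a per-term false-inclusion rate near 0.18 and
~0.45 across three candidates — which would defeat the purpose of selection.
The small-sample correction raises the bar enough that an intercept-only
model wins the majority of null cohorts, while a genuine single-sedative
effect is still recovered; both AIC and AICc appear in the candidate ledger.
The response is the AUC under a Gaussian identity link by default ("logistic
regression" in the plan's narrative, but the declared response is the
continuous AUC); a logit-transformed response is available.

## Numerical and runtime choices

Test and acceptance runs use a scaled profile — 16 channels, 144 trials
(120/24, preserving the 1/6 deviant rate), 100 Hz, 50 permutations, and a
single-candidate or two-candidate STTA configuration for permutation-heavy
checks — sizes at which the null calibration study (50 recordings × 51
pipeline runs) completes in under a minute while exercising every stage. The
protocol-scale defaults (63 channels, 1200 Hz, 960 series, 100 permutations,
k ∈ 1..6) remain the package defaults throughout.

All randomness flows from explicit integer seeds; child seeds are derived by
hashing the parent seed with stage names into `[0, 2^31)`, so stages are
reproducible independently and a full rerun is bit-identical. Degenerate
inputs are handled explicitly: flat topographies are masked rather than
divided by zero GFP; empty mixture components trigger a restart; zero-variance
covariates are dropped with a warning; a Fisher test with an empty margin and
a correlation with a zero-variance scale are skipped with a logged reason
rather than aborting the cohort run.

## Known limitations

- The synthetic noise model (mixed white + AR(1)) underestimates the
  low-frequency power of real EEG; decoding performance at a given amplitude
  is therefore optimistic relative to patient data.
- The GMM is fitted to topographies pooled over latencies, so temporal
  structure within the window enters only through the window selection, not
  the density model.
- The surrogate amplitude→AUC link in cohort simulation is monotone by
  construction; it cannot probe decoder-level failures at the cohort scale.
- Continuous-EEG ingestion expects an already-loaded channels × samples
  matrix plus an events table; no EDF reader is bundled.
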