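---
title: "Quantifying mental fatigue from prefrontal EEG with wavelet Renyi entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mental fatigue from prefrontal EEG with wavelet Renyi entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The marker and its rationale

Sustained cognitive load flattens the spectral profile of resting-state
EEG: the dominance of the alpha rhythm seen in alert, eyes-closed
recordings erodes, and power spreads more evenly over the delta-to-beta
range. `renyieeg` quantifies this flattening with a single number per
recording, the **normalized order-2 Renyi entropy of the relative wavelet
energies** of the four classical bands.

For each 8-s window of a preprocessed channel, a 4-level discrete wavelet
transform (Daubechies-4, periodized boundary) yields detail coefficients
$w_j(k)$ at levels $j = 1..4$. The band energies and relative energies are

$$E_j = \sum_k w_j(k)^2, \qquad p_j = \frac{E_j}{\sum_{j'} E_{j'}},$$

and the marker is

$$RE = \frac{1}{1-q}\,\log \sum_j p_j^{\,q} \Big/ \log 4, \qquad q = 2 .$$

$RE = 1$ for a perfectly flat band profile and $RE = 0$ when all energy
sits in one band; a rising $RE$ across repeated assessments indicates
band flattening, the signature of accumulating mental fatigue. The
order-2 member of the Renyi family is used because it weights
concentrated profiles strongly while remaining smooth; $q = 1$ (the
Shannon limit) is deliberately out of scope.

Before the energies enter the entropy, each detail level is denoised by
an in-band threshold rule: with $T_j = \mathrm{mean}(|w_j|) +
2\,\mathrm{sd}(|w_j|)$, every coefficient with $|w| > T_j$ (strictly) is
halved, keeping its sign. Two interpretation choices in this rule were
genuinely open and are fixed as follows:

* **Magnitudes, population sd.** Detail coefficients are near zero-mean,
  so a threshold built from the raw mean would collapse to
  $2\,\mathrm{sd}$ and ignore the scale of typical coefficients; the rule
  operates on magnitudes, with the population (divide-by-$n$) standard
  deviation.
* **Strict inequality.** The analytic boundary case — four equal
  magnitudes $a$ plus one outlier $b$ gives $T = b$ exactly — stays
  stable under a strict comparison: the outlier is left unchanged rather
  than flip-flopping with rounding.
* **Per-window thresholds.** The rule is applied inside each 8-s window
  (thresholds recomputed every window), consistent with the windowed
  processing chain.

The approximation band (below about 2 Hz) is excluded from the relative
energies: the 3 Hz high-pass empties it, and including a near-zero band
would only dilute the profile.

Whether the published variant of this marker is normalized, and in which
logarithm base, is not stated anywhere we could verify; session values
reported for it lie in $[0.65, 0.85]$, which is consistent with natural
logs normalized by $\log 4$, and that interpretation is adopted here.
Likewise the aggregation from ~74 windows to one session value is fixed
as the arithmetic mean of per-window entropies.

## Preprocessing and the band mapping

The chain is fixed: **band-pass -> z-score -> decimate -> segment**.

* **Band-pass, 3-30 Hz.** Fourth-order Butterworth high-pass and
  low-pass sections in cascade, each applied forward and backward (zero
  phase). A single transfer-function band-pass with corners at
  $3/125$ and $30/125$ of Nyquist is numerically fragile in double
  precision, so the cascade realization is used; its magnitude response
  is the product of the two sections. Edges are padded by odd
  reflection over roughly twelve periods of the low corner (about 4 s at
  250 Hz) — with shorter padding, the filter's startup transient leaks
  visible energy into the output of low-frequency or constant inputs.
* **Z-score per channel over the whole session.** This removes gain and
  offset differences between assessment days. It is deliberately not
  applied per window: per-window scaling would erase exactly the
  between-window variance structure the entropy summarizes.
* **Decimation x4 (250 Hz to 62.5 Hz).** At 250 Hz a 4-level dyadic
  decomposition puts detail level 1 at 62.5-125 Hz, which corresponds to
  no EEG rhythm. At 62.5 Hz the details span approximately 15.6-31.2 /
  7.8-15.6 / 3.9-7.8 / 2.0-3.9 Hz — beta, alpha, theta, delta. This is
  the only effective rate at which the level-to-band assignment is true,
  so the pipeline decimates after filtering. Because the signal is
  already confined to 3-30 Hz, below the new 31.25 Hz Nyquist, plain
  keep-every-4th decimation is alias-free; the function still estimates
  the out-of-band power share and warns (rather than fails) above 1%.
* **Segmentation: 8-s windows, 50% overlap.** A 300-s recording at
  62.5 Hz yields $\lfloor(18750-500)/250\rfloor + 1 = 74$ epochs.
  Trailing partial windows are discarded, not padded — padding would
  bias band energies. Epochs are pure slices of the source signal.

The DWT itself uses the periodized boundary so that the analysis operator
is orthonormal: perfect reconstruction and Parseval's identity hold to
numerical precision on dyadic-length inputs, which makes the transform's
correctness directly testable. The 500-sample epochs produced by the
default geometry are not dyadic; odd lengths inside the cascade are
extended by repeating the last sample, and energy is then conserved to
within 1% rather than machine precision.

## The synthetic cohort

No public recordings accompany the study design this package targets, so
the generator is a first-class module: every downstream stage is
validated closed-loop against cohorts whose ground truth is programmed.

A cohort is nine subjects assessed at six sessions (labels
`Day1..Day3`, `Day4A`, `Day4B`, `Day5`), each session providing a 300-s,
4-channel recording at 250 Hz (prefrontal montage `AFp7, Fp1h, Fp2h,
AFp8`), a 240-s audio and a 240-s visual oddball log, a Stanford
Sleepiness Scale (SSS) score and a prior-sleep duration. Defaults follow
the descriptive statistics of the emulated study: the entropy trajectory
(0.657, 0.684, 0.661, 0.737, 0.761, 0.841), SSS means rising from about
2.3 to 4.2, reaction times drifting from ~0.33 to ~0.40 s, and sleep
durations collapsing from ~375 min to ~2 min in the sleep-deprivation
phase.

Each recording is built as four band-limited oscillatory components plus
$1/f$ background noise:

* The per-cell band profile comes from inverting the entropy target: the
  profile is sought on the line between an alpha-dominant base profile
  (delta/theta/alpha/beta = 0.15/0.15/0.60/0.10, entropy ~0.63 — an
  eyes-closed resting mix) and the uniform profile; entropy is monotone
  along that line so the solution is unique. Per-subject offsets
  (sd 0.15) and per-session jitter act on the entropy scale before the
  inversion.
* Components are **filtered white noise, not sinusoids** — pure tones
  would make the per-window energies degenerate. They are synthesized
  spectrally: white Gaussian noise shaped by a zero-phase Butterworth
  band magnitude (the same response a forward-backward filter pass
  applies), which is fast enough to run hundreds of replicate cohorts in
  the test suite.
* Components are confined to the **geometric interior** (60% in
  log-frequency) of each dyadic band with a steep order-8 envelope. The
  db4 filter bank has wide transition bands; content sitting on a dyadic
  edge splits its energy between adjacent detail levels and would
  systematically distort programmed profiles (with naive edge-to-edge
  placement, a programmed uniform profile measured ~0.88 instead of
  ~0.95).
* Component power is normalized **after the 3-30 Hz analysis filter**,
  i.e. at the point the marker sees it. The delta band straddles the
  3 Hz corner, so normalizing before the filter would roughly halve its
  effective share.
* The background is $1/f$ noise (exponent 1) carrying 30% of the in-band
  power — enough to be realistic, little enough that programmed band
  ratios remain recoverable (a periodogram oracle in the test suite
  verifies recovery within 15%, and measures ~3%).

All randomness is drawn from counter-based substreams of the master
seed, keyed by purpose, subject, session and channel. Substreams make
every generated object a pure function of its own coordinates: adding or
removing a subject, or changing the channel count, never perturbs the
data of others — a property the test suite asserts bit-for-bit.

**What the generator does not emulate:** eye-blink/EMG artifacts, volume
conduction or any forward model, channel covariance (channels are
independent realizations sharing a band profile), non-stationarity
within a session, and the apparatus of acquisition. Passing closed-loop
tests therefore demonstrates that the pipeline recovers what it is
designed to measure from signals with the assumed statistical structure,
not that it is robust to real-world artifacts.

One generator default is explicitly a testability choice rather than an
empirical one: the within-subject session-to-session entropy jitter
(sd 0.02) has no published counterpart. It is set small enough that
per-session cohort means are estimable from a single channel at modest
recording lengths, which is what makes the monotone-marker acceptance
check meaningful at desk scale.

## Behavioral instruments

Oddball logs contain stimulus onsets at a fixed 1.05-s period (1000 ms
interval + 50 ms duration), each stimulus independently deviant with
probability 0.2. Reaction-time extraction assigns to each deviant the
first unassigned press in the window (onset + 0.1 s, onset + 1.0 s];
deviants without a press are misses, presses without a deviant are false
alarms. The window bounds are a package choice: 0.1 s excludes
anticipations, and 1.0 s equals the inter-stimulus interval so a
response can never be reattributed across stimuli. The bookkeeping
identity hits + misses = deviants holds by construction and is enforced
by tests. Counts are always reported alongside the mean RT so the
handling of misses is auditable.

The SSS is generated on a latent continuous scale (trend + subject
offset + noise), then rounded and clamped to the instrument's 1..7
range; clamping events are reported. The session-table validator rejects
out-of-range scores, negative sleep and duplicated (subject, session)
keys, reporting row indices.

## Inference layer

One-way and two-way fully-within-subject ANOVA are computed from
explicit sums of squares; each effect is tested against its own
subject-interaction error term. The Greenhouse-Geisser epsilon
$\hat\varepsilon = (\sum\lambda_i)^2 / ((k-1)\sum\lambda_i^2)$, from the
eigenvalues of the orthonormal-contrast covariance, is applied
**unconditionally** to every within-subject effect; Mauchly's test (Box
two-term chi-square approximation) is attached as a diagnostic only,
never used as a gate. LSD post-hoc comparisons are plain paired t-tests
with unadjusted p-values — that is what the named procedure means, and
the report says so. Pearson correlations with sleep duration are pooled
over subject-session observations (n = 54 at the default design); pooling
ignores within-subject dependence and is recorded as a limitation, not a
recommendation.

Two calibration facts about the GG correction shape the test suite.
Under exact sphericity the estimator $\hat\varepsilon < 1$ almost
surely, so the corrected test is conservative at small designs: at 9
subjects x 6 conditions the measured type-I rate is ~2% at nominal 5%.
The suite therefore checks the nominal level (5% +/- 1.5 percentage
points over 1000 null replicates) at 20 subjects x 4 conditions, where
the epsilon estimate is stable enough for the nominal level to apply,
and separately checks specificity at the study's own 9 x 6 size with the
one-sided bound (<= 10%) that the conservatism cannot violate.

## Numerical and design choices, collected

* db4 filter taps are stored to full double precision; the transform
  convention was frozen against an independent wavelet toolbox at
  coefficient level.
* Degenerate inputs error loudly and early: constant channels cannot be
  z-scored, zero detail energy cannot be normalized (reported with the
  offending epoch index), correlation of a constant series is refused,
  and a zero error mean-square yields an infinite-F diagnostic rather
  than NaN.
* Ties at the denoising threshold are resolved by the strict inequality
  (see above).
* `profile_for_entropy()` clamps unattainable entropy targets into the
  attainable range of its base profile, [~0.25, 1].
* Every output table carries the MD5 of the generating configuration
  (file paths excluded) in a `#` header line, and the whole pipeline is
  a pure function of (config, seed): reruns are byte-identical.

## Problem sizes used by the automated checks

The test suite and acceptance script choose sizes that keep the full run
in the tens of minutes on one core while leaving each check's
statistical margin intact: transform properties run on 1000 random
512-sample epochs; marker monotonicity on twenty single-channel cohorts
of 9 subjects at 64 s per recording; detection power and null
specificity on one hundred cohorts each at 32 s; the determinism check
on a 3-subject, 2-channel, 16-s configuration (determinism is
size-independent); and the acceptance script runs one full default
cohort (9 x 6 x 4 channels at 300 s). Monotonicity, power and
specificity margins at these sizes were verified to be limited by the
programmed noise levels, not by the shortened recordings.

## Known limitations

* The marker's absolute scale is compressed relative to programmed
  targets (background noise, wavelet band leakage and finite-window
  estimation all push profiles toward uniformity), so programmed
  trajectories are recovered in order and detectability, not in absolute
  value. Comparisons should always be within-pipeline.
* The db4 level-to-band mapping is approximate by nature; the dyadic
  edges (e.g. 15.6 Hz between alpha and beta) do not coincide with the
  conventional 13 Hz boundary.
* EDF support covers continuous, uniform-rate, 16-bit recordings only.
* No artifact rejection is implemented; recordings contaminated by
  blinks or EMG will inflate broadband energy and bias the entropy
  upward.
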