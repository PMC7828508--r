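---
title: "Methods: snippet-averaged online decoding of auditory attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snippet-averaged online decoding of auditory attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaad)
```

This vignette documents the model implemented by `oaad`, the assumptions
behind it, the choices made where the design was genuinely open, and what
the synthetic-data generator does and does not establish about real EEG.

## The decoding model

Selective attention modulates the cortical representation of concurrent
speech streams: the attended stream's slow (2–8 Hz) envelope is tracked more
strongly than an ignored one. A backward decoder turns this into a
classifier. Writing $R(t, n)$ for the preprocessed EEG of channel $n$ and
$S(t)$ for a speech envelope, both z-scored at 64 Hz, the decoder is a
lag-by-channel weight array $D(\tau, n)$ applied to post-stimulus lags
$\tau \in [0, 250]$ ms (17 lags at 64 Hz):

$$\hat S(t) = \sum_n \sum_\tau D(\tau, n)\, R(t + \tau, n).$$

Estimation is ridge regression on the raw lagged covariance,
$D = (R R^\top + \lambda I)^{-1} R S^\top$ with $\lambda = 10$. Both
$\lambda$ and the lag span are fixed package-wide defaults, applied to the
unnormalised covariance of z-scored data; no intercept is fitted and every
row, including lag zero, is regularised identically.

The *online* model introduces a sliding window: within a $T = 60$ s trial,
snippet $j$ spans seconds $(j-1)M$ to $(j-1)M + W$, giving
$J = \lfloor (T - W + 1)/M \rfloor$ snippets (evaluated in seconds, then
converted to samples; $W$ and $M$ must map to whole samples). One decoder is
fitted per snippet against the *attended* envelope, and the online model is
the unweighted mean over all $I \cdot J$ snippet decoders from the $I$
construction trials. When $W = T$ the procedure collapses to the mean of
per-trial full-length decoders; the implementation clamps $J$ to at least
one in that case so a full-trial window always exists, whatever $M$.

At test time the reconstruction from each snippet is Pearson-correlated
with the left and right envelopes, $r^L_j$ and $r^R_j$; the larger one wins
and the decision is timestamped at the window end $(j-1)M + W$. With the
default $M = 1$ s this yields one decision per second, the first at
$t = W$. Correlation series may be smoothed within each trial — never
across trials — by a causal moving average over the window of $k$ values
ending at the current one (shorter prefixes average what is available, so
$k = 1$ is the identity). Smoothing is applied to the correlations before
comparison, not to the decisions.

Exact ties between the two smoothed correlations repeat the previous
decision within the trial, defaulting to "left" at the first snippet. Ties
have measure zero on real-valued data; the rule exists only to make the
pipeline deterministic.

## Open choices and how they were resolved

Several details of the procedure are underdetermined; the package fixes
each one explicitly and exposes the alternative where reasonable:

* **Lag sign.** Backward models are sometimes written with $R(t - \tau)$.
  Physiologically the EEG *follows* the stimulus, so reconstruction of
  $S(t)$ must read EEG at $t \dots t + 250$ ms; this is what the
  implementation does, treating the opposite sign as notational.
* **Envelope definition.** "Power of the analytic signal" is read literally
  as the squared magnitude; `extract_envelope(power = FALSE)` gives the
  magnitude instead. After z-scoring the downstream effect is small.
* **Construction target.** Snippet decoders are fitted against the attended
  envelope only (not both streams), matching standard stimulus-
  reconstruction training.
* **Ground truth in switching trials.** A decision is labelled by the
  scheduled side at its timestamp, i.e. at the window *end*; a window
  ending exactly at the transition still counts as pre-transition. Windows
  straddling the transition are therefore labelled by the post-transition
  side, which depresses measured accuracy immediately after a switch — a
  property of the labelling convention, not of the decoder.
* **Biased pairs on switching trials.** Matched-side evaluation is defined
  per snippet: the decoder whose bias matches the scheduled side at the
  detection timestamp is applied. On attention-fixed trials this reduces to
  the usual "left decoder on left trials" rule.
* **Chance level.** The exact binomial convention — the smallest success
  count $k^*$ with $\mathrm{CDF}(k^*; n, p) \ge 0.95$, reported as
  $100\,k^*/n$ — reproduces all the conventional printed values (52.99% at
  $n=736$, 53.44% at $n=552$, 35%, 39.29%, 37.5% for the 4-option question
  counts); no normal approximation is used.

## Preprocessing chains

The offline chain (for data preprocessed after acquisition) applies, at the
raw rate: a 0.5 Hz Butterworth high-pass, band-stop notches at 60 and
120 Hz, common average re-referencing computed over non-EOG channels only,
a zero-phase 2–8 Hz band-pass (cascaded high- and low-pass Butterworth
sections run forward–backward), polyphase anti-aliased resampling to 64 Hz,
and per-channel z-scoring. The cascade form keeps the very low normalised
corner frequencies numerically safe at 1000 Hz.

The online chain is causal: CAR, then a linear-phase windowed-sinc
(Hamming) FIR band-pass of order 1650. A causal FIR of that order delays
its output by order/2 = 825 samples (825 ms at 1000 Hz); left uncompensated
this would misalign EEG and envelope by almost a second, so the
implementation discards the leading 825-sample transient, after which
output sample $t$ aligns with input sample $t$. The buffer must exceed the
filter order before any output exists. Whether to z-score per block, per
buffer, or per snippet is not dictated by the procedure itself; the
implementation z-scores each channel over the processed span of the
accumulated trial buffer, which keeps streamed and batch paths consistent.

## The streaming emulator

`run_online_session()` emulates acquisition: EEG arrives in $M$-second
blocks, accumulates in a per-trial buffer, and every snippet is processed
as soon as its window is complete — fitted into the running decoder average
during the first $n_\text{construction}$ trials, classified afterwards.
Wall-clock time is virtual (arrival order is emulated, nothing sleeps), so
runs are deterministic, and the streamed outputs are *bit-identical* to the
batch pipeline (`aad_decoder()` + `detect_attention()`) on the same data:
the emulator visits snippets in the same order and performs the same
floating-point operations, which the test suite checks with `identical()`.
No decision at time $t$ uses samples arriving after $t$.

The default session structure is 14 attention-fixed construction trials
(7 per side, so the same 14 trials also build the left/right biased pair)
followed by 12 attention-fixed and 4 attention-switching test trials, sides
balanced, with the switch at the trial midpoint (30 s; "near the middle" is
not an exact prescription, so the midpoint is the default and the
transition time is configurable). The simulation-style protocol with 15
construction trials is available by changing `session_plan()`.

## The synthetic-data generator

The generator exists so every stage is testable end-to-end without human
recordings. It emulates the *statistical* structure the decoder relies on,
nothing more:

* **Envelopes** are half-wave-rectified 2–8 Hz band-limited Gaussian noise,
  z-scored at 64 Hz: non-negative before standardisation, dominant
  modulation energy in the delta–theta range (empirical spectral centroid
  ≈ 5 Hz), and essentially uncorrelated across draws (|r| < 0.1 at 60 s).
  They carry no phonemic, prosodic or linguistic structure.
* **EEG** is generated by a known lagged forward model: each channel is
  gain_att × (kernel ∗ attended envelope) + gain_ign × (kernel ∗ ignored
  envelope) + white noise, z-scored. Kernels are damped oscillations whose
  peak latency (spanning roughly 30–170 ms across the montage) and
  oscillation phase vary by channel; this channel diversity is what makes
  the 0–250 ms backward problem well posed, so that in the noiseless
  single-stream limit the snippet-averaged decoder reconstructs held-out
  envelopes at r > 0.99 under the default λ. Gains default to 1.0/0.4,
  encoding the attended-stronger-than-ignored premise. The ignored stream
  drives the mirror-image topography by default (`ign_topography =
  "reversed"`); with `"same"` kernels and equal gains the two streams are
  statistically indistinguishable and decoding is at chance by symmetry.
* **Montage and noise.** The default montage has 8 channels — a compact
  array of the size targeted by wearable AAD hardware — and noise_sd = 120,
  i.e. per-channel envelope tracking is deliberately weak (single-channel
  stimulus–response correlations of a few hundredths, as in real cortical
  recordings). This operating point puts the default session in the
  realistic 75–90% accuracy band, between chance and ceiling, so parameter
  effects are visible. Noise is white at 64 Hz; real EEG noise is coloured
  and spatially correlated, which the generator does not model.
* **Generation is at 64 Hz directly** by default — the preprocessing chains
  are exercised separately on constructed raw-rate signals — which keeps
  simulations fast; a raw-rate path can be emulated by feeding
  `simulate_eeg()` output through the preprocessing functions.
* **Spatial effect.** With `spatial_effect = TRUE` the half of the montage
  contralateral to the attended ear responds more strongly (gain × 1.6),
  giving direction-biased decoders a real advantage to detect; within a
  switching trial the topography follows the initial side (a simplification
  — biased-model analyses use attention-fixed trials).

Because of these simplifications, passing tests establish correctness of
the *pipeline* — snippet arithmetic, estimation, averaging, streaming
equivalence, decision and evaluation logic — and qualitative behaviour
(accuracy rising with window size and training data, insensitivity to hop
size, benefit of smoothing on attention-fixed data). They do not establish
accuracy levels on real EEG, where nonstationarity, artifacts, coloured
noise and inter-subject variability dominate.

## Numerical choices

* Snippet arithmetic is done in printed seconds and converted once to
  samples; `window_spec()` rejects W or M that do not map to whole samples,
  avoiding rounding drift across snippets.
* Lagged design matrices zero-pad beyond the segment end, and snippets are
  lagged *as independent segments* (their final 250 ms are padded even when
  the trial continues), exactly as the per-snippet estimator prescribes.
* The ridge system is solved densely; a singular unregularised system falls
  back to the pseudo-inverse with a warning.
* The grid search fits each (trial, window-start) decoder once on the
  one-second start grid and re-averages per (W, M, I) cell, which equals
  direct per-cell construction up to summation order (verified to 1e-12).
  Construction averages accumulate snippet-by-snippet in a fixed order so
  streamed and batch runs agree exactly, and storage stays O(1) in the
  snippet count.
* Zero-variance snippets (possible only on degenerate input) yield r = 0
  with a warning rather than NA.

## Calibration of statistical checks

Overlapping windows make consecutive decisions strongly dependent (with
W = 15 s and M = 1 s adjacent windows share 93% of their samples), so
binomial intervals on raw decision counts are valid only when decisions are
effectively independent. The chance-level check in the test suite therefore
uses non-overlapping 5 s windows over many trials, where the empirical
between-seed dispersion matches the binomial standard error. Trend checks
(accuracy vs W, I, M) use Spearman rank correlations across all unsmoothed
grid cells of five simulated subjects; the problem sizes used throughout
the suite (8-channel montages, 30-trial sessions, five seeds) were chosen
once as the smallest sizes at which these properties are stable.

## Known limitations

* The generator's noise is white and spatially independent; there is no 1/f
  spectrum, no artifacts, no electrode drift.
* Envelopes are stationary noise, not speech; effects tied to linguistic
  content (or to sub-2 Hz prosody) are out of scope.
* The online z-scoring scope and FIR delay compensation are documented
  conventions, not validated against a specific acquisition system.
* Decoder weighting schemes, channel selection, state-space smoothing of
  decisions, and nonlinear decoders are deliberately not implemented.
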