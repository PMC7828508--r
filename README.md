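# oaad — online auditory attention decoding from streaming EEG

In a cocktail-party setting, the cortical response tracks the slow amplitude
envelope of speech, and it tracks the *attended* talker more strongly than an
ignored one. Auditory attention detection (AAD) exploits this: from
multichannel EEG it infers which of two dichotically presented speech streams
a listener is attending. Classical stimulus-reconstruction AAD is an offline
procedure — decoders are trained on a full recording and evaluated
retrospectively. `oaad` implements the *online* variant: decoders are built
incrementally from short overlapping snippets of EEG while the signal is
still streaming in, and attended-direction decisions are emitted once per
second. It is aimed at researchers prototyping closed-loop AAD applications
(neuro-steered hearing aids, attention neurofeedback) who need a testable,
fully synthetic-data-backed reference implementation.

## The model

A backward (stimulus-reconstruction) decoder `D(τ, n)` maps EEG channel `n`
at post-stimulus lags `τ ∈ [0, 250]` ms to an estimate of the attended
speech envelope:

    Ŝ(t) = Σ_n Σ_τ D(τ, n) · R(t + τ, n)

Each decoder is the ridge (L2-regularised) least-squares solution on the raw
lagged covariance,

    D = (R Rᵀ + λI)⁻¹ R Sᵀ ,   λ = 10,

computed on z-scored 64 Hz data. The online model slides a window of `W`
seconds over each 60 s trial in hops of `M` seconds, fits one decoder per
snippet `j` (spanning `(j−1)·M` to `(j−1)·M + W` seconds, `J = ⌊(T−W+1)/M⌋`
snippets per trial), and averages all `I·J` snippet decoders from the `I`
construction trials into a single model. At test time the reconstruction
from each new snippet is Pearson-correlated with the left and right speech
envelopes; whichever correlates more is the decoded direction, timestamped
at the window end `(j−1)·M + W`. Correlation series may be smoothed with a
causal moving average of width `k ∈ {1, 3, 5, 7}` before comparison.
Direction-biased decoder pairs (trained on left- or right-attended trials
only, evaluated on matched-side data) are supported alongside the single
model, as are exact binomial chance levels for accuracy assessment.

Speech envelopes are the squared magnitude of the analytic (Hilbert) signal,
resampled to 64 Hz and z-scored. EEG preprocessing is provided in both the
offline flavour (0.5 Hz high-pass, mains notches, common average reference
excluding EOG channels, zero-phase 2–8 Hz band-pass, 64 Hz, z-score) and the
causal in-situ flavour used during streaming (CAR, 1650th-order linear-phase
FIR band-pass with group-delay compensation, 64 Hz, z-score).

## Worked example

Simulate one full experimental session — 14 attention-fixed construction
trials, then 12 attention-fixed and 4 attention-switching test trials, EEG
generated from a known lagged forward model with weak per-channel envelope
tracking — stream it block-by-block, and evaluate the decoded directions:

```r
library(oaad)
ses <- generate_session(session_plan(), forward_model(), seed = 42)
res <- run_online_session(ses)
print(res$single)
#> <aad_decoder> 17 lags x 8 channels, lambda=10, bias=none
#>   averaged over 14 trials, 644 snippet decoders

acc <- evaluate_accuracy(res$records)
subset(acc, k %in% c(1, 7) & model == "single")
#>     model k trial_type   n accuracy_pct
#> 2  single 1        all 736         82.2
#> 8  single 7        all 736         83.4
#> 10 single 1      fixed 552         84.1
#> 16 single 7      fixed 552         85.7
#> 18 single 1  switching 184         76.6
#> 24 single 7  switching 184         76.6

binomial_chance_level(736, 0.5)
#> [1] 52.98913
```

The 16 test trials yield 46 snippets each (736 decisions per smoothing
width; 552 from the attention-fixed trials). Unsmoothed single-model
accuracy is 82.2% — far above the 52.99% chance level for n = 736 — and the
widest moving-average filter (k = 7) lifts attention-fixed accuracy from
84.1% to 85.7% while attention-switching trials, where the decoder must
re-lock after the mid-trial transition, sit lower at 76.6%. `grid_search()`
reruns the whole construction/evaluation pipeline over the
`W × M × I` parameter grid, and `summary()` on its result table gives the
per-cell and marginal accuracy structure.

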