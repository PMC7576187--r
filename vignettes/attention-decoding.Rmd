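---
title: "Envelope tracking and auditory attention decoding: models and methods"
author: "trfaad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope tracking and auditory attention decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfaad)
```

## The model

Cortical activity in the delta–theta range tracks the slow amplitude
envelope of speech. With two concurrent talkers, tracking of the attended
stream is enhanced relative to the ignored one, which makes the attended
talker decodable from EEG alone. `trfaad` implements both directions of the
standard linear analysis.

The **forward (encoding) TRF** treats each EEG channel as the output of a
causal-ish linear filter on the stimulus envelope,

$$ r(t, n) = \sum_{\tau} w(\tau, n)\, s(t - \tau) + \varepsilon(t, n), $$

with lags $\tau$ spanning −200..800 ms by default (the negative lags act as
a sanity strip: a real response must not precede its stimulus). The lag
profile of $w$, averaged over fronto-central channels, shows three canonical
deflections — P1 (positive, read out in 80–110 ms), N1 (negative,
150–180 ms), P2 (positive, 230–300 ms) — whose amplitudes and latencies
`trf_components()` extracts.

The **backward (decoding) model** pools all channels and lags 0..400 ms to
reconstruct the envelope,

$$ \hat s(t) = \sum_{n} \sum_{\tau} r(t + \tau, n)\, g(\tau, n). $$

Note the sign: the reconstruction at time $t$ reads the EEG *after* $t$,
because the brain lags the stimulus. Internally the decoder is fit as an
ordinary lagged regression with negated lags; the stored lag grid stays on
the conventional 0..400 ms decoder axis.

Both are ridge regressions solved in closed form from the normal equations,
with an unpenalized intercept column. Zero-padding at the lag edges keeps
every fitted series at the trial length; on 59 s trials the padded edge is a
negligible fraction, which a regression test quantifies (training-set
correlation changes by under 0.01 when 1 s edges are excluded).

Attention is decoded per window: a window is classified as attending the
talker whose actual envelope correlates more strongly with $\hat s$. Exact
ties count as incorrect. Accuracy is pooled over trials per SNR condition
and per window duration; `chance_level(2)` = 0.5 is the reference.

## Stimulus features

The stimulus side mirrors the segmentation-plus-envelope pipeline used in
speech-intelligibility work, in this order:

1. *(high-RMS variant only)* **Relative-RMS gating.** The waveform is cut
   into 16 ms Hamming-delimited blocks with 50% overlap; a block is "high"
   when its RMS is at or above the whole-utterance RMS (a relative 0 dB
   threshold, configurable via `threshold_db`), ties counting as high. A
   sample is flagged when *any* overlapping high block covers it, and
   off-mask samples are zeroed in place — the timeline is preserved so
   stimulus and EEG stay aligned.
2. **Hilbert envelope** at the audio rate (magnitude of the analytic
   signal).
3. **Anti-aliased resampling** to the 100 Hz EEG rate.
4. **Zero-phase FIR band-pass**, 150th order, into 2–8, 8–15, or 15–30 Hz;
   2–8 Hz is the analysis default since envelope tracking concentrates
   there.
5. **Per-trial z-scoring**, which makes ridge penalties comparable across
   trials and variants.

Two choices here were genuinely open and are worth recording. First, block
RMS is computed on *unweighted* samples — the Hamming window defines block
boundaries only — because the utterance-level reference RMS is unweighted
and Hamming-weighted block RMS would bias the 0 dB comparison by the
window's own RMS factor; `block_rms(weighted = TRUE)` provides the
alternative. Second, the block-to-sample rule is an OR over overlapping high
blocks, which preserves contiguous high-energy regions; an AND rule would
poke holes at block seams. Both mask decisions are covered by a brute-force
per-sample reference implementation in the tests. The comparison against the
threshold carries a relative slack of 1e-9 so that exact ties (a constant
utterance) survive floating-point summation order.

Two-talker mixtures are formed by `mix_at_snr()`: the attended stream's RMS
is the fixed reference and the ignored stream is rescaled to set the SNR, so
condition labels never change the attended stream itself.

## Synthetic data and what it does (not) show

No public recordings accompany this analysis, so validation rests on a
seeded generator with known ground truth (`synth_config()`,
`gen_dataset()`):

- **Speech-like waveforms** (`gen_speech_waveform()`): a broadband noise
  carrier multiplied by a nonnegative slow modulator (squared 2–8 Hz
  band-passed noise, winsorized at its 99th percentile, with a small floor),
  with silent gaps alternating with 0.5–1.5 s speech stretches so that
  roughly 30% of each trial is quiet. The silences make the relative-RMS
  mask nontrivial: across seeds the high-RMS fraction lands near 0.4, inside
  the broad 0.15–0.50 band one expects for running speech, and the test
  suite checks the band rather than any specific value.
- **EEG** (`simulate_eeg()`): channel $n$ is
  `topography[n] × (attention_gain · (kernel ∗ s_att) + ignored_gain ·
  (kernel ∗ s_ign))` plus white Gaussian noise. The ground-truth kernel is a
  sum of Gaussian bumps in lag (+95 ms, −165 ms, +265 ms by default) —
  smooth, parameterized directly by latency/width/gain, and peaking exactly
  where placed, which is what parameter-recovery tests need. Simulation runs
  at the 100 Hz envelope rate, not the audio rate: the encoding model is
  defined on envelopes, and this avoids million-sample convolutions.
- **Conditions**: 5 SNRs (6, 3, 0, −3, −6 dB) × 4 trials of 60 s, 64
  channels, response gains 1.0 (attended) / 0.3 (ignored). The first second
  after mixture onset is dropped from EEG and envelopes by one shared
  trimming function, leaving 59 s epochs; the nominal "60 s" decoding window
  therefore maps to the whole 59 s epoch.
- **Noise level**: `noise_sd = 600` (relative to unit-variance envelopes
  through a unit-gain kernel) was calibrated once so that single-trial
  attended-envelope reconstruction correlations land around 0.15–0.25 —
  the scale observed in real two-talker EEG — and then frozen. At this
  operating point whole-epoch decoding is near ceiling while 2 s windows
  degrade visibly, reproducing the qualitative duration effect.

What passing tests on this generator demonstrate: the estimators invert the
generative model they target (kernel recovery to r ≥ 0.999 noise-free;
attended > ignored reconstruction; chance-level behaviour when the two
streams drive the EEG equally). What they cannot demonstrate: robustness to
real EEG nuisance structure. The generator has no 1/f background, no
artifacts, no phoneme-level or linguistic structure, no reverberation or
spatial cues, and a single shared topography for all kernel components.
Accuracy figures obtained here are not forecasts for human data.

## EEG conditioning

For real recordings (and the 500 Hz fixtures in the tests): mastoid-average
re-referencing (mastoid channels dropped afterwards), 4th-order Butterworth
1–50 Hz applied forward-backward, epoching that discards the first second
after each onset, Fourier-domain downsampling to 100 Hz, then narrowband
zero-phase FIR filtering with the order rule `3 · fs / f_low` rounded to the
nearest even integer — 150 for 2–8 Hz at 100 Hz, 38 for 8–15, 20 for 15–30.
Narrowband filtering is applied per epoch rather than to the continuous
recording; edge behaviour differs slightly from the continuous-first
ordering, which is documented rather than resolved. An `artifact_hook()`
no-op is the seam where users of real data can insert component-based
artifact removal; no artifact modelling is attempted here.

## Numerical choices

- **Filters.** IIR zero-phase filtering delegates to
  `signal::filtfilt(butter(...))`. FIR zero-phase filtering mirror-pads
  three filter lengths at each end before forward-backward application, so
  start-up transients die inside the padding; the magnitude response is
  applied twice (relevant when comparing attenuation figures). Every filter
  is pulse-tested: a symmetric pulse's peak may shift by at most one sample.
- **Resampling** is Fourier-domain (spectrum truncation at the output
  Nyquist): exact for band-limited signals, O(n log n), and
  duration-preserving within one output sample. A polyphase implementation
  was considered and rejected on cost at 10^6-sample waveforms.
- **Ridge.** Solutions come from a Cholesky factorization of
  `X'X + λI` (bias unpenalized). An unpenalized rank-deficient system is
  detected via the trailing Cholesky pivot and rejected with advice to set
  λ > 0. The solver is property-tested against a literal
  `solve(X'X + λI, X'y)` oracle on random systems to 1e-8.
- **Cross-validation.** One model per trial, fold decoder = mean of the
  other trials' models (computed as sum-minus-one, so the whole scheme costs
  one factorization per trial per λ). The default grid is
  `2^0, 2^2, ..., 2^12`; the score is the held-out reconstruction
  correlation (backward) or mean predicted-EEG correlation (forward), MSE
  logged alongside; one pooled optimum per dataset; ties break to the
  smallest candidate.
- **Component extraction.** P1/P2 are window maxima, N1 a window minimum,
  on the weight profile averaged over the (user-overridable) fronto-central
  set {Fz, FCz, Cz, FC1, FC2, F1, F2, C1, C2}; on a flat profile the
  earliest lag in the window wins.
- **Degenerate inputs** error early and explicitly: all-zero utterances
  (relative threshold undefined), constant envelopes (z-score and Pearson r
  undefined), mismatched lengths or sampling rates, missing mastoids,
  lag windows off the sample grid.

## Problem sizes used in validation

The test suite and the acceptance script run the standard conditions at
their full size — 20 trials × 64 channels × 59 s for the attention
analyses, 40 trials for the null calibration (200 ten-second windows) — and
reduced sets (2–8 channels, 8–31 s trials) for unit-level checks where the
full size adds nothing. These sizes were chosen so the complete validation
runs in minutes on a laptop while keeping the statistical checks
well-powered (e.g. the null-calibration acceptance band is the exact
binomial 95% interval at n = 200).

## Known limitations

- The high-RMS analysis implements only the high/other split at a
  configurable relative threshold; middle/low-RMS segment classes are out of
  scope.
- Envelope normalization is per trial; corpus-global normalization would
  change the effective λ scale across datasets.
- Whether short decoding windows should be scored with decoders retrained
  per duration was an open choice; the whole-epoch-trained averaged decoder
  is reused for all durations (cheaper, and consistent with the
  averaged-decoder scheme).
- The EEG driver in the generator is the band-passed intact envelope; when a
  dataset is generated with only the high-RMS variant, that variant drives
  the simulation instead.
- No statistics beyond accuracy aggregation are provided (no ANOVA
  machinery, no subject-level models): synthetic datasets have a single
  "subject".
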