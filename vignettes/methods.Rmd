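---
title: "Detecting atrial fibrillation in long-term PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation in long-term PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgaf)
```

## The problem

Atrial fibrillation (AF) is the most common sustained arrhythmia and a major
stroke risk factor, but its episodes are often paroxysmal: short ECG snapshots
miss them. Photoplethysmography (PPG) — the optical pulse signal that wrist
wearables and bedside oximeters record continuously — offers a cheap long-term
alternative. The haemodynamic signature of AF in PPG is *irregular
irregularity*: inter-beat intervals with high variability and no serial
structure, plus beat-to-beat amplitude fluctuation, against the quasi-periodic
pulse train of normal sinus rhythm (NSR).

`ppgaf` implements a complete detection chain for 2-minute, 125 Hz PPG
segments:

1. **Preprocessing** — local-maxima peak detection, a 15,000-sample segment
   anchored at the first peak, min-max normalization.
2. **Decomposition** — complementary ensemble empirical mode decomposition
   (CEEMD) into intrinsic mode functions (IMFs), with coherence-based IMF
   selection.
3. **Features** — framed power spectra of the selected IMFs passed through a
   Gammatone filterbank, divided by the record's mean band power, compressed
   by a power law; six inter-beat-interval statistics appended per record.
4. **Classification** — a bidirectional LSTM with a fully-connected layer and
   a two-class softmax head, trained with Adam under a step learning-rate
   schedule.
5. **Evaluation** — per-class recall/precision/F-measure and the *ET-score*,
   which multiplies the harmonic mean of the two per-class F-measures by a
   computation-speed rank factor (fastest method 1.00, each further rank
   −0.02), so that accuracy and efficiency are judged together:

$$\mathrm{ET} = \frac{(\beta^2+1)\, F_{AF} F_{NSR}}{\beta^2 (F_{AF}+F_{NSR})}
\times \mathrm{time},\qquad \beta = 1 .$$

## The synthetic rhythm generator

Real AF-labelled PPG cohorts cannot be redistributed, so the package carries a
generator whose *defaults define the study conditions* for every test:

* **Inter-beat intervals.** Truncated normal (lower bound 0.3 s), with a
  latent AR(1) giving the lag-1 correlation. Presets: NSR mean 0.8 s,
  CV 0.04, lag-1 0.6 (respiratory sinus arrhythmia); AF mean 0.7 s, CV 0.20,
  lag-1 0 (irregularly irregular, slightly tachycardic). The 5× CV ratio is
  the conventional phenomenology; AF CV well above 0.1 and NSR well below.
* **Pulse shape.** Two Gaussian lobes — systolic at the beat time and a
  dicrotic lobe at +0.25 IBI with 30% amplitude, widths scaling with the
  interval. This matches the gross two-bump PPG morphology while staying
  fully parametric.
* **Amplitudes.** Per-beat amplitude CV 0.03 (NSR) vs 0.15 (AF), reflecting
  the beat-strength variability of fibrillation.
* **Artifacts.** 0.1 Hz sinusoidal baseline wander at 10% of pulse amplitude
  and white Gaussian noise at 2%.

What the generator does *not* emulate: motion artifacts, sensor saturation,
ectopic beats, comorbid arrhythmias, inter-patient morphology differences.
Passing the synthetic benchmark therefore demonstrates that the chain
*recovers the rhythm statistics it models* — not clinical-grade performance
on hospital data.

```{r}
rec <- generate_record(rhythm_params("AF"), duration_s = 30, seed = 1)
plot(seq_along(rec$samples[1:1250]) / 125, rec$samples[1:1250], type = "l",
     xlab = "time (s)", ylab = "PPG (a.u.)", main = "synthetic AF, 10 s")
```

## Decomposition choices

EMD internals are famously under-specified; the choices here are the standard
ones and are recorded in `emd_config()`:

* **Sifting stop**: Cauchy criterion
  $\sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.2$, at most 100 iterations.
* **Envelopes**: cubic splines through the extrema, two extrema mirrored at
  each boundary to control edge effects.
* **Termination**: residual monotonic / fewer than 3 extrema, or 12 IMFs.
* **Ensemble noise**: SD = 0.2 × signal SD. Defaults N = 20 for CEEMD and
  N = 200 for EEMD, the conventional order-of-magnitude contrast; the
  complementary ±noise pairing makes CEEMD's ensemble average reconstruct
  the input essentially exactly (the injected noise cancels term by term),
  which is why it needs ten times fewer realizations than EEMD.
* **Unequal IMF counts** across realizations are zero-padded before
  averaging — truncation would break the additive reconstruction identity.
* **IMF selection**: Pearson coherence of each IMF with the source signal,
  threshold 0.1; if nothing passes, the single most coherent IMF is kept
  (warned). A zero-variance IMF has coherence 0 by convention.

All randomness flows through one seeded generator, so every decomposition is
bit-reproducible.

## Feature chain choices

* **Framing**: 4 s frames, 2 s hop → 59 frames per 2-minute record, at least
  three beats per frame at plausible heart rates. The framed, Hann-windowed
  periodogram is used as the spectral estimator; its one-sided bins are
  energy-scaled so each frame obeys Parseval exactly (the printed limit form
  of the power spectrum is not a computable estimator; the windowed
  periodogram is the standard realization).
* **Filterbank**: 32 order-4 Gammatone filters, log-spaced centers
  0.1–20 Hz (the PPG band: heart-rate fundamentals ~0.7–3 Hz plus
  harmonics), bandwidth 0.25 × center frequency floored at 0.05 Hz, each
  filter's spectral weight vector peak-normalized to 1.
* **Power normalization** divides by the record's global mean band power
  (mean of the normalized matrix ≡ 1), making the whole chain invariant to
  positive rescaling of the waveform — sensor gain should not matter. A
  per-band option exists but is off by default.
* **Compression** uses exponent ϑ = 1/15, the classic power-normalized
  cepstrum value; any ϑ ∈ (0,1) is accepted.
* **IMF combination**: per-IMF spectra are *summed* before filtering
  (a stacked per-IMF mode is available behind `stack_imfs`); the DCT to
  cepstral coefficients is off by default — the compressed band matrix
  itself is the feature, with the option retained.
* **Time-domain features** (per record, broadcast to every frame at the
  network input): mean IBI, SD of IBI, RMSSD, pNN50, Shannon entropy of the
  8-bin IBI histogram, and peak-amplitude CV.

## Network and training

The classifier is a sequence-to-label BiLSTM written from first principles in
base R (forward pass, backpropagation through time, Adam), verified against
finite-difference gradients in the test suite. Defaults: 64 hidden units per
direction, FC width 32, batch 16, initial learning rate 0.01525, drop factor
(LRDF) 0.5 every 10 epochs, at most 100 epochs. The learning rate at epoch
$e$ is exactly $\omega\,\mathrm{LRDF}^{\lfloor (e-1)/10\rfloor}$.

Features are scaled by their training-set column maxima (inputs are
nonnegative, so the input ReLU stays an identity and scaling cannot leak sign
information). The final forward and backward hidden states are concatenated
and passed through the FC layer to the softmax; label order is fixed
(NSR = 0, AF = 1) and exact probability ties resolve to NSR — the
conservative direction for a screening tool is debatable, but a deterministic
tie-break matters more than its direction at double precision.

The learning-rate range test increases the rate geometrically batch by batch,
retains each batch's loss, smooths with a 5-point moving average, truncates
at divergence, and suggests the rate at the first minimum of the smoothed
curve — the descending-branch minimum. On a quadratic surrogate this lands
near the inverse curvature, inside the classical stability interval
$(0, 2/a)$.

## Evaluation conventions

Percentages are carried at full precision and rounded half-up to two decimals
only at report boundaries. The speed factor is applied as a fraction
(rank factor / 100): with equal per-class F-measures and rank 1 the ET-score
equals that F-value, which is the reading consistent with the published
worked examples. Measured wall times are accepted for ranking but never
asserted in tests — they are hardware facts, not method properties; ranks can
be supplied directly.

## Problem sizes in the test suite

Unit tests run on short records (30–60 s, ensemble N = 2) so the suite stays
interactive. The end-to-end benchmark trains on 100 records and tests on 50
(2-minute segments, N = 8, 64 hidden units, 30 epochs) — large enough for
stable class separation, small enough for a single CPU. The duration sweep
helper (`duration_sweep()`) reports, but does not assert, metrics for 1/2/5
minute records, since the trade-off it probes is partly a timing property of
the host machine.

## Known limitations

* EMD is an empirical algorithm: IMF boundaries and counts can shift with
  tiny input perturbations; only ensemble averages and reconstruction
  identities are asserted, not per-IMF equality across platforms.
* The pure-R network is practical at desk scale (hundreds of records), not
  cohort scale; the architecture is deliberately small.
* The WFDB reader supports the common single-`.dat`, format-16 layout only.
* Synthetic AF vs NSR is an easier discrimination than hospital PPG with
  comorbidities; headline accuracies here bound the pipeline's mechanics,
  not clinical performance.
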