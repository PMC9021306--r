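---
title: "Paired-round glucose estimation from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-round glucose estimation from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Noninvasive blood-glucose estimation from finger photoplethysmography
(PPG) rests on a weak physiological signal: pulse-waveform morphology
varies with glucose through hemodynamic factors, but it also varies — far
more strongly — between people and, within a person, over months. A
personalized model trained on a handful of measurement *rounds* (one
fasting session with two 1-minute PPG replicates and one finger-prick
reference value each) therefore faces two obstacles: very little training
data, and slow morphological drift that is unrelated to glucose.

`glucopair` implements a paired-input formulation of this problem. Instead
of mapping one recording directly to its glucose value (the conventional
single-channel model, called **IL** throughout), the central regressor —
called a *differential cell* by analogy with a differential amplifier —
takes a **two-channel** input: an analysis window from the current round
and one from the preceding round, plus the preceding round's *measured*
glucose as a scalar baseline. Writing \(S_i\) for the round-\(i\) signal
and \(BG_i\) for its reference value, training accumulates the pair losses

\[
\sum_{i=2}^{N} \mathcal{L}\!\left[f(S_i, S_{i-1}, BG_{i-1}),\; BG_i\right],
\]

and deployment predicts a later round \(k\) by pairing it with the last
training round: \(\widehat{BG}_k = f(S_k, S_N, BG_N)\). The network only
has to learn how glucose *changes* express themselves in waveform
*differences*, anchored to a recent ground-truth value — a much easier
target than the absolute mapping when data are scarce and morphology
drifts. The screened variant (**DL+S**) adds a two-stage confidence filter
described below.

## Pipeline

1. **Band split** (`split_bands`). A raw recording is separated into a
   baseline-wander part below 0.75 Hz and the pulsatile remainder by an
   order-4 Butterworth low-pass applied forward and backward (zero phase,
   so pulse timing is preserved), in two passes: a single zero-phase pass
   still leaves ~8% of a 60-bpm beat fundamental (1 Hz) in the wander
   estimate, which measurably distorts pulse morphology at the low end of
   the heart-rate range, and raising the filter order instead is
   numerically unstable at a normalized cutoff of 0.006. The high band is
   defined as the exact residual `raw - low`, making the decomposition
   additive to machine precision. R's `signal::filtfilt` applies no edge
   treatment, so the series is padded by odd reflection over `3 / cutoff`
   seconds before filtering; even so, the outermost seconds of a
   recording keep visible transients (see *Numerical choices*).
2. **Pulse annotation** (`bfss_annotate`). Every PPG pulse ends in the
   largest amplitude drop of the beat (peak to the immediately following
   valley — the "bigger fall side"). All (local maximum, next local
   minimum) pairs are formed, the 30th-largest drop is taken as the
   representative value `mbfss` (with fewer than 30 falls, the median
   drop), and falls within \([0.5, 1.5] \times\) `mbfss` (inclusive) are
   accepted. Spurious micro-extrema from noise or residual drift produce
   drops far below the band and are discarded. The rule presumes a
   recording with at least ~30 genuine beats (a 1-minute recording at
   60–90 bpm); on much shorter recordings the 30th-largest drop can land
   on a micro-fall and the annotation degenerates — the package keeps the
   published rule and documents the limit rather than patching it.
3. **Windows and features** (`extract_windows`, `morph_features`). From
   each accepted valley a 400-sample window (1.6 s at 250 Hz) is taken
   backwards. Six morphological features of the window's last complete
   pulse — heart rate, area under the curve, and the pulse widths at 0%
   (full width), 25%, 50% and 75% of peak amplitude — are prepended to the
   400 samples, giving a 406-element model input vector.
4. **Pairing** (`build_dl_samples`). Each window of round \(i\),
   replicate \(k\) is paired with a window drawn uniformly at random, with
   replacement, from the *same replicate* of round \(i-1\). Pairing uses a
   deterministic per-(subject, round, replicate) RNG substream, so adding
   data elsewhere never perturbs existing pairings. With replacement is
   the natural choice because window counts differ between rounds.
5. **Regressor** (`build_network`, `train_model`). Five 1-D convolution
   units (kernel 3, same padding, ReLU, max-pool 2) with 256, 256, 512,
   1024, 2048 filters at full scale; flatten; merge of the baseline
   glucose scalar (two-channel mode); batch normalization; a 4096-unit
   ReLU dense layer; a linear output unit. MSE loss, Adam optimizer. At
   full scale this is ≈ 1.09 × 10⁸ trainable parameters; the `scale`
   divisor shrinks every filter count and the dense width so the identical
   architecture trains on a desktop CPU (scale 32 → 8/8/16/32/64 filters,
   dense 128, ≈ 1.1 × 10⁵ parameters).
6. **Screening** (`validation_confidence`, `test_spread`). *Stage 1*
   gates the model: leave-one-out cross-validation over the training
   rounds yields pooled predictions whose Clarke-zone counts give the
   confidence score \(S_V = 100 \sum w_i C_i / \sum C_i\) with weights 1
   (zone A), 0.5 (B), 0 (C/D/E); the model is rejected when \(S_V\) is
   below 50 (test round < 7) or 60 (round ≥ 7). *Stage 2* filters
   individual predictions: the final model is retrained \(N = 5\) times
   with different seeds; after removing one maximum and one minimum, the
   spread score \(S_T = \sqrt{\mathrm{SS}/(N-1)}\,/\,\mathrm{median}\) of
   the retained predictions must stay below \(y = 0.07\), in which case
   the retained median is the accepted prediction. The threshold can be
   re-derived from data with `roc_threshold`, which scores candidate
   thresholds by TPR/FPR against a "both replicates clinically accurate"
   truth label and picks the point nearest the (0, 1) corner.
7. **Evaluation** (`ceg_zone`, `error_metrics`). Clarke Error Grid zones
   (rules evaluated in the fixed order A, E, C, D, else B, with
   boundary-inclusive comparisons, which makes the classification total
   and exclusive), MAE, RMSE, sample Pearson correlation, and a
   per-prediction accuracy score.

## The synthetic-data generator

Real cohorts for this problem are private, so the package ships a
generator (`generate_subject`) whose defaults are the study conditions the
rest of the package is exercised under: 250 Hz sampling; 1.6 s flat
lead-in, 60 s pulse train, 0.8 s lead-out (so the final valley is
detectable); heart rate drawn per round from 60–90 bpm; two replicates per
round; 6–15 rounds; reference glucose a bounded random walk in
80–350 mg/dl (steps of SD 40 mg/dl, reflected at the bounds).

Each beat is a single asymmetric lobe — a cosine shape blended with a 25%
tent component, with a fast rise (one third of the period) and a slower
fall — raised to a power solved numerically so its width at half maximum
equals `width_fraction` × period. The tent component keeps the
inter-beat valleys V-shaped, as diastolic turns are in real PPG; a
flat-bottomed valley would make the detected minimum ill-conditioned.
Glucose couples to morphology through the width:

\[
w_r = w_0 \cdot d_r \cdot \left(1 + c\,\frac{BGL_r - BGL_1}{100}\right),
\]

with base width \(w_0 = 0.4\), coupling \(c\) (default 0.1 per
100 mg/dl), and a multiplicative random-walk drift \(d_r\) (SD 0.02 per
round). The drift term is deliberate: it injects the glucose-*unrelated*
slow morphological change that makes absolute-morphology (single-channel)
modelling hard in practice; without it the synthetic task would be
unrealistically easy for the IL baseline. Baseline wander is a sinusoid
below the 0.75 Hz cutoff (default 0.2 Hz, amplitude 0.5, random phase per
round, shared by both replicates). Measurement noise is Gaussian,
low-passed at 8 Hz and rescaled to `noise_sd` (default 0.02): a PPG analog
front end band-limits its output, and unfiltered white noise at 250 Hz
would fragment the local-extrema sequence in a way real recordings do not.
Replicates of a round differ only in the noise realization, and the whole
subject is reproducible from one integer seed.

What the generator does **not** emulate: optical/hemodynamic physics,
motion artifacts, arrhythmia, beat-to-beat amplitude variability,
replicate-specific reference values, or any nonlinearity in the
glucose–morphology link. Passing tests on this generator therefore show
that the pipeline recovers a *planted* coupling under realistic nuisance
structure — not that the physiological coupling exists or is this strong
in real subjects.

## Numerical choices

- **Filter edges.** Zero-phase filtering settles over several multiples
  of `1 / cutoff`; despite reflection padding, beats within ~5 s of
  either recording edge show distorted valleys and widths (errors up to
  tens of percent at the edges versus ≤ 0.2% in the interior). All
  width-recovery checks in the test suite measure interior beats only.
- **Widths.** A width at fraction \(q\) is the total duration where the
  baseline-corrected pulse stays ≥ \(q\) × peak amplitude, with linear
  interpolation at threshold crossings; the baseline is the smaller of
  the two bounding valley amplitudes (keeps the AUC non-negative and
  drift-insensitive). The full width (\(q = 0\)) is the valley-to-valley
  duration, and heart rate is 60 / that duration, computed per window.
- **Extrema.** Plateaus contribute their first sample; detected maxima
  and minima strictly alternate by construction. Pool ties route to the
  first slot; max/min trimming in the spread score removes exactly one
  instance of each.
- **Spread score.** Implemented literally as published: deviations summed
  over the \(N-2\) retained values, divisor \(N-1\), mean and median both
  over the retained set. The conventional sample variance (divisor
  \(N-3\)) is available via `st_divisor = "conventional"`.
- **Confidence scale.** The zone-weighted score is reported on a 0–100
  scale; the 50/60 thresholds are only meaningful on that scale.
- **Accuracy score.** The literal published expression
  \(|((p-r)/r)-1| \times 100\) exceeds 100 for any underprediction; the
  package defaults to the symmetric form \(100\,(1 - |p-r|/r)\) and keeps
  the literal one as `mode = "as_printed"`.
- **Pearson correlation.** The printed formula omits the \(1/n\) factors
  inside the denominator radicals; the standard sample correlation is
  used (`stats::cor`), cross-checked against the explicit formula in the
  tests.
- **Training.** Targets are standardized to zero mean / unit variance
  during training and de-standardized at prediction (`target_scaling`,
  on by default) — pure conditioning, so Adam makes progress at mg/dl
  scale within tens of epochs instead of thousands. The baseline glucose
  is merged raw (mg/dl); `baseline_scale` can rescale it. Batch-norm uses
  batch statistics during training and running statistics (momentum 0.1)
  at prediction. Training is deterministic for a fixed seed on one CPU;
  backpropagation is verified against finite differences in the tests.
- **Accumulated training.** Training "through round N" pools the sample
  sets of all \(N-1\) adjacent-round pair tasks and trains one network on
  the union. This reading makes the result independent of task order, so
  pair-task construction may be parallelized without changing results.
- **Cross-validation folds.** A paired fold holds out round \(j\) as the
  *target*: the \((j-1, j)\) pair leaves the training set, round \(j\) is
  predicted paired with round \(j-1\), and round 1 is never a fold target
  (it has no predecessor). Other pairs involving round \(j-1\) as a
  source remain in training — target leakage is what matters.

## Desk-scale problem sizes

The test suite and examples run the architecture at `scale = 32` (and
smaller), 40 epochs, batch 128, Adam 3 × 10⁻³, on subjects of 6–10 rounds
with 30–60 s recordings. These sizes were chosen as the package's
desk-scale study conditions: large enough for the paired model's advantage
to be measurable (the suite's method-comparison check runs three seeds of
IL versus DL on identically generated 10-round subjects with coupling 0.15
and compares median held-out RMSE), small enough that the whole suite runs
on one CPU in well under half an hour. Full-scale settings (scale 1,
batch 3000, up to 1000 epochs) are valid configurations but are not
exercised by the tests.

## Known limitations

- The BFSS annotation inherits the published rule's assumption of ≥ 30
  genuine beats per recording; it degenerates on shorter recordings.
- The spread-score divisor \(N-1\) over \(N-2\) retained values is kept
  as published even though it is not a textbook variance; both variants
  are exposed.
- Whether real reported accuracy used the literal or symmetric accuracy
  score cannot be determined from the text; both are provided.
- The simulator's glucose–width coupling is linear and deterministic;
  real couplings are at best weak and confounded, so absolute error
  levels on synthetic data say nothing quantitative about clinical
  performance.

```{r example}
library(glucopair)
ds <- generate_subject(sim_config(n_rounds = 10, seed = 1))
plan <- experiment_plan(ds, method = "DL+S", training_rounds = 8,
                        test_rounds = 9:10, seed = 1)
res <- run_experiment(plan, verbose = TRUE)
print(res)
```
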