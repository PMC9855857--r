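---
title: "Methods: recognising attentional focus from multichannel surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognising attentional focus from multichannel surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During free-weight strength training, deliberately concentrating on the
contracting muscle ("attentional focus") measurably increases muscle fibre
activation. A wearable 8-channel surface-EMG garment — electrode pairs over
the chest, shoulders, triceps and biceps — records muscle activity while a
subject performs five standard dumbbell exercises (bench press, pullover,
front raise, kickback, biceps curl) at three loads (no weight, 67% and 85%
of the one-repetition maximum, 1RM) with and without attentional focus.
`emgfocus` implements the complete recognition pipeline for such
recordings: movement segmentation, feature extraction, a multitask neural
classifier for the three labels (exercise, focus, load), baseline models,
evaluation, and an RMS-based contraction analysis.

Because no public recordings of this kind exist, the package includes a
first-class synthetic session generator that emulates the acquisition
protocol; every statistical claim the test suite makes is made against that
generator's known ground truth.

## Signal model and segmentation

Raw samples are integer ADC codes in $[0, 4096]$. Every channel is
normalized by the fixed full-scale divisor 4096 — *not* per-recording
min–max, so amplitudes stay comparable across sessions. The eight channels
are averaged, high-pass filtered at 1 Hz (4th-order Butterworth, applied
forward-and-backward so detected boundaries are not phase-shifted; the
filter realization is config-exposed), and scanned with 0.25 s frames at a
0.1 s step. Frame energy is the plain sum of squared samples in the frame.

A movement runs from the first frame whose energy exceeds the onset
threshold $\xi$ to the first frame that falls back below it. Candidates
shorter than 1.5 s, or whose maximum frame energy stays below the retention
threshold $\delta$, are discarded; frame indices map to time as
$t = f \times 0.1\,\mathrm{s}$, and surviving boundaries are extended
outward by 0.15 s (in time units at the actual sampling rate), clipped to
the recording. A run still above $\xi$ at the end of the record is closed
at the last frame.

$\xi$ and $\delta$ have no universal values; they depend on the noise
floor. `auto_threshold()` calibrates them from the first 0.5 s of rest that
the protocol guarantees before the first repetition:
$\xi = k_1 \times \mathrm{median\ rest\ frame\ energy}$ (default $k_1 = 4$)
and $\delta = k_2 \xi$ (default $k_2 = 2$). With the generator's default
noise floor, burst frame energies exceed $\xi$ by a factor of roughly
twenty-five even in the weakest condition (unweighted pullover), which is
why recovery of all 12 bursts per session is essentially exact; both
constants are parameters of `segmentation_params()` and every run reports
the thresholds used. An all-zero rest falls back to an absolute floor of
1e-8.

## Features

Each segment yields 56 features: per channel, in fixed order — RMS,
waveform length (cumulative absolute first difference), mean absolute
value, variance (zero-mean form $\sum x_i^2/(N-1)$, appropriate because the
signal is high-passed; an exact-mean variant sits behind a flag),
thresholded zero crossings (default threshold 0.01 normalized units,
calibrated to sit above the generator's noise floor; 0 disables it), and
the modified median and mean frequencies. "Modified" means both spectral
statistics are computed on the one-sided *amplitude* (not power) spectrum:
MMDF is the smallest bin at which the cumulative amplitude reaches half the
total (with a 1e-9 relative tolerance so an exact half-split resolves to
the lower bin), MMNF is the amplitude-weighted centroid. The DFT is
un-windowed by default (a Hann taper is available): segments are long
(≥ 1.5 s) and band-limited, so leakage is immaterial at the 1 Hz bin
scale. Features are computed on the same conditioned signal the
segmenter uses (normalized, high-passed per channel).

## The multitask network

The classifier is a three-headed network sharing one trunk:

* trunk: dense 56→64 (sigmoid) → dropout 0.5 → dense 64→32 (sigmoid);
* three branches, one per task, each dense 32→32 (sigmoid);
* classification layers: softmax over 5 (exercise), 2 (attention),
  3 (load).

Hidden layers are sigmoid throughout; the output layers use softmax because
the loss is categorical cross-entropy, which needs a normalized
distribution. The total loss is the weighted sum
$\mathcal{L} = \sum_t \omega_t \mathrm{CE}_t$ with $\omega_t = 1$ — the
three tasks are equally important. Optimisation is Adam at learning rate
0.001, batch size 16.

**Fusion layer.** Different exercises at different loads can produce EMG of
similar overall energy (a light bench press can match a heavy front raise),
so load is not identifiable from energy alone. The load head therefore
receives, concatenated to its 32 branch features, the *output probability
vectors* of the exercise and attention heads (input width 32+5+2 = 39),
conditioning the load decision on what movement was performed and whether
it was focused. Probabilities (not logits) are fused, and by default the
fused inputs are detached — the load loss does not backpropagate through
them, so it cannot degrade the donor heads; `detach_fusion = FALSE`
enables joint backprop (the analytic gradient through the donor softmax is
implemented and verified against finite differences in the test suite).

**Training regime.** Models are trained per subject — muscle geometry and
skin impedance make absolute feature scales subject-specific. Features are
z-scored with training-split statistics (sigmoid trunks saturate on raw
magnitudes). The default split assigns, within every 12-repetition
session, 8 repetitions to training, 2 to validation and 2 to test by a
seeded shuffle, so every condition appears in every split; a plain
70/15/15 fractional mode is also provided. Model selection takes the epoch
with the best validation combined loss; training runs at most 600 epochs
with an early stop after 60 epochs without validation improvement. (A
fixed 200-epoch budget was considered and rejected: at 200 epochs the
validation loss on default synthetic subjects is still clearly
decreasing, so the stopping point is left to the validation split.)
Everything — initialisation, shuffling, dropout — is driven by one seed,
and two runs with the same seed produce identical weights.

**Baselines.** A one-vs-one RBF SVM per task (defaults $C = 1$, $\gamma =
1/(56 \cdot \overline{\mathrm{var}})$, with a small grid-search utility),
and single-task networks: the same trunk+branch trained with one task's
loss only, the load variant without fusion.

## Evaluation

Confusion matrices are accumulated per task at repetition level; precision
(positive predictive value), recall, specificity (true negative rate) and
accuracy are derived per class with macro averages (the averaging rule for
multi-class summaries is macro, stated explicitly since single-number
summaries are otherwise ambiguous). Zero-denominator metrics are reported
as undefined (`NA`), never as 0. Majority voting aggregates repetition
predictions to one label per subject-condition block (or per session —
both levels are exposed, since the study-level aggregation could be read
either way); ties break toward the lower class index and are flagged.

## Contraction analysis

Muscle contraction per movement is the RMS of the channel-averaged
conditioned segment. Contrasts compare mean segment RMS with vs without
attentional focus at each load, per subject or per exercise, with a paired
two-sided Wilcoxon signed-rank test across repetition-matched segments
(chosen over a paired t-test because RMS distributions are skewed; the
test is selectable). Each group is flagged when focused 67%-1RM lifting
out-contracts unfocused 85%-1RM lifting — the qualitative signature that
focused low-intensity training can activate more muscle than unfocused
heavy training. Contrasts are computed on segment-level RMS (not
per-repetition maxima), and no maximal-voluntary-contraction normalization
is applied (the emulated protocol has no MVC reference).

## The synthetic generator

Each repetition is a burst of band-limited Gaussian noise under a Hann
amplitude envelope — an amplitude-modulated Gaussian process, which is
exactly the model under which RMS measures contraction. Defaults mirror
the emulated protocol: 12 subjects, 5 exercises × 3 loads × 2 attention
conditions × 12 repetitions (360 per subject, 72 per exercise), 2.5 s
bursts separated by 1 s of rest, 1000 Hz sampling, codes clipped to
$[0, 4096]$ around mid-scale 2048.

Structure, all config-exposed:

* **Channel activation profiles** per exercise (chest/shoulder/triceps/
  biceps electrode pairs); channels with gain ≥ 0.8 are the exercise's
  *target* channels.
* **Load gains** 0.5 / 0.7 / 1.0 for 0% / 67% / 85% 1RM.
* **Attention** multiplies target channels by 1.3 *and* shifts the burst
  band (20–150 Hz) upward by 10%. The spectral component is part of the
  default attention model: focused contractions recruit at higher rates,
  and with an amplitude-only effect the attention gain (1.3) would be
  nearly collinear with the load step (1.4) — the Bayes error of the
  attention task would be ~10% and no classifier could reach the
  recognition rates the emulated study design presumes. Setting
  `attention_band_shift = 0` restores the amplitude-only model (used by
  the null-calibration tests).
* **Cross-exercise ambiguity**: per-exercise amplitude multipliers
  $1 + \mathrm{overlap} \times d_e$ (directions +0.6, −0.25, +0.6, −0.25,
  0) move one exercise's 67%-1RM energy onto another's 85%-1RM energy as
  `ambiguity_overlap` grows (at 0.6 the front raise at 67% lands on the
  biceps curl at 85% in channel-averaged energy) — the identifiability
  problem the fusion layer exists to solve. Default 0.3.
* **Heterogeneity**: per-subject lognormal channel gains (sd 0.1) and
  per-repetition lognormal amplitude jitter (sd 0.08) shared across
  channels, mimicking common-drive variation in effort.
* **Noise floor**: 4 ADC codes sd of white jitter everywhere.

Amplitude scale (700 codes) keeps the strongest condition within ~2.3 sd
of the ADC rails (mild clipping, as real front-ends exhibit) while the
weakest condition's burst frame energy still clears the auto-calibrated
onset threshold with a ~25× margin.

What the generator does **not** model: motor-unit action-potential trains
and recruitment/firing-rate microstructure, electrode-skin impedance
drift, movement artefacts, inter-channel crosstalk, fatigue within a
session, and day effects across sessions. Passing tests on this generator
therefore demonstrate that the pipeline's machinery is correct and that
the classifier can exploit the kinds of structure the study design
presumes — not that these accuracy levels would transfer to real
recordings.

## Numerical choices and degenerate inputs

* The mean is removed before high-pass filtering: the filter kills DC
  anyway, but filtering around zero avoids the boundary transient a
  forward-backward filter injects when the record sits at mid-scale.
* Generator noise is spectrally shaped in the frequency domain with the
  4th-order Butterworth band-pass magnitude response (linear shaping
  preserves Gaussianity; FFT lengths are padded to 2-3-5-smooth sizes).
* True-class probabilities are clamped at 1e-12 inside the loss; all-zero
  windows define MMDF = MMNF = 0 with a warning; empty segment lists,
  empty frame sequences and missing contrast cells are valid, flagged
  results, not errors.
* Argmax ties in prediction and majority voting break toward the lower
  class index, deterministically.
* A session with fewer than 12 detected repetitions is a split error
  naming the session (the per-session 8/2/2 split needs all 12); sessions
  with more send the surplus to training.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the default study conditions but
per subject: label-recovery and fusion-benefit checks train on single
synthetic subjects (360 repetitions each, 5 replicate seeds, median
reported), segmentation recovery uses 200 seeded sessions across all 30
conditions, and the Wilcoxon null calibration uses 1000 independent
session pairs with ground-truth burst windows (the calibration concerns
the test's level, not the segmenter). These sizes were chosen as the
smallest at which the medians and rates being asserted are stable.

## Known limitations

* Synthetic-only validation; see the generator's non-goals above.
* On the synthetic generator the fusion ablation is a wash: fused and
  non-fused multitask models reach the same median load accuracy (~0.95)
  under strong cross-exercise ambiguity (`ambiguity_overlap = 0.6`).
  Inspection shows why — every residual load error is a within-exercise
  adjacent-load confusion made while the exercise head is simultaneously
  correct. The channel activation profiles make exercise identity
  trivially decodable from the same 56 features, so the shared trunk (and
  even a load-only single-task network) learns exercise-conditioned load
  boundaries implicitly, and the explicit fusion wiring adds nothing the
  trunk did not already provide. The fusion layer's value should be
  expected on data where movement identity is *not* redundantly encoded —
  the fused architecture, its detached/joint gradient paths and its wiring
  are all verified independently in the test suite.
* The per-subject model cannot generalise across subjects by design; no
  transfer or pooling is implemented.
* `auto_threshold()` requires leading rest; recordings that begin
  mid-movement need explicit thresholds.
* The network is a plain dense architecture on engineered features; no
  convolutional or recurrent variants are provided.
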