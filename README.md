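# emgfocus

Recognising **exercise type**, **attentional focus** and **lifted load
(%1RM)** from 8-channel surface electromyography recorded during
free-weight strength training — and quantifying how much more muscle
contraction focused training produces.

The package is aimed at wearable-sensing and exercise-physiology work with
burst-structured multichannel sEMG: it takes raw ADC-code recordings (or
synthesises them), cuts them into single movements, builds a 56-dimensional
feature representation, and trains a per-subject multitask neural network
whose load head is *fused* with the other two heads' outputs.

## Method at a glance

**Segmentation.** Channels (codes in [0, 4096]) are normalized by the fixed
full-scale 4096, averaged, high-passed at 1 Hz, and scanned with 0.25 s
frames at a 0.1 s step. A movement runs while frame energy (sum of squares)
exceeds a threshold ξ; candidates shorter than 1.5 s or with maximum energy
below δ are dropped; boundaries map to time as t = f × 0.1 s and are
extended by 0.15 s. ξ and δ are auto-calibrated from leading rest.

**Features.** Per channel: RMS, waveform length Σ|xᵢ₊₁ − xᵢ|, mean absolute
value, zero-mean variance Σxᵢ²/(N−1), thresholded zero crossings, and the
modified median/mean frequencies of the one-sided *amplitude* spectrum —
8 channels × 7 features = 56.

**Classifier.** A shared sigmoid trunk (56→64→dropout→32) feeds three
branches (32 each) with softmax heads: exercise (5), attention (2), load
(3). The load head's input is the concatenation of its branch features with
the exercise- and attention-head probability vectors (32+5+2 = 39): EMG
energy alone does not identify load across exercises, so the load decision
is conditioned on the other two tasks. Training minimises
ℒ = Σₜ ωₜ·CEₜ (ωₜ = 1) with Adam (lr 0.001), per subject, on an 8/2/2
repetition split within every 12-repetition session.

**Contraction analysis.** Per movement, RMS = √(1/N Σxᵢ²) of the
channel-averaged conditioned segment; with/without-focus contrasts at each
load use a paired Wilcoxon signed-rank test, flagging groups where focused
67 %-1RM lifting out-contracts unfocused 85 %-1RM lifting.

Because recordings of this kind are not publicly deposited, the package
ships a synthetic session generator (Hann-enveloped, band-limited Gaussian
bursts with exercise-specific channel activation profiles, load/attention
gains and a controllable cross-exercise load-energy ambiguity) that serves
as ground truth for the whole test suite. See the methods vignette
(`vignettes/emgfocus-methods.Rmd`) for the model, defaults and limitations.

## Worked example

```r
library(emgfocus)

# one synthetic subject at the default study conditions:
# 5 exercises x 3 loads x 2 attention conditions x 12 repetitions
cfg   <- generator_config(n_subjects = 1, seed = 41)
recs  <- generate_study(cfg, subjects = 1)
feats <- featurize_study(recs)          # 360 rows x 56 features + labels
model <- train_subject(feats, network_config(seed = 41))
report <- evaluate_model(model, feats, model$splits$test, vote_by = "subject")
cat(report$exercise$metrics$accuracy,
    report$attention$metrics$accuracy,
    report$rm$metrics$accuracy, "\n")
#> 1 1 0.9333333
```

The three numbers are test-split accuracies for exercise, attentional focus
and %1RM on the held-out 2 repetitions per session (60 of 360): exercise
and attention are recovered perfectly, load at 0.93 — errors sit between
adjacent loads whose amplitude ratio (1.4) is only a few times the
generator's repetition-to-repetition jitter. The contraction side:

```r
segs <- unlist(lapply(recs, detect_segments), recursive = FALSE)
ct <- condition_contrast(contraction_records(segs), by = "exercise")
head(ct[, c("group", "load", "mean_with", "mean_without", "p_value")])
```

shows, per exercise and load, higher mean contraction RMS with focus and
paired-Wilcoxon p-values across the 12 repetition pairs.

A command-line wrapper over the same functions is installed at
`inst/cli/emgfocus.R` (subcommands `simulate`, `segment`, `train`,
`evaluate`, `contraction`, `all`).

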