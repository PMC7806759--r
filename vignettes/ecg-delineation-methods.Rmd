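---
title: "Methods: ECG delineation as 1D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG delineation as 1D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Delineation of the electrocardiogram means locating, for every heartbeat,
the onset, peak and offset of the P wave, the QRS complex and the T wave.
`ecgdelnet` frames this as one-dimensional semantic segmentation. Per lead
`ℓ` of record `r`, the annotations are encoded as a three-channel binary
mask

    B[n] = 1  if n ∈ [w_on[m], w_off[m]] for some annotated wave m,
           0  otherwise,

with one channel per wave type (channels may overlap across types; sample
indices are 0-based and intervals are closed on both ends, so a wave with
`on = 10`, `off = 20` occupies exactly 11 samples). A fully convolutional
U-Net maps the sampled voltage trace to three per-sample occupancy
probabilities; decoding a thresholded mask back to fiducials (each maximal
run of ones becomes one wave) yields the predicted delineation with no
further post-processing.

The network is the classic encoder/decoder with skip connections, adapted
to 1D: all convolutions are one-dimensional with zero padding (`same`
resolution), `levels` (L) resolution levels are connected by max-pooling
and nearest-neighbour upsampling of factor 2, channel width doubles after
each downsampling step — level `l` carries `2^l * N` channels — and a stem
convolution lifts the input to width `N` right after the input. Each level
stacks `CB` convolutional blocks. Three block types are available, written
as compositions of convolution `C` (or depthwise-separable convolution
`S`), nonlinearity `N` (ReLU) and regularizer `R`:

* vanilla: `y = C(R(N(C(R(N(x))))))`
* residual: `y = C(R(N(C(R(N(x)))))) + x`
* xception: `y = S(R(N(S(R(N(x)))))) + x`

with a pointwise projection on the skip path when input and output widths
differ. The regularizer `R` applies spatial dropout (whole-channel
dropout) followed by batch normalization; both are individually
switchable. The final block is a 1x1 convolution with a sigmoid, emitting
3 channels. Fixed settings follow the usual choices for this family:
kernel size 3, pool size 2, ReLU activations with a sigmoid head, soft
Jaccard loss, Adam, and a default seed of 1234.

Note that the block composition applies the nonlinearity directly to the
raw block input (also for the first block after the stem); this literal
ordering is kept for comparability across block types.

## Loss, optimization and training protocol

The loss is the smoothed (soft) Jaccard index averaged over channels,

    J_c = (Σ p·t + ε) / (Σ p + Σ t − Σ p·t + ε),   loss = 1 − mean_c J_c,

with ε = 1. It is scale-free per channel, so no class re-weighting is
applied. Optimization uses Adam (default learning rate 1e-3 for general
use; the bundled experiments use 2e-3, batch size 16). Training samples
random fixed-length windows (default 512 samples ≈ 2 s at 250 Hz,
divisible by `2^(L−1)`) from each record every epoch. Two inference
strategies exist: *single-lead* (each lead is an independent sample
through a 1-channel model, one mask per lead) and *multi-lead* (leads
stacked as input channels, one mask).

Two numerical choices deserve mention:

* **Input normalization.** Every lead is z-normalized per record before
  entering the network (training and inference alike). Ambulatory leads
  differ in gain and polarity; without a common scale the batch-norm
  statistics must average over a multimodal input distribution, which
  destabilizes small models.
* **Output prior initialization.** The bias of the final convolution is
  initialized to `logit(0.1)` rather than 0. Under the Jaccard loss a
  low-coverage channel (typically the P wave) can otherwise collapse to
  an all-ones prediction early in training, after which the saturated
  sigmoid provides almost no gradient to escape.

**Subject-wise cross-validation.** Because beats within a recording and
across its leads are highly redundant, folds are split by *subject*: all
windows, leads and beats of a subject stay on one side of every fold.
`make_folds()` shuffles subjects under a seed and partitions them into
`k = 5` near-equal test sets; leakage is impossible by construction and
is additionally asserted in the test-suite over a thousand seeds.

**Semi-supervised pre-training.** When plentiful automatic ("low-quality")
labels exist alongside scarce expert ("high-quality") ones, the model can
be trained from scratch on the low-quality labels without augmentation
(stage 1) and then fine-tuned on the high-quality labels (stage 2),
keeping identical fold assignments across both stages.

## SNR-calibrated data augmentation

Six additive noise sources are calibrated against the input power
`P_s = mean(x²)` to a requested signal-to-noise ratio via
`P_n = P_s / 10^(SNR/10)`:

* **AWGN** — i.i.d. normal with variance `P_n`;
* **RS** (random spikes) — the 5-tap template `[0, 0.15, 1.5, −0.25,
  0.15]` plus fresh per-tap uniform noise U(−0.25, 0.25), scaled by
  `sqrt(P_n/f)` and stamped every `1/f` seconds at a uniformly drawn
  phase;
* **AS** (amplifier saturation) — clipping at `S_v = p·max|x|`;
* **PN / BW** (powerline / baseline wander) — the cosine
  `sqrt(2 P_n)·cos(2πfn/f_s)` at 50 Hz and 0.5 Hz respectively (its
  power is exactly `P_n` over integer periods);
* **PS** (pacemaker spikes) — the constant `sqrt(P_n/f)` on a 1-sample
  neighbourhood immediately before each QRS onset.

Generator hyperparameters receive uniform jitter `value + U(±SNR/10)` to
maximize input variability. Because the composition of sources is a free
choice, the default policy applies each source independently with
probability 0.25, at most 3 concurrently, with SNR drawn uniformly from
5–30 dB per invocation; all of this is configuration. Frequency-like
rates for RS/PS are interpreted in events per second and converted by
`f_s`, consistent with the `f/f_s` usage of the sinusoidal sources. The
RS normalization `sqrt(P_n/f)` is implemented literally; its realized SNR
depends on spike sparsity and is deliberately not re-calibrated
empirically. Augmentation never alters the labels.

## Synthetic data generator

The generator exists so that every component is testable against exactly
known ground truth without downloading data. A beat is a sum of smooth
Gaussian deflections: one bump for P, three narrow alternating-sign bumps
(Q, R, S) for the QRS complex, one wider bump for T. Onset and offset of
each wave are *measured* on the sample grid as the first/last sample
where that wave's own component exceeds 5% of its own peak magnitude —
unambiguous and resolution-independent — and the peak is the extremal
sample. Records place beats at RR intervals drawn around a target heart
rate (5% jitter), perturb template amplitudes/widths multiplicatively per
beat (10% by default), and drop the P wave with a configurable
probability (10% default, mimicking beats without visible atrial
activity). Leads are affine projections of one source train (gains
`1, −0.6, ...`) plus small independent Gaussian noise (0.01 mV), which
reproduces the inter-lead redundancy that motivates subject-wise
splitting. Default conditions: two leads at 250 Hz — the ambulatory
two-lead setting this package targets.

A low-quality label variant (`degrade_labels()`) jitters boundaries with
Gaussian noise (default 8 ms SD), drops waves, and inserts spurious short
waves, restoring ordering invariants by clipping — emulating single-lead
automatic annotation.

What the generator does *not* emulate: realistic 12-lead
vectorcardiography, arrhythmias, morphology changes within a record
(e.g. ST drift), non-Gaussian noise. Passing tests on this data therefore
demonstrate the correctness of the pipeline and the learnability of
smooth quasi-periodic morphologies, not clinical-grade performance on
pathological ECGs.

## Evaluation

Detection matches true and predicted waves through the correspondence
matrix: `H[i, j] = 1` iff any predicted fiducial (onset, peak or offset)
of wave `j` falls inside the closed true interval `i`, or any true
fiducial of `i` falls inside the predicted interval `j`. (The printed
form of the second membership test indexes inconsistently with the stated
ranges of `i` and `j`; the symmetric membership reading implemented here
is the only dimensionally consistent one.) Per-lead matrices are fused
with an elementwise OR when their dimensions agree; with per-lead
predictions of unequal counts the fusion happens at the row level (a true
wave is a TP if matched in any lead; unmatched predictions accumulate FP
per lead), which coincides with the OR whenever both are defined. TP is
the number of matched true waves and FP the number of unmatched predicted
waves, so a one-to-many match can never drive a count negative; with no
predictions and no truth, precision and recall use the 0/0 → 1
convention. Counts are pooled over records and leads before computing the
reported rates (micro-averaging).

Onset/offset errors are computed over TPs only, as the signed difference
*true − predicted* in ms with minimal absolute value over all matched
predictions and leads, summarized as mean ± SD; at 250 Hz every error is
a multiple of 4 ms. Dice is `2|A∩B|/(|A|+|B|)` per channel, 1 when both
masks are empty.

Two observer-bias estimators contextualize the errors. Inter-observer
bias matches two annotators' waves by the same correspondence rule and
reports the signed boundary differences; a wave type absent in one
annotator is skipped. Intra-observer bias extends each annotated segment
by 40 ms on both sides, computes the normalized running cross-correlation
(unit autocorrelation at zero displacement; full-segment energies in the
normalization) between all same-type pairs over all overlapping lags, and
pairs reaching 0.99 contribute their boundary differences after the
best-lag shift is removed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `levels` (L) | 4 (sweep 4–7) | U-Net depth; input window must divide by `2^(L−1)` |
| `blocks_per_level` (CB) | 2 (sweep 2–6) | blocks per level |
| `base_width` (N) | 8 | channels at the top level (`2^l N` at level l) |
| `spatial_dropout_p` | 0 (0.25 in experiments) | channel-dropout probability |
| `window` | 512 samples | training/prediction window |
| binarization threshold | 0.5 | mask decoding; ties map to 1 |
| `min_duration_ms` | 20 | decoded runs shorter than this are dropped (5 samples at 250 Hz); suppresses speckle without hiding genuine waves |
| SNR range | 5–30 dB | augmentation draw range per source |

The binarization threshold and minimum-run rule have no canonical values
in the delineation literature; both are exposed as configuration with the
defaults above.

## Problem sizes in the bundled runs

The test-suite and the acceptance script run deliberately desk-scale
problems: an overfit sanity check (one 17 s record, 16 beats, a
4-level/2-block/4-channel net, 200 epochs), a 20-subject × 10 s dataset
under 5-fold subject-wise CV (4-level/2-block/8-channel net, 20 epochs),
and a 3-replicate regularization comparison on 8 subjects. These sizes
were chosen as the smallest at which the studied effects are stable;
full-scale runs on real ambulatory databases use the same code paths with
larger records, deeper configurations and more epochs.

## Known limitations

* Training is CPU-bound, pure R linear algebra; it is intended for
  method study and desk-scale experiments, not for GPU-scale sweeps.
* BN inference statistics are exponential moving averages collected
  during training; very short trainings can leave them slightly stale.
* The WFDB dialect covers text headers with format-16 signals and an
  rdann-style text annotation table; binary MIT annotation files are not
  parsed.
* The synthetic generator's limitations above apply to every bundled
  result.
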