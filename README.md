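# ecgdelnet

ECG delineation — locating the onset, peak and offset of the P wave, the
QRS complex and the T wave in every heartbeat — framed as one-dimensional
semantic segmentation. The package targets researchers in physiological
signal processing who want a self-contained, fully testable delineation
pipeline: per-beat fiducial annotations are encoded as three-channel
binary masks

    B[n] = 1  iff  n ∈ [w_on[m], w_off[m]]  for some annotated wave m,
    w ∈ {P, QRS, T},

a configurable 1D U-Net (levels L with 2^l·N channels at level l, CB
convolutional blocks per level, vanilla / residual / depthwise-separable
block types, batch normalization and spatial dropout) is trained on the
masks with a soft Jaccard loss

    J_c = (Σ p·t + ε) / (Σ p + Σ t − Σ p·t + ε),   loss = 1 − mean_c J_c,

Adam optimization and six SNR-calibrated ECG noise sources for data
augmentation (additive white Gaussian noise, random spikes, amplifier
saturation, powerline noise, baseline wander, pacemaker spikes; noise
power P̃ₙ = Pₛ/10^(SNR/10)). Predicted masks are decoded back to
fiducials and scored with correspondence-matrix detection metrics
(precision/recall/F1 via TP/FP/FN over OR-fused leads), signed
onset/offset error statistics (true − predicted, mean ± SD in ms), Dice
overlap, and inter-/intra-observer bias estimators. A synthetic
multi-lead ECG generator with exactly known fiducials, a minimal
WFDB-style reader/writer, subject-wise cross-validation and
semi-supervised pre-training on degraded labels complete the pipeline.
The network, its backpropagation and the Adam optimizer are implemented
in base R on BLAS matrix products; gradients are verified against finite
differences in the test-suite.

## Worked example

Simulate a small two-lead dataset with known truth, train a delineator
under subject-wise cross-validation, and score the held-out subjects:

```r
library(ecgdelnet)

spec  <- sim_spec(n_subjects = 6, duration = 10, heart_rate = 70,
                  seed = 42)
ds    <- simulate_dataset(spec)
folds <- make_folds(names(ds$records), k = 3, seed = 1234)

cfg <- unet_config(levels = 4, blocks_per_level = 2, base_width = 8,
                   seed = 1234)
ctl <- train_control(strategy = "single_lead", epochs = 40,
                     batch_size = 16, window = 512,
                     windows_per_record = 6, lr = 2e-3, seed = 1234)

fits <- cv_delineator(ds$records, ds$fiducials, folds, cfg, ctl)
ev   <- cv_evaluate(fits, ds$records, ds$fiducials, window = 512)
print(ev$pooled)
```

```
<delineation_report> (single_lead)
 wave TP FP FN precision recall  f1 on_mean_ms on_sd_ms off_mean_ms off_sd_ms
    P 59  0  0       100    100 100      -0.07     3.19       -0.75      2.40
  QRS 67  0  0       100    100 100       0.06     2.03        0.06      1.77
    T 67  0  0       100    100 100      -0.54     2.40        0.90      4.17
 n_err
    59
    67
    67
```

Every held-out P, QRS and T wave is detected (precision = recall =
100%, zero false positives or negatives), and the decoded boundaries sit
within about one sample of the truth (at 250 Hz one sample is 4 ms):
e.g. QRS onsets are recovered with a 0.06 ± 2.03 ms error. Errors are
signed true − predicted, so negative means the prediction is slightly
late. The run takes about two and a half minutes on one CPU.

Individual pieces work standalone:

```r
b <- generate_beat(beat_template(), fs = 250)   # one beat + fiducials
m <- fiducials_to_mask(b$fiducials, b$n, fs = 250)
mask_to_fiducials(m)                            # decodes to the same on/off
x <- ds$records[[1]]$signal[, 1]
x_noisy <- x + noise_sinusoid(x, snr_db = 10, f = 0.5, fs = 250)  # wander
```

A thin command-line front-end is installed with the package
(`inst/cli/ecgdelnet.R`) with `simulate`, `augment-demo`,
`model-summary`, `train`, `predict`, `evaluate` and `grid` subcommands.

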