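---
title: "Tracking the carotid diameter from A-mode ultrasound: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the carotid diameter from A-mode ultrasound: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The carotid artery distends with every heart beat, and the waveform of its
diameter over time carries the information that downstream haemodynamic
analyses (pulse-wave velocity, stiffness indices) start from. On a single
ultrasound scanline, one A-mode frame is a 1-D profile of echo amplitude
along tissue depth: the vessel appears as two strong wall echoes with a
nearly echo-free (hypoechoic) lumen between them. Tracking the diameter
means locating those two walls in every frame of a 500 Hz stream, without a
sonographer clicking on anything.

`lumentrack` implements a fully automated two-stage neural pipeline for
this task, together with a synthetic phantom generator that provides exact
ground truth, so the whole system can be trained and evaluated at desk
scale:

1. a **region-of-interest (ROI) detector** — a tiny convolutional network
   that turns each envelope frame into a per-depth response map whose
   argmax is the lumen center; a fixed-width window is then clipped there
   (hard attention);
2. a **diameter tracker** — a convolutional regression network that maps
   one clipped window to one diameter estimate, in depth samples;
3. a **Savitzky–Golay post-smoother** that removes the frame-to-frame
   estimation noise of the per-frame (stateless) tracker.

Every frame is processed independently: the pipeline cannot accumulate
drift, and it is streaming-capable by construction.

## The synthetic phantom

No public A-mode carotid dataset with wall-position ground truth exists, so
the package ships a generative stand-in built from the acoustics the
pipeline actually exploits.

**Geometry and units.** Depth is sampled at 24.65 µm per sample
(= c/2f_s with c = 1540 m/s and RF sampling at 31.25 MHz), 1020 samples per
frame, 500 frames/s. All positions and diameters in the package are 0-based
depth samples; `samples_to_mm()` converts.

**Diameter waveform.** Per frame,

D(t) = D0 + A_p·pulse(cardiac phase) + A_r·sin(2π f_r t) + trend(t)

with defaults D0 = 7.5 mm (the average carotid diameter in the emulated
study population), cardiac amplitude A_p = 0.5 mm at 60 bpm, paced-breathing
modulation A_r = 0.2 mm at 7.5 cycles/min, and an optional slow hand-grip
trend (default off). The cardiac pulse is a raised-cosine upstroke over the
first 15% of the cycle followed by an exponential decay with time constant
25% of the cycle, normalized to [0, 1]. This shape was chosen because it
has a sharp systolic foot — precisely the waveform feature that the choice
of post-smoother is meant to preserve, so it must be present in the phantom
for that design question to be testable. The distension amplitude 0.5 mm is
a physiological default (the emulated study does not state its subjects'
amplitudes) and is exposed as a tunable.

**Rendering.** Each frame is a reflectivity train convolved along depth
with a Gabor pulse (Gaussian σ = 4 samples ≈ one pulse-echo carrier period,
carrier at the normalized center frequency 7.8/31.25 cycles per sample):
tissue speckle (σ = 0.1) outside the vessel, near-anechoic intraluminal
scatter (σ = 0.02) inside, unit-amplitude wall reflectors at the
real-valued wall positions (deposited by linear interpolation), static
high-contrast artifact bands (amplitude ≤ 0.8) away from the lumen, and
white sensor noise (σ = 0.02). This reproduces the A-mode features the
pipeline uses — two dominant wall echoes, a quiet lumen (envelope inside
the lumen below 10% of the wall peak), and strong distractor bands — and
nothing more.

**Sessions.** The emulated acquisition protocol recorded each subject in
three sessions, with the probe re-attached between sessions, explicitly to
cover intra-subject measurement variability. The phantom reproduces this:
each subject's recording is split into `n_sessions = 3` segments, each with
fresh scatterer realizations and a common random depth offset
(`session_shift_sigma = 15` samples); artifact bands additionally receive an
independent per-session offset of the same scale, because repositioning the
probe changes the apparent depths of off-artery structures more than the
artery itself. This matters for generalization: with
a single frozen speckle pattern per subject, a detector trained on five
subjects can memorize texture relative to the lumen and carry a systematic
per-subject localization bias onto the held-out subject; session-resampled
texture forces it toward the texture-invariant cue (two strong echoes
around a quiet gap) that transfers.

**Cohorts.** `make_cohort()` draws per-subject lumen baselines uniformly in
[350, 650] samples, 2–4 artifact bands outside the lumen excursion range,
and per-subject sub-seeds, all deterministically from one master seed.

**What the phantom does not emulate.** Real tissue acoustics (frequency-
dependent attenuation, reverberation, off-axis clutter), probe motion,
swallowing/coughing artifacts, ECG, blood-pressure coupling, or
between-subject diameter differences beyond the lumen position. Passing the
recovery tests below therefore shows that the pipeline's mechanics work —
labels, attention, regression, smoothing, evaluation — not that the trained
weights transfer to clinical data.

## Response-vector labels

The ROI detector is trained as a regressor, not a per-depth classifier (one
positive depth among 1020 would be hopelessly imbalanced). For a frame with
anterior/posterior wall positions P_A < P_P:

* lumen center P_C = (P_A + P_P)/2;
* cut-off points halfway from the center to each wall,
  (P_C + P_A)/2 and (P_C + P_P)/2;
* label R_i = 1 − (i − P_C)² / (P_C − P_cutoff)² for depth indices strictly
  between the cut-offs (using the cut-off on the same side as i), 0
  everywhere else.

The label is a downward-opening quadratic bump in [0, 1] peaking at the
lumen center. Support is the open interval (values at the cut-offs are
exactly 0, matching the strict inequalities of the definition). Centers and
cut-offs are kept real-valued and evaluated at integer depths — rounding
them first would bias labels by up to half a sample. Labels are
shift-equivariant, which is what makes depth-translation augmentation
(uniform ±150 samples, resampled every epoch) exact: the frame and its
label shift together with zero fill.

## The ROI detector

Architecture (1210 trainable parameters): one 1-D convolution from the
envelope to 3 channels with a 401-sample kernel (wide enough to span the
largest plausible diameter, ~9.9 mm), a rectifier, a 1-wide convolution
collapsing the channels to a single per-depth map, and a parameterless
31-sample moving-average pooling. No layer changes the signal width (zero
padding throughout), so the pooled map's argmax *is* the lumen-center depth
estimate; ties break to the smallest index. The clipping window (401
samples, matching the first-layer kernel) is centered at the rounded
estimate and shifted inward when it would overhang an edge — clamping was
preferred over zero-padding the window because padding would fabricate
signal for the tracker.

Training minimizes the mean squared error between the **pre-pooling** map
and the response vector; the pooling layer is excluded from the loss path.
Pooling is a fixed smoother, and back-propagating through it blurs the
localization gradient; regressing the sharp map directly and smoothing only
at inference gives a crisper optimum. Mean (not summed) MSE is used; the
choice only rescales the learning rate. Optimizer: Adam, initial learning
rate 1e-3 with cosine annealing over the run, weight decay 1e-4, batch 64,
10 epochs.

Two augmentations are applied per epoch: the depth translation above, and
random **artifact injection** — with probability 0.5 a frame receives a
synthetic high-contrast band (the wall pulse's Gaussian envelope, amplitude
0.3–0.8) at a random depth away from the label support. Without it, a
detector trained on a handful of subjects keys on their specific artifact
geometry; injection forces it to treat a lone echo band as a distractor
wherever it appears.

Two intrinsic limits of this stage are worth knowing. The response-vector
label is a broad bump (it still reads 0.83 at 30 samples off center for a
typical diameter), so the pooled argmax inherits scatter of roughly ±10
samples from small residual map errors. And a strong artifact band sitting
close to one wall can form a plausible "false pair" with the opposite wall,
to which the label assigns a high value too; subjects with such anatomy
show localization errors of 15–20 samples where typical subjects show
5–9. The downstream stage is sized to absorb exactly this error
distribution.

## The diameter tracker

Architecture (993,861 trainable parameters; together with the ROI stage the
pipeline rounds to one million): five same-width, zero-padded 1-D
convolutions with kernel 9 and channel counts 8→16→32→16→8, each followed
by batch normalization and a ReLU; no pooling anywhere — the diameter is
read from relative depth positions, which pooling would destroy; then a
flatten (8 × 401) and fully connected layers 3208→300→64→1 with dropout 0.2
on the first two. The final unit is a logistic sigmoid scaled by the window
width, so the output lives in (0, 401) samples and the regression target is
naturally bounded. Activation functions and exact widths are package
choices within the stated architectural constraints (channel rise/fall, 5+3
layers, ~1M total parameters).

The loss is the Huber loss in sample units with δ = 1 sample: quadratic for
errors below one depth sample (the label-noise scale), linear above, so
occasional gross mis-estimates caused by high-amplitude artifacts do not
dominate the fit the way a squared loss would let them.

Training windows are clipped around the **ground-truth** centers with a
fresh uniform jitter of ±35 samples per frame and epoch; inference windows
come from the ROI stage. The two stages are deliberately trained
independently — small, separately regularized models train reliably on
small cohorts — and the jitter is what bridges them: it must cover the ROI
stage's localization scatter, including its tail on hard subjects. The
default of 35 samples was set from that scatter as measured on held-out
phantom subjects (localization errors reach 30–40 samples on subjects
whose artifact anatomy forms a "false pair" with one wall); smaller
jitters leave the tracker facing window offsets it never saw in training,
and because the ROI error fluctuates with the breathing cycle the
resulting distortion lands inside the physiological band, visibly
corrupting the recovered waveform. Wide jitter costs nothing measurable on
easy subjects — the diameter is a translation-invariant feature of the
window, and ±35 training offsets force the network to treat it that way.
Optimizer: Adam, initial learning rate 1e-3 with cosine annealing, weight
decay 1e-4, batch 256 (chosen for optimizer-step economy on a single CPU),
20 epochs. The output layer is initialized near zero so the bounded
sigmoid head starts at mid-scale with its maximum gradient; a randomly
initialized head can start saturated (the pre-activation acquires a
sample-independent offset), which freezes training entirely. Batch-norm
uses batch statistics during training and global running averages
(momentum 0.1) at inference, so inference is deterministic.

## Post-smoothing

The per-frame tracker output carries high-frequency estimation noise. The
default smoother is a Savitzky–Golay filter of order 5 and window 31
samples (62 ms at 500 Hz): a local least-squares polynomial fit that passes
polynomials up to degree 5 through unchanged, short enough to preserve the
systolic foot. Edges are handled by evaluating the boundary polynomial fits
rather than padding the record with fabricated samples. A plain moving
average with the same window is available as the comparator
(`smoother_config("moving_average")`); it smooths more aggressively and
rounds the systolic foot.

## Evaluation

`compute_metrics()` reports Pearson r; the coefficient of determination
R² = 1 − SS_res/SS_tot of the prediction against the reference (not r² —
the two differ whenever the prediction is biased or mis-scaled); Lin's
concordance correlation coefficient, which penalizes the scale and location
shifts Pearson ignores; MAE, MSE, RMSE; the absolute deviation summarized
both as a median (`mad_median`, robust headline figure) and a mean
(`mad_mean`) because the field uses "MAD" for both; the t statistic of the
correlation; and the skewness and excess kurtosis of the error
distribution (population moments). Moment-based quantities (CCC, skewness,
kurtosis) use 1/n variances.

`loso_evaluate()` runs leave-one-subject-out cross-validation: for each
held-out subject both networks are retrained from scratch on the remaining
subjects, the held-out recording is streamed through the pipeline, smoothed,
and scored against ground truth; the summary row is the unweighted mean
over subjects (per-fold frame counts are kept so weighted summaries remain
possible). Per-fold seeds derive deterministically from one master seed,
and per-fold traces are retained so temporal-alignment checks
(cross-correlation peak at lag zero — drift-freedom) can be made on the
result object.

## Numerical choices

* All network arithmetic is single precision; convolutions are evaluated
  as BLAS GEMMs over kernel-tap shifts in a guard-row batch layout, with
  hand-vectorized kernels used on CPUs that support them (results are
  identical in distribution; training is deterministic given the seed on a
  given machine).
* Every stochastic step — phantom rendering, cohort draws, initialization,
  shuffling, augmentation, dropout — draws from named seeds through R's
  RNG; the caller's RNG state is always restored.
* Zero-width lumens, non-finite frames, all-zero frames, out-of-range
  shifts and inconsistent acquisition constants are rejected with errors
  naming the offending quantity.
* Argmax ties break toward the smallest index; decimated argmaxes map back
  to full resolution at block centers (i·K + K/2).

## Problem sizes

The bundled evaluation (tests and the acceptance script) uses a 6-subject
cohort with 2000 frames per subject, ROI training for 10 epochs and tracker
training for 20 epochs per fold — the regime in which the training curves
of both networks reach their initial plateau on this phantom. Unit and
property tests run on much smaller fixtures (tens of frames, shortened
configs) generated in code.

## Known limitations

* Phantom realism is deliberately minimal (see above); reported recovery
  numbers characterize the pipeline, not clinical performance.
* Localization is argmax-based and integer-valued at full resolution;
  sub-sample wall tracking (via preserved RF phase) is out of scope.
* The ROI stage's accuracy degrades when high-contrast artifact bands fall
  inside the attention span of the lumen center; the response-map design
  tolerates but does not eliminate this.
* Single scanline only; multi-scanline fusion and B-mode segmentation are
  out of scope.
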