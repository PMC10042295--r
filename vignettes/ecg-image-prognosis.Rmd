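---
title: "From ECG waveforms to images: encoding, classification and attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ECG waveforms to images: encoding, classification and attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecg2img)
```

## The problem

Patients admitted to a cardiac care unit (CCU) with severe cardiac disease
have complicated, comorbidity-laden ECGs, and their short-term prognosis is
hard to read from the waveform directly. One line of work converts the
multi-lead ECG into a conventional-looking chart *image* and lets a 2-D
convolutional network, often one pretrained on natural images, classify the
patient's in-unit outcome (survivor vs non-survivor). Working in image space
keeps the input close to what a cardiologist actually reads, and makes the
model's evidence inspectable with gradient-based attribution (GradCAM).

`ecg2img` packages that pipeline end to end: deterministic waveform-to-image
encoding, a pluggable binary classifier harness with patient-level score
aggregation, the ten-fold train/validation/test evaluation protocol with
confusion metrics and ROC/AUC, GradCAM overlays, and a synthetic cohort
generator so that everything can be exercised without clinical data.

## The image encoding

The canonical record is 10 s of a 12-lead resting ECG sampled at 500 Hz
(5000 samples per lead, amplitudes in mV). Four leads are imaged, in fixed
top-to-bottom order: **II, V3, V5, aVR**. When a record carries no measured
aVR channel, it is derived from the Einthoven limb leads by the augmented-lead
identity

$$\mathrm{aVR}(t) = -\frac{I(t) + II(t)}{2},$$

which is exactly the arithmetic a bedside monitor applies. A measured aVR,
when present, passes through unchanged — derivation is a fallback, not a
transformation.

Each lead is split into **three contiguous time segments** (5000 samples
→ 1667/1667/1666; earlier segments take the extra samples). Using thirds
keeps enough time resolution per image for both rhythm and waveform shape to
remain legible. Per segment, each lead is rendered as a one-pixel polyline
on a white background — samples are placed uniformly across the width,
amplitudes are linearly interpolated at every output column, and each column
is joined to its neighbour by a vertical run so steep QRS deflections stay
connected — then reduced with **Lanczos (3-lobe windowed-sinc) resampling**,
and the four reduced strips are stacked into one 224×224 8-bit grayscale
PNG with 40 background rows between consecutive strips.

Geometry choices worth spelling out:

* **Reduce-then-compose.** With three 40-px gaps inside a 224-px image, the
  only integer strip height is 26 px (4·26 + 3·40 = 224). We therefore
  reduce each strip to 224×26 first and then stack. Composing first and
  reducing afterwards would make the "40 pixels" pre-reduction quantities,
  which has no integer-consistent reading at 224×224.
* **Fixed amplitude scaling.** Strips map a fixed symmetric physical range
  (default ±2.0 mV) onto their height, clipping beyond it. Per-segment
  min–max scaling would destroy amplitude comparability across segments and
  patients — which both cardiologists and attribution maps rely on.
* **Native render height.** Strips are rasterised at 256 px height before
  reduction, ≥8× the final 26 px, so waveform morphology survives the
  windowed-sinc reduction. The trace loses contrast (a one-pixel line spread
  over ~10 source rows per output row) but remains a consistent, learnable
  signal; the classifier normalises images to trace-positive [0, 1] anyway.
* **Orientation and polarity.** Row 0 is the image top; positive amplitude
  is up; the trace is black (0) on white (255), matching conventional chart
  polarity.
* Encoding is fully deterministic: the same record yields byte-identical
  PNG files.

## The classifier harness

The transfer-learning scheme is head replacement: take a backbone, drop
everything beyond its final convolution, and attach two fresh fully
connected layers — global average pooling, a hidden ReLU layer (default 256
units), and a 2-way softmax-normalised output. With `freeze_backbone = TRUE`
(the default) only those two layers train, which is the right regime for a
pretrained backbone.

No pretrained ImageNet weights can be assumed available offline, so the
built-in backbone `tiny2d` is a small three-block CNN (8/16/32 filters of
3×3, max-pooling 4/2/2) sized for CPU training. Because its weights are
random rather than pretrained, the end-to-end experiments in this package
train it **unfrozen** — freezing a random backbone would fix meaningless
features; the freeze switch keeps its spec'd default for the pretrained
use case. Training is mini-batch Adam on softmax cross-entropy (desk-scale
defaults: learning rate 1e-3, 10 epochs, batch size 8, threshold 0.5; the
clinical-scale regime behind the protocol used 1e-6 over 50 epochs on GPU
backbones). The final-epoch model is kept — no early stopping. Everything is
deterministic given the seed.

A four-branch 1-D CNN baseline (`build_1d_baseline()`) mirrors the
conventional waveform-domain comparator: each panel lead feeds an
independent branch of four conv+pool blocks and the concatenated branch
features are classified by a single fully connected layer.

The convolution/pooling kernels are compiled (Rcpp/RcppArmadillo, im2col +
BLAS GEMM); the surrounding model logic, Adam, and all protocol code are
plain R.

## Patient-level evaluation protocol

Each patient contributes three segment images; the network scores each
image with a death probability, and the patient-level probability is their
**arithmetic mean** (average first, threshold after — thresholding
per-image and voting is deliberately not done). Ties at the threshold
classify as positive, fixed for reproducibility.

Cohort balancing follows the undersampling design: survivors are randomly
sampled without replacement down to the non-survivor count (in the clinical
setting, 291 from 9457) before any training.

Cross-validation deals patients into 10 groups (sizes differing by at most
one) and rotates: fold *f* tests on group *f*, validates on the two
cyclically following groups, trains on the remaining seven. Every group is
the test group exactly once; all roles are at patient level so a patient's
three images always travel together, and any overlap raises a structured
leakage error rather than silently biasing results. Model parameters are
re-initialised for every fold. Metrics are the confusion-matrix rates in
percent — sensitivity TP/(TP+FN), specificity TN/(FP+TN), accuracy
(TP+TN)/total — plus the ROC curve traced by sweeping the cutoff over all
distinct scores and its trapezoidal AUC (equal to the Mann–Whitney pairwise
statistic, with ties grouped into single steps). A rate whose denominator
is zero is reported as flagged-undefined, never as a silent zero.

## GradCAM attribution

For a chosen target class, the gradient of that class's logit with respect
to the final convolution's activation maps is averaged spatially into one
weight per channel; the weighted channel sum is rectified, upsampled
bilinearly to image resolution, and max-normalised (identically zero maps
are flagged "empty" instead of divided). Overlays blend a blue→red
colormap over the grayscale ECG. `strip_attribution()` turns a heatmap into
per-lead (and per-time-bin) mass shares using the 26/40 row layout, so
statements like "attention concentrates on the ST portion of V3" become
quantities. Upsampling method and normalisation are documented choices, not
properties of the attribution method itself.

## The synthetic cohort generator

The generator stands in for the private clinical cohort; it is first-class,
tested code. Each beat is a sum of five Gaussians (P, Q, R, S, T) with a
default wave table — P(0.15 mV, −0.20 s, 0.025 s), Q(−0.10, −0.035, 0.010),
R(1.00, 0, 0.012), S(−0.25, 0.035, 0.010), T(0.35, 0.22, 0.045) — scaled
per lead (I 0.7, II 1.0, V3 1.2, V5 1.1). Beats are laid down with RR
intervals 60/HR plus Gaussian jitter (SD 0.02 s, truncated positive), the
heart rate drawn once per patient from 55–100 bpm, and white measurement
noise of 0.02 mV SD is added. Leads I, II, V3 and V5 are emitted so the
aVR-derivation path is always exercised.

Non-survivor records differ by three injected effects, chosen to mirror the
morphologies attribution analyses tend to single out on real CCU data:
a **+0.2 mV ST-segment offset** between the S and T wave centers, applied in
a single lead (default V3, making "the lead carrying the ST effect" well
defined for localisation checks); an **R-amplitude multiplier of 1.3**
(left-ventricular-hypertrophy-like R height, all leads); and an **RR-jitter
multiplier of 3** (rhythm irregularity). A sum-of-Gaussians model was chosen
over a full dynamical ECG simulator because it is closed-form, fast, and its
parameters map one-to-one onto these effects. `neutralise_class_effects()`
zeroes all three, making the classes distributionally identical for null
checks.

What the generator does *not* emulate: baseline wander, electrode artefacts,
arrhythmia taxonomies, comorbidity-specific morphologies, or inter-lead
torso physics. Passing the end-to-end checks therefore demonstrates that the
pipeline is wired correctly and can recover a planted class signal from
encoded images — it says nothing about clinical performance, which requires
clinical data.

## Problem sizes and numerical choices

The end-to-end experiments use 100 patients per class, encoded once and
split 7/2/1 at patient level via the fold dealer (140 train / 40 validation /
20 test patients), with the tiny2d backbone trained unfrozen for 10 epochs —
sizes at which the planted signal is comfortably recoverable on one CPU.
The signal-recovery check is run at three training seeds with a majority
rule, the null check at one seed, and the attribution-localisation check on
a freshly generated batch of 30 non-survivors disjoint from the training
cohort (the 7/2/1 test fold alone would hold only ~10 non-survivors, too few
to assess a mean share over ≥20 correctly classified patients).

Smaller numerical decisions, all deliberate: segment splitting gives the
extra samples to earlier segments; rasterised rows are `floor(y + 0.5)` of
the interpolated position (no banker's rounding); Lanczos weights are
normalised per output pixel, so constant images are exactly preserved, and
edges clamp to the nearest source pixel; pooling uses floor semantics with
first-element tie-breaking; the MFER-style fixture container stores int16
samples at a configurable resolution (default 1 µV/LSB), so round-trips are
exact for resolution-aligned amplitudes and bounded by half an LSB
otherwise; undefined metric denominators yield flagged `NA`s; AUC tie
handling groups equal scores into one ROC step.

## Limitations

* The seven named ImageNet backbones are interface-compatible but not
  bundled — no pretrained weights ship with the package, so clinical-scale
  transfer learning requires the user to plug in a backbone.
* The synthetic generator's effect sizes are fixed study conditions, not
  fitted to any clinical distribution.
* The MFER-style container is a documented minimal subset for fixtures and
  interchange, not an implementation of the full standard.
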