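# ecg2img

Short-term mortality prediction for cardiac-care-unit patients from
ECG *images*: `ecg2img` converts 10-second multi-lead ECG waveforms into
stacked-lead grayscale chart images, trains and evaluates binary
survivor/non-survivor classifiers on them with a patient-level protocol, and
explains predictions with GradCAM attribution. It is aimed at researchers in
biomedical signal analysis who want the full waveform→image→CNN→metrics
pipeline as reusable, deterministic, tested components — runnable end to end
on a bundled synthetic cohort generator, with no clinical data required.

## What it implements

**Encoding.** A record (5000 samples/lead at 500 Hz, mV) is imaged from the
four leads II, V3, V5, aVR. A missing aVR is derived from the limb leads:

    aVR(t) = -((I(t) + II(t)) / 2)

Each lead is split into three contiguous segments (1667/1667/1666 samples),
rendered as a 1-px polyline with per-column linear interpolation, reduced
with Lanczos (3-lobe) resampling, and stacked — four 224×26 strips with
40-px gaps — into three 224×224 8-bit grayscale PNGs per patient.

**Classification.** A backbone-agnostic harness replaces a backbone's head
with global average pooling → dense(256, ReLU) → dense(2, softmax), with an
optional frozen backbone (transfer-learning regime). A built-in `tiny2d`
CNN backbone trains on CPU (compiled im2col/BLAS kernels); a four-branch
1-D CNN baseline covers the conventional waveform-domain comparison.

**Evaluation.** Per-patient death probability is the mean of the three
per-image probabilities. Survivor undersampling balances the cohort; a
10-group patient-level rotation gives the 7/2/1 train/validation/test
protocol with leakage detection; metrics are sensitivity, specificity and
accuracy in percent,

    Sensitivity = TPs / (TPs + FNs) * 100
    Specificity = TNs / (FPs + TNs) * 100
    Accuracy    = (TPs + TNs) / (TPs + TNs + FPs + FNs) * 100

plus the cutoff-swept ROC curve and trapezoidal AUC.

**Attribution.** GradCAM heatmaps from the final convolution, bilinear
upsampling and max-normalisation, blue→red overlays, and per-lead /
per-time-bin attribution shares via the strip layout.

**Synthetic cohorts.** A sum-of-Gaussians PQRST beat model generates
labelled 4-lead records; non-survivors carry a +0.2 mV ST offset in V3, a
1.3× R amplitude and 3× rhythm jitter. See the methods vignette
(`vignettes/ecg-image-prognosis.Rmd`) for every modelling choice.

## Worked example

```r
library(ecg2img)

# 1. generate a labelled synthetic cohort and encode it (~1 min)
cohort  <- gen_cohort(n_per_class = 100, seed = 101)
dataset <- image_dataset(encode_cohort(cohort$records), cohort$labels)

# 2. train tiny2d on the 7/2/1 holdout split, score held-out patients (~3 min)
ex <- run_holdout_experiment(dataset, train_config(seed = 1, epochs = 10))
print(ex$report)
#> <ecg_metrics_report> TP=7 TN=13 FP=0 FN=0 | sens 100.00% spec 100.00% acc 100.00% | AUC 1.000

# 3. attribute a freshly generated non-survivor's prediction to image regions
rec <- gen_patient("non_survivor", seed = 900001, patient_id = "F01")
panel <- encode_patient(select_panel(rec))
hm <- compute_gradcam(ex$model, panel$images[[1]], target_class = 1)
round(strip_attribution(hm)$lead_shares, 4)
#>     II     V3     V5    aVR
#> 0.1875 0.3040 0.1133 0.1088
```

The report line says every held-out patient of the test fold (7
non-survivors, 13 survivors) was classified correctly, with patient-level
AUC 1 — the planted class signal is fully recoverable at this cohort size.
The attribution shares say ~30% of the heatmap mass falls in the V3 strip,
the lead carrying the injected ST-segment offset, versus ~11–19% for each
other lead (the remainder lies in the gap rows between strips).

A thin CLI wraps the same functions (`exec/ecg2img` after installation):
`ecg2img synth`, `ecg2img convert`, `ecg2img train`, `ecg2img evaluate`,
`ecg2img gradcam`.

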