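# radarleak

Contactless continuous-wave radar can measure the sub-millimetre chest
motion of a person at rest, and that motion carries their heartbeat.
`radarleak` is an R implementation of a privacy-oriented analysis of such
recordings: it asks whether demographic attributes — **sex** and **age
group** — leak from the cardiac channel of a vital-sign radar, and how fast
an adversary's confidence grows with observation time.

The package is aimed at biomedical signal-processing and ML-privacy
researchers. Because clinical radar recordings cannot be redistributed, the
package includes a first-class synthetic cohort generator, so the complete
chain is reproducible from a single seed; a loader for real I/Q data only
needs to produce the same `radar_recording` structure.

## The method

Starting from quadrature (I/Q) radar signals sampled at 2 kHz:

1. **Arctangent demodulation with ellipse fitting.** Chest displacement
   d(t) modulates the carrier phase over the two-way path,
   Φ(t) = 4π·d(t)/λ. Receiver imperfections (DC offsets, amplitude
   imbalance, quadrature phase error) distort the circular I/Q locus into
   an ellipse; a direct least-squares ellipse fit per 10 s window followed
   by whitening and `atan2` recovers Φ, hence d(t).
2. **MODWT cardiac isolation.** A maximal-overlap (undecimated) discrete
   wavelet multiresolution analysis at a 200 Hz working rate separates the
   heartbeat octaves (default band 0.8–3.5 Hz) from respiration and noise.
3. **CWT scalograms.** Each 10 s window is cut into 13 overlapping 4 s
   frames (stride 0.5 s); each frame becomes a 200×200 normalized analytic
   Morlet scalogram.
4. **Conditional WGAN-GP augmentation.** A label-conditioned Wasserstein
   GAN with gradient penalty (λ·(‖∇x̂ D(x̂)‖₂ − 1)²), trained only on
   training-subject scalograms, synthesizes class-labeled images that
   enlarge the training set by a configurable percentage.
5. **CNN classification with window voting.** A five-stage CNN (kernels
   5, 3, 13, 5, 2; flattened width 2048; dense stack 1024/256/64/1)
   predicts each frame; hard majority voting yields the window decision.
6. **Subject-wise evaluation.** Stratified subject-level splits with hard
   leakage guards; window/frame accuracy, FAR/FRR (= 100 − macro
   precision/recall, the convention of the reference tables), macro F1,
   Welch tests over repeated runs, Grad-CAM explanations, and
   temporal-aggregation curves (majority votes over all contiguous frame
   runs spanning ≥ 7 s).

The networks, backpropagation and the exact WGAN-GP penalty gradient are
implemented in the package itself (with C++ convolution kernels) — every
gradient is finite-difference checked in the test suite. See the methods
vignette (`vignettes/radar-demographic-leakage.Rmd`) for the modelling
decisions and their rationale.

## A worked example

A desk-scale run: simulate eight subjects (four per sex) with a strong
planted class effect, demodulate, isolate the heartbeat, render 32 px
scalograms, train a reduced classifier on six subjects and evaluate on the
two held out.

```r
library(radarleak)

cfg <- cohort_config(n_subjects = 8, sex_proportions = c(0.5, 0.5),
                     effect_size = 2.5, duration_per_subject = 30, seed = 7)
cohort <- simulate_cohort(cfg)
cohort$recording[[1]]
#> <radar_recording> subject S001: 30.0 s at 2000 Hz (60000 samples)

scalos <- compute_scalograms(cohort, config = scalogram_config(size = 32))
scalos$label <- scalos$sex_label   # 312 frames: 8 subjects x 3 windows x 13

split <- subject_split(dplyr::distinct(scalos, subject_id, label),
                       n_test = 2, stratify = "label", seed = 7)
fit <- train_classifier(scalos[scalos$subject_id %in% split$train_subjects, ],
                        classifier_config(epochs = 4, seed = 7),
                        cnn_spec_small(32), test_subjects = split$test_subjects)

frames  <- predict_frames(fit, scalos[scalos$subject_id %in% split$test_subjects, ])
windows <- vote_windows(frames)
compute_metrics(windows, frames)
#> <leak_metrics> windows 100.00% | frames 100.00% | FAR 0.00 | FRR 0.00 | P 100.00 | R 100.00 | F1 100.00
```

With `effect_size = 2.5` the two sexes differ by 2.5 pooled standard
deviations in heart rate, pulse width and pulse amplitude, so the scalogram
ridges are well separated and the held-out windows are classified
perfectly; with `effect_size = 0` the same pipeline sits at chance. The
temporal-aggregation curve answers the adversarial question — here the
classifier is already confident at the shortest qualifying span:

```r
agg <- temporal_aggregation(frames)
head(agg$cohort, 3)
#> # A tibble: 3 × 2
#>   duration_bin fraction_confident
#>          <dbl>              <dbl>
#> 1            7                  1
#> 2            8                  1
#> 3            9                  1
autoplot(agg, which = "cohort")
```

`run_pipeline(pipeline_config(...))` wires all stages (including GAN
augmentation and Welch comparisons across augmentation amounts) from one
configuration object and seed; `tidy()` / `glance()` methods return the
per-run and aggregated metric tables.

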