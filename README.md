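# gazemarker

Do natural eye movements carry enough signal to detect glaucomatous
visual-field (VF) loss? `gazemarker` implements a complete assessment of
that question for *simulated* loss: synthetic cohorts of observers
free-view videos and images either with no simulated VF loss, moderate loss
(mean deviation −12 ≤ MD ≤ −6 dB) or advanced loss (MD < −12 dB) rendered
as a gaze-contingent scotoma, and their eye movements are analysed for
diagnostic accuracy. It is aimed at vision scientists and biostatisticians
who want a tested, seeded reference pipeline for eye-movement biomarker
studies.

## What it computes

**Event detection.** Binocular 60 Hz pixel gaze is converted to degrees
using per-sample viewing distance, the eyes are merged, and samples are
classified as saccadic when both speed > 30°/s and acceleration >
8000°/s²; saccades under 0.5° and fixations over 500 ms (smooth pursuit)
are discarded.

**Four biomarkers** per participant × stimulus:

* median saccade amplitude (degrees);
* BCEA, the 95% bivariate contour ellipse area of start-aligned saccade
  endpoints: `2kπ σ_dx σ_dy √(1−ρ²)`, `k = −ln(0.05) ≈ 2.9957` (deg²);
* SLV, the proportion of saccades landing on VF-loss locations of the
  gaze-relative scotoma mask (the binocular integrated field is the
  pointwise max of the monocular 24-2 fields; loss = sensitivity < 20 dB);
* KDE score: per 30 fps video frame, the density of a participant's mean
  gaze position under a Gaussian kernel density (`h = 1.5°`) fitted to the
  control group's positions for that frame (leave-one-out for controls,
  isolation-forest outlier screening), averaged over frames.

**Statistics & diagnostic accuracy.** Kruskal–Wallis across the three
groups; pairwise two-tailed Mann–Whitney tests, Bonferroni-corrected for
three comparisons, with rank effect size η² = Z²/N; ROC curves with
trapezoid AUC (equal to the Mann–Whitney pair-count probability),
sensitivity at fixed 90% specificity, and windowed AUC on the temporal KDE
traces.

**Multi-feature classifier.** 87 features per video (84-cell saccade
endpoint map + amplitude + BCEA + KDE mean; 86 for images) → Gaussian-kernel
PCA → AdaBoost over decision stumps, hyperparameters chosen by inner
cross-validation, evaluated by leave-one-out with pooled ROC.

**Synthetic cohorts.** Because no gaze recordings from such a paradigm are
public, a seeded generator is a first-class module: shared saliency
targets, alternating fixations/saccades with detector-calibrated
kinematics, binocular rendering to screen pixels, blinks, and planted group
effects (contracted scan paths in advanced loss, scotoma-directed saccades
and idiosyncratic viewing in moderate loss). See the methods vignette
(`vignettes/eye-movement-biomarkers.Rmd`) for every default and its
rationale.

## Worked example

```r
library(gazemarker)
cfg <- cohort_config(6, 4, 4,
  stimuli = list(stimulus_spec("video1", "video", 60),
                 stimulus_spec("image1", "image", 30)),
  seed = 42)
res <- run_pipeline(cfg)
subset(res$summary, feature == "median_amp",
       select = c(stimulus, group, n, median))
#>  stimulus    group n   median
#>    video1     none 6 4.237029
#>    video1 moderate 4 4.026404
#>    video1 advanced 4 2.948382
#>    images     none 6 5.039102
#>    images moderate 4 5.265959
#>    images advanced 4 3.216789
```

The advanced group's median saccade amplitude is visibly reduced (the
generator contracts its scan paths by 0.6, attenuated here by
inter-individual gain variability), while the moderate group is close to
controls. The same bundle carries the omnibus tests and per-feature
diagnostic accuracy:

```r
head(subset(res$stats, comparison == "omnibus"), 4)
#>     feature stimulus comparison statistic          p eta2
#>  median_amp   video1    omnibus  5.257143 0.07218151   NA
#>        bcea   video1    omnibus  4.523810 0.10415191   NA
#>         slv   video1    omnibus  9.166667 0.01022077   NA
#>         kde   video1    omnibus  5.357143 0.06866117   NA
subset(as.data.frame(res$roc), stimulus == "video1" & pair == "none-advanced")
#>     feature stimulus          pair       auc sens_at_spec90
#>  median_amp   video1 none-advanced 1.0000000            1.0
#>        bcea   video1 none-advanced 0.9166667            0.5
#>         kde   video1 none-advanced 0.7500000            0.0
#>         slv   video1 none-advanced 0.5833333            0.0
```

At this toy size (6 vs 4 participants) the statistic `statistic` is the
Kruskal–Wallis χ² on 2 df, `auc` the threshold-free separability of the
groups by each biomarker, and `sens_at_spec90` the empirical sensitivity at
90% specificity. Amplitude separates none from advanced loss; SLV and KDE
carry the moderate-loss signal (`pair == "none-moderate"` rows).

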