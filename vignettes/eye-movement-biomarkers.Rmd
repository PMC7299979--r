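---
title: "Eye-movement biomarkers for simulated visual-field loss: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-movement biomarkers for simulated visual-field loss: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the pipeline

Glaucomatous visual-field (VF) loss changes how people move their eyes
during ordinary viewing. If those changes were large and consistent enough,
natural eye movements recorded while someone watches a video could screen
for the disease without perimetry. `gazemarker` implements an end-to-end
assessment of that idea on simulated data: a gaze-contingent scotoma
paradigm in which healthy observers free-view videos and images either with
no simulated loss, moderate loss (mean deviation, MD, between −12 and −6
dB), or advanced loss (MD below −12 dB), and their eye movements are mined
for diagnostic signal.

The pipeline has five stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **Synthetic cohort generation** (`generate_cohort()`): seeded gaze
   recordings for three groups with planted group effects.
2. **Preprocessing** (`pixels_to_degrees()`, `merge_binocular()`,
   `detect_events()`): raw binocular pixel gaze to degrees, then
   saccade/fixation classification.
3. **Biomarkers** (`build_biomarkers()`): median saccade amplitude, 95%
   bivariate contour ellipse area (BCEA), proportion of saccades landing on
   VF-loss locations (SLV), and a per-frame kernel-density (KDE)
   gaze-similarity score.
4. **Statistics and diagnostic accuracy** (`group_stats()`, `roc_table()`,
   `windowed_auc()`): Kruskal–Wallis, Bonferroni-corrected Mann–Whitney
   tests with rank η², ROC/AUC, sensitivity at fixed 90% specificity.
5. **Multi-feature classification** (`build_feature_table()`,
   `adaboost_loo()`): an 87-feature bank through kernel PCA and AdaBoost,
   evaluated by leave-one-out (LOO).

# Visual fields, severity, and the scotoma mask

Perimetry is represented on the standard 24-2 grid (6° spacing, offset 3°
from the meridians, 54 locations, nasal extension to 27°). The binocular
integrated visual field (IVF) takes the pointwise **maximum** sensitivity of
the two monocular fields; severity is classified from the worse eye's MD
(moderate −12 ≤ MD ≤ −6 dB; advanced MD < −12 dB). Because the simulated
scotoma is gaze-contingent, the loss region is approximately static in
retinal coordinates: the mask is therefore expressed **relative to current
gaze**, as 6°×6° cells centred on IVF locations whose sensitivity falls
below a cutoff.

Two choices here are genuinely open and are exposed as parameters:

* The dB level at which a blurred region counts as "loss" is nowhere
  standardised; the default cutoff is 20 dB (`scotoma_mask(cutoff = )`).
* The loss region could be grid cells or an interpolated contour; cells
  were chosen because membership is then exactly testable (half-open
  squares, `[centre−3, centre+3)` per axis).

The package ships a synthetic perimetry builder (`synthetic_perimetry()`)
emulating superior binocular loss — the clinically most common binocular
pattern — with planted MD values inside each class range. It is labelled
synthetic throughout: the single real patient's longitudinal fields used in
the original paradigm are not public.

# Event detection

Gaze is recorded binocularly at 60 Hz in screen pixels with a per-sample
eye-to-screen distance. Conversion to degrees uses each axis's own cm/px
scale (the study display is 51 × 25.5 cm at 1920 × 1080 — non-square
pixels) and the per-sample distance, so the screen subtends ~46° × 24° at
the nominal 60 cm. The two eyes are averaged where both are valid; one
valid eye is used alone; otherwise the sample is invalid.

A sample opens a saccade when speed exceeds **30°/s** *and* acceleration
exceeds **8000°/s²**; the saccade extends while speed stays above 30°/s.
Saccades below **0.5°** amplitude are discarded (microsaccades/tracker
artefacts), fixations longer than **500 ms** are discarded (smooth-pursuit
removal), and invalid runs longer than 100 ms split events while shorter
runs are bridged by linear interpolation.

Numerical choices that the thresholds alone do not fix:

* **Differentiation**: two-point finite differences of position; speed is
  the magnitude of the sample-to-sample displacement over Δt, acceleration
  the derivative of speed.
* **Smoothing**: none by default (`smooth_window = 1`). At 60 Hz, a
  3-sample median filter erases the single-sample velocity transient that
  small saccades rely on to cross the 8000°/s² threshold; enabling it
  (`smooth_window = 3`) makes saccades below roughly 2.8° undetectable at
  this sampling rate. The filter remains available for noisy trackers.
* **Minimum saccade duration**: 2 moving samples; single-sample crossings
  are treated as noise.
* Fixation durations are compared against the 500 ms bound with a 1 ns
  tolerance so that sampling-grid durations landing exactly on the bound
  are retained.

A robustness property holds on synthetic cohorts and is asserted in the
test suite: removing the 500 ms filter leaves the direction of the group
differences unchanged.

# The four biomarkers

* **Median saccade amplitude** — one value per participant × stimulus; the
  median because amplitude distributions are right-skewed. The three
  images are concatenated into a single stream before summarising.
* **BCEA (95%)** — saccades are aligned by translating each start point to
  the origin; the endpoint cloud's ellipse area is
  `2kπ σ_dx σ_dy √(1−ρ²)` with `k = −ln(1−0.95) ≈ 2.9957`. Degenerate
  clouds (under 3 points, zero variance, collinear) return 0 with a
  `degenerate` attribute rather than erroring, keeping cohort tables
  rectangular.
* **SLV** — the fraction of aligned endpoints inside the gaze-relative
  mask; controls are scored against both the moderate and the advanced
  mask (two columns), impaired groups against their own.
* **KDE score** — for each 30 fps video frame, non-saccadic gaze samples
  are averaged per frame; the control group's frame positions define a
  Gaussian KDE `f(x,y) = (1/n) Σᵢ N(x; xᵢ, h²) N(y; yᵢ, h²)` with
  `h = 1.5°` (≈ foveal extent), evaluated exactly by direct summation.
  Impaired participants are scored against the control model; each control
  is scored leave-one-out. Frame-wise control outliers are removed first
  by a seeded isolation forest (contamination 0.05, 100 trees — parameters
  the method leaves open; implemented in C++ because it runs once per
  frame). The per-participant summary is the mean over defined frames.
  KDE is computed for videos only; the `h` exponent is `−d²/(2h²)`, i.e.
  `h` is the kernel standard deviation.

# Statistics and ROC

Group tests are nonparametric throughout (small samples, skewed measures):
Kruskal–Wallis across the three groups (`stats::kruskal.test`), then
pairwise two-tailed Mann–Whitney tests with Bonferroni correction for the
three comparisons. `U` is reported as `min(U_a, U_b)`; p-values are exact
below a combined n of 20 without ties, otherwise normally approximated with
tie and continuity corrections; the rank effect size is `η² = Z²/N` from
the tie-corrected Z.

ROC curves sweep thresholds at midpoints between adjacent unique scores, so
ties are never split and the trapezoid AUC equals the Mann–Whitney
pair-count probability `U/(n₁n₂)`. The direction of impairment is declared
per feature (amplitude, BCEA, KDE: lower = impaired; SLV: higher =
impaired). Sensitivity at 90% specificity reads the empirical step function
(largest TPR with FPR ≤ 0.10) without interpolation — reproducible at small
n. Group-median confidence intervals use a percentile bootstrap (B = 2000
by default). Windowed analysis restricts KDE traces to user-supplied time
windows before the ROC; a sliding-window scan utility reports windowed AUCs
for inspection but never selects a window for inference — window choice is
the analyst's, made a priori.

# Multi-feature classifier

Per stimulus, each participant contributes 87 features (86 for images): an
84-cell saccade map — aligned endpoints binned on a fixed 12 × 7 grid of
4°×4° cells spanning ±24° × ±14°, counts normalised to proportions — plus
median amplitude, BCEA, and (videos) the KDE mean. The exact feature bank
behind the published analysis is not public; this grid is a declared
stand-in consistent with the saccade-map tradition, and
`build_feature_table(map_fun=)` accepts any replacement. For the
classifier the map is smoothed with a 1-cell Gaussian blur: raw 4° bin
proportions at realistic saccade counts (a few hundred per recording) are
noise-dominated, and saccade-map analyses conventionally smooth the density
before use. `saccade_map_features()` itself defaults to raw proportions.

Features are standardised on the training fold; the Gaussian kernel
`K_ij = exp(−γ‖Xᵢ−Xⱼ‖²)` is double-centred and eigendecomposed (kernel
PCA); projections are α-weighted kernel sums scaled by 1/√λ, with
out-of-fold points projected through the centred cross-kernel. (A printed
squared-distance variant `γ‖Xᵢ−Xⱼ‖²` is retained behind
`kernel_matrix(form = "printed")` for comparison; it is not a kernel and is
not used.) Classification is discrete AdaBoost over depth-limited `rpart`
trees.

Two estimator details matter for honest leave-one-out evaluation:

* **Class-balanced initial weights.** Every LOO fold is imbalanced by
  exactly one sample against the held-out participant's class; with
  uniform initial weights this tilts every held-out score away from its
  own class and biases the pooled null AUC to ≈ 0.38. Balanced weights
  restore a median null AUC of ≈ 0.5 under label permutation.
* **Fold-centred scores.** Held-out decision scores are centred on the
  fold's mean training score before pooling, removing fold-to-fold offsets
  that would otherwise distort the pooled ROC.

Hyperparameters (kernel width, component count, tree depth, learning rate)
are selected by stratified inner cross-validation **within each training
fold only**; the suite verifies that corrupting a held-out row never
changes that fold's fitted model.

# The synthetic cohort: what is planted and what is not

No gaze data from the original paradigm are deposited, so the generator is
a first-class, tested module that emulates the study conditions: 25/15/15
participants (none/moderate/advanced), two videos of 301 s and 307 s at 30
frames/s, three 60 s images, 60 Hz binocular recording on the 51 × 25.5 cm
/ 1920 × 1080 px screen at ~60 cm.

Gaze alternates fixations and saccades. Fixation durations are normal
(mean 300 ms, SD 100 ms, truncated at 100 ms) — long enough tails to
exercise the 500 ms discard rule. All participants share per-stimulus
saliency targets (videos: a new target every 1–3 s; images: a fixed set of
10–20 points); individual viewing adds a per-recording idiosyncratic
offset, local exploratory scatter (SD 1.5°, tripled for a 25% excursion
fraction, giving realistic heavy-tailed amplitudes), endpoint scatter, and
per-sample jitter. Two eyes are rendered as a common point plus independent
0.2° jitter; viewing distance sways slowly around 60 cm; 2% of samples are
flagged invalid in blink-like runs of 3–10 samples.

**Saccade kinematics are built for the detector, not for biology.** At
60 Hz the acceleration threshold of 8000°/s² requires a single-sample step
above ~2.2°, which a linear ramp cannot deliver for small saccades. The
generator therefore plants a front-loaded profile: a first step of ≥ 2.8°
(onset acceleration ≈ 10⁴ °/s² from rest) followed by corrective steps of
at least 0.55°/sample, overshooting and returning for amplitudes below the
first step — so even sub-0.5° saccades are kinematically detectable and the
amplitude filter, not the detector, removes them. Near the screen edge the
overshoot aims toward the centre instead, because the pixel clamp would
otherwise flatten the first step below threshold.

The planted group effects mirror the directions and approximate effect
sizes of the phenomenon under study:

| Effect | none | moderate | advanced | shows up in |
|---|---|---|---|---|
| `amplitude_scale` | 1 | 0.9 | 0.6 | amplitude, BCEA ↓ in advanced |
| `spread_scale` | 1 | 0.95 | 0.85 | endpoint scatter |
| `scotoma_attraction` | 0 | 0.15 | 0.05 | SLV ↑ in moderate |
| `idiosyncrasy` (°) | 0.8 | 2.0 | 1.2 | KDE ↓ in moderate |

`amplitude_scale` contracts the whole scan path toward the initial central
fixation. The per-recording log-normal gain (SD 0.35) and the screen bound
are applied to the shared aim process *before* this contraction, so every
group views a contraction of the same bounded process and the group
amplitude-median ratio recovers the planted scale to within sampling noise.
The gain is what keeps group separations at realistic levels (AUC ~0.75–0.9
rather than 1.0). Scotoma-attracted saccades land uniformly in the near
band of the mask (cells within 6° of its inner edge) and *replace*
exploratory excursions of similar magnitude via a shared uniform draw, so
SLV rises without inflating the amplitude distribution; per-recording
log-normal heterogeneity (SD 0.9, mean preserved) keeps the SLV separation
realistic. The idiosyncratic offset is constant within a recording — a
stable personal bias that depresses cross-participant gaze similarity
without entering saccadic displacements — and `idiosyncrasy_window`
confines it to a time interval, planting the temporally localised
separation the windowed KDE analysis exploits.

**What the generator does not emulate:** saccadic main-sequence dynamics,
smooth pursuit of moving objects, actual image/video saliency structure,
pupil or blink physiology, tracker-specific noise spectra, or learning
effects over the session. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well-calibrated (detector recovery,
oracle equivalence, null calibration, planted-effect recovery and
monotonicity, leakage-free evaluation) — not that real patients' eye
movements would separate this well.

# Problem sizes in tests and scripts

The test suite and the reproduction script run the same machinery at
reduced scale, a deliberate choice so the full chain reruns in minutes:
cohorts of 2–25 participants per group, videos of 20–180 s, images of
12–60 s, 10–20 replicate cohorts for calibration checks, and compact
classifier grids. The `analysis/` drivers use 12/8/8 participants over a
120 s and a 90 s video plus two 45 s images; the statistical-calibration
checks use 2000 null simulations at the study's 25/15/15 group sizes; the
classifier's null-permutation and margin checks run at the study's
25-vs-15 pair size. Every stochastic stage is seeded, and identical seeds
reproduce bit-identical cohorts and reports.

# Known limitations

* The 84-feature bank is a stand-in; published results used an unavailable
  supplementary definition. The bank is pluggable.
* The SLV binarisation cutoff (20 dB) and cell-based loss region are
  repository decisions where the method description is silent.
* Isolation-forest parameters (contamination 0.05, 100 trees) are
  defaults, not published values.
* Pooled-LOO AUC remains a noisy estimate at n ≤ 40 even after balancing
  and centring; the suite asserts distributional properties (medians over
  seeds, fractions within bands), not single-run values.
* The generator's effect sizes were set from the reported direction and
  approximate magnitude of each group difference; they are study
  conditions, not quantities fitted to any test outcome.
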