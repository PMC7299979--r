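#!/usr/bin/env Rscript
# Compute the four eye-movement biomarkers per participant x stimulus:
# median saccade amplitude, 95% BCEA of aligned saccade endpoints, the
# proportion of saccades landing on visual-field loss locations (SLV,
# against the moderate and/or advanced scotoma mask), and for videos the
# mean per-frame KDE probability score against the control group's gaze.
# The three images are concatenated into one "images" stream.
#
# Reads results/gaze_cohort.csv; writes results/biomarkers.csv and the
# per-frame KDE traces for the windowed analysis.

suppressPackageStartupMessages(library(gazemarker))

seed <- 20260930
rec <- read_recordings("results/gaze_cohort.csv")
# rebuild the config the cohort was generated under (samples are identical;
# only stimulus metadata and masks are needed here)
stimuli <- list(stimulus_spec("video1", "video", 120),
                stimulus_spec("video2", "video", 90),
                stimulus_spec("image1", "image", 45),
                stimulus_spec("image2", "image", 45))
cfg <- cohort_config(12, 8, 8, stimuli = stimuli, seed = seed)

bundle <- build_biomarkers(rec, config = cfg, kde_seed = seed)
utils::write.csv(bundle$biomarkers, "results/biomarkers.csv",
                 row.names = FALSE)
for (v in names(bundle$kde_traces)) {
  kt <- bundle$kde_traces[[v]]
  tr <- data.frame(frame_t = rep(kt$frame_t, each = length(kt$groups)),
                   participant = rep(seq_along(kt$groups),
                                     times = length(kt$frame_t)),
                   group = rep(kt$groups, times = length(kt$frame_t)),
                   score = as.vector(kt$scores))
  utils::write.csv(tr, sprintf("results/kde_trace_%s.csv", v),
                   row.names = FALSE)
}
saveRDS(bundle, "results/bundle.rds")  # intermediate for 04/05 (local only)

b <- bundle$biomarkers
for (feat in c("median_amp_deg", "bcea95_deg2", "kde_mean")) {
  agg <- aggregate(stats::as.formula(paste(feat, "~ group + stimulus")),
                   b, function(v) round(median(v, na.rm = TRUE), 3))
  cat("median", feat, "by group x stimulus:\n")
  print(agg, row.names = FALSE)
}
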