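#!/usr/bin/env Rscript
# Generate the synthetic free-viewing cohort and its perimetry inputs.
#
# Cohort design mirrors the study: three groups (no / moderate / advanced
# simulated visual-field loss), every participant viewing the same stimuli.
# Sizes and stimulus durations here are scaled down from the study design
# (25/15/15 over two ~5 min videos and three 60 s images) so the whole
# workflow reruns in minutes; scale up via the constants below.
#
# Outputs under results/: gaze CSV + screen JSON, perimetry JSONs.

suppressPackageStartupMessages(library(gazemarker))

seed <- 20260930
dir.create("results", showWarnings = FALSE)

stimuli <- list(stimulus_spec("video1", "video", 120),
                stimulus_spec("video2", "video", 90),
                stimulus_spec("image1", "image", 45),
                stimulus_spec("image2", "image", 45))
# the moderate group's idiosyncratic viewing is concentrated in t in
# [30, 90) s of the videos, the structure the windowed analysis exploits
eff <- effect_spec(idiosyncrasy_window = c(30, 90))
cfg <- cohort_config(12, 8, 8, stimuli = stimuli, seed = seed, effect = eff)

rec <- generate_cohort(cfg)
write_recordings(rec, "results/gaze_cohort.csv")

for (sev in c("none", "moderate", "advanced")) {
  per <- synthetic_perimetry(sev)
  write_perimetry(per$left, sprintf("results/perimetry_%s_left.json", sev))
  write_perimetry(per$right, sprintf("results/perimetry_%s_right.json", sev))
}

n_sac <- sum(vapply(rec, function(r) nrow(r$truth$saccades), numeric(1)))
cat(sprintf("wrote %d recordings (%d participants x %d stimuli), %d planted saccades\n",
            length(rec), 28, length(stimuli), n_sac))
cat("gaze: results/gaze_cohort.csv (+ .json sidecar); perimetry: results/perimetry_*.json\n")
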