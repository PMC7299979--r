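#!/usr/bin/env Rscript
# Convert raw pixel gaze to degrees, merge the two eyes, and classify
# samples into saccades, fixations and discards using the velocity (>30
# deg/s) and acceleration (>8000 deg/s^2) criteria, the 0.5 deg minimum
# amplitude, and the 500 ms maximum fixation duration (pursuit removal).
#
# Reads results/gaze_cohort.csv; writes results/events.csv and a per-
# recording event summary.

suppressPackageStartupMessages(library(gazemarker))

rec <- read_recordings("results/gaze_cohort.csv")
rows <- list()
summ <- list()
tmp <- tempfile(fileext = ".csv")
for (r in rec) {
  ev <- detect_events(recording_to_trace(r))
  write_events(ev, r$participant, r$stimulus, tmp)
  rows[[length(rows) + 1L]] <- utils::read.csv(tmp)
  summ[[length(summ) + 1L]] <- data.frame(
    participant = r$participant, group = r$group, stimulus = r$stimulus,
    n_saccades = nrow(ev$saccades), n_fixations = nrow(ev$fixations),
    n_small = sum(ev$discarded$reason == "small_saccade"),
    n_long_fix = sum(ev$discarded$reason == "long_fixation"),
    n_gaps = sum(ev$discarded$reason == "invalid_gap"))
}
events <- do.call(rbind, rows)
summ <- do.call(rbind, summ)
utils::write.csv(events, "results/events.csv", row.names = FALSE)
utils::write.csv(summ, "results/event_summary.csv", row.names = FALSE)

cat(sprintf("classified %d recordings: %d saccades retained, %d small discarded, %d long fixations discarded\n",
            nrow(summ), sum(summ$n_saccades), sum(summ$n_small),
            sum(summ$n_long_fix)))
agg <- aggregate(n_saccades ~ group, summ, median)
cat("median saccades per recording by group:",
    paste(agg$group, agg$n_saccades, collapse = "; "), "\n")
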