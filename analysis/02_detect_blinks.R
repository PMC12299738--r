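#!/usr/bin/env Rscript
# Stage 2: preprocess and detect blinks.
#
# Each recording is notch-filtered at 50 Hz and band-passed 0.5-20 Hz
# (zero-phase 4th-order Butterworth). The Fp1 channel, band-passed
# 0.5-16 Hz, serves as vEOG; an automatically selected stereotypical blink
# is matched against it by normalized cross-correlation, events are
# anchored at the vEOG maximum (T0), and blinks less than 3 s apart are
# discarded. Because the cohort is synthetic we can also score detection
# against ground truth.

suppressMessages(library(broeeg))

sessions <- list.files("scratch/sessions", full.names = TRUE)
stopifnot(length(sessions) > 0)
dir.create("scratch/detected", showWarnings = FALSE)

rows <- list()
for (path in sessions) {
  session <- readRDS(path)
  s <- as.integer(sub(".*subject_(\\d+)\\.rds", "\\1", path))
  truth <- session$ground_truth$blink_peak_samples
  for (sys in c("textile", "dry")) {
    rec <- bandpass_filter(notch_filter(session[[sys]]), 0.5, 20)
    ev <- detect_blinks(rec)
    saveRDS(list(recording = rec, events = ev),
            sprintf("scratch/detected/subject_%02d_%s.rds", s, sys))
    tol <- 0.1 * rec$fs
    hits <- vapply(ev$peak_samples, function(p) any(abs(truth - p) <= tol), logical(1))
    found <- vapply(truth, function(g) any(abs(ev$peak_samples - g) <= tol), logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, system = sys,
      n_truth = length(truth), n_detected = length(ev$peak_samples),
      precision = mean(hits), recall = mean(found)
    )
  }
}
det <- do.call(rbind, rows)
write.table(det, "results/02_detection_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf(
  "detection over %d recordings: precision %.3f-%.3f, recall %.3f-%.3f\n",
  nrow(det), min(det$precision), max(det$precision),
  min(det$recall), max(det$recall)
))
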