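#!/usr/bin/env Rscript
# Step 2 — conventional accuracy metrics.
#
# Reads the trial pairs from step 1, preprocesses each (clip to the
# co-tracked span, resample the camera stream onto the reference time base,
# align coordinates at the first common index-MCP sample) and computes the
# conventional agreement measures: per-signal correlations and MAEs,
# fingertip-distance correlations, segment-length errors, and the trial's
# static/dynamic parameters.

suppressPackageStartupMessages(library(handtrackr))

manifest <- read.csv("results/01_manifest.csv")
rows <- list()
for (i in seq_len(nrow(manifest))) {
  mrow <- manifest[i, ]
  ref <- read_trajectory(mrow$ref_file)
  cam <- read_trajectory(mrow$cam_file)
  pair <- preprocess_pair(ref, cam)
  rep <- accuracy_report(pair, task = mrow$task)
  write_accuracy_report(rep, sprintf("results/02_report_%s.json", mrow$name))
  prox <- grep("proximal", names(rep$segment_errors))
  rows[[i]] <- data.frame(
    name = mrow$name, task = mrow$task,
    corr_signal = rep$corr_signal, mae_avg_mm = rep$mae_avg,
    corr_fingertip_mean = mean(rep$corr_fingertip),
    proximal_err_mm = mean(rep$segment_errors[prox]),
    distal_err_mm = mean(rep$segment_errors[grep("distal",
                                                 names(rep$segment_errors))]),
    wrist_height_mm = rep$wrist_height_mm, speed_mm_s = rep$speed_mm_s)
  cat(sprintf("%-16s corr_signal %.4f  MAE %6.3f mm  proximal err %5.2f mm\n",
              mrow$name, rep$corr_signal, rep$mae_avg,
              mean(rep$segment_errors[prox])))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/02_conventional_metrics.csv", row.names = FALSE)

cat("\nThe clean pairs sit near the ideal (corr ~ 1, MAE ~ 0); the noisy",
    "\nlagged pair loses correlation, and the biased pair shows the proximal",
    "\nsegment error at the injected 15 mm while other segments stay clean.\n")
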