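#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs and record their ground
# truth in the run manifest. Later stages rebuild the same objects from
# the same seeds (see analysis/00_config.R), so only small examples are
# materialized on disk: the first 100 tracks of one wild-type cell and
# 100 peaks of one peak set.

source("analysis/00_config.R")
dir.create("results", showWarnings = FALSE)

manifest <- list()

fast <- fast_tracksets()
for (cond in names(fast)) {
  for (ts in fast[[cond]]) {
    gt <- ground_truth(ts)
    manifest[[sprintf("fast_%s_seed%d", cond, gt$seed)]] <- gt
  }
}
example <- fast$WT[[1]]
example$tracks <- example$tracks[1:100]
write_tracks_csv(example, "results/example_tracks_WT_cell01.csv")

slow <- slow_dwellsets()
for (cond in names(slow)) {
  manifest[[paste0("slow_", cond)]] <- ground_truth(slow[[cond]])
}

for (ti in titrations()) {
  manifest[[paste0("titration_", ti$probe_id[1])]] <- ground_truth(ti)
}

pk <- peaksets()
for (cond in names(pk)) {
  manifest[[paste0("peaks_", cond)]] <- ground_truth(pk[[cond]])
}
write_peaks(pk$WT_high[1:100, ], "results/example_peaks_WT_high.bed",
            "results/example_peaks_WT_high.fa")

write_run_manifest(manifest, "results/run_manifest.json")
n_jumps <- length(extract_jumps(fast$WT[[1]]))
cat(sprintf(
  "simulated %d fast-regime cells (~%d jumps/cell), %d dwell sets, %d titrations, %d peak sets\n",
  sum(lengths(fast)), n_jumps, length(slow), length(PROBE_KDS),
  length(pk)))
cat("manifest: results/run_manifest.json\n")
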