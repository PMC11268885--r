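#!/usr/bin/env Rscript
# Stage 3 — time-resolved IEM decoding during encoding: simulate forward-model
# sensor epochs for each subject (three items at 0, 1.5, 3.0 s), preprocess
# (band-pass, baseline, variance rejection), decode each serial position's
# location with leave-one-block-out cross-validation, and test the group slope
# time courses with the cluster permutation test. Writes results/03_iem/.

suppressPackageStartupMessages(library(ringmem))

out_dir <- "results/03_iem"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_subjects <- 8
n_trials <- 144
fs <- 100
seed0 <- 3000

times <- NULL
slopes <- vector("list", 3)  # per serial position: subjects x time

for (s in seq_len(n_subjects)) {
  d <- generate_design(n_trials, n_blocks = 8, seed = seed0 + s)
  sim <- simulate_eeg(d, n_sensors = 16, snr = 1, fs = fs,
                      tmin = -0.5, tmax = 4.5,
                      item_latencies = c(0, 1.5, 3.0), envelope_width = 0.8,
                      seed = seed0 + 500 + s)
  pp <- preprocess(sim$epochs, band = c(2, 50), target_fs = NULL,
                   baseline = c(-0.3, -0.1), reject_multiplier = 5)
  ep <- pp$epochs
  if (length(pp$rejected))
    cat(sprintf("subject %d: rejected %d high-variance trial(s)\n",
                s, length(pp$rejected)))
  times <- ep$times
  for (pos in 1:3) {
    lab <- ep$design[[paste0("loc", pos, "_nom")]]
    dec <- suppressWarnings(decode_timecourse(ep, lab))
    slopes[[pos]] <- rbind(slopes[[pos]], dec$slope)
  }
}

for (pos in 1:3) {
  df <- data.frame(time = times, t(slopes[[pos]]))
  names(df) <- c("time", paste0("s", seq_len(n_subjects)))
  write.csv(df, file.path(out_dir, sprintf("slopes_item%d.csv", pos)),
            row.names = FALSE)
}

cat("\nCluster permutation test on group slopes (cluster alpha 0.001):\n")
summary_rows <- NULL
for (pos in 1:3) {
  cr <- cluster_permutation(slopes[[pos]], null_value = 0,
                            cluster_alpha = 0.001, n_perm = 1000,
                            seed = seed0 + pos)
  sig <- cr$clusters[cr$clusters$p_corrected < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      summary_rows <- rbind(summary_rows, data.frame(
        item = pos, t_start = times[sig$start[i]], t_end = times[sig$end[i]],
        size = sig$size[i], p = sig$p_corrected[i]))
  }
  cat(sprintf("  item %d: %d significant cluster(s)\n", pos, nrow(sig)))
}
if (!is.null(summary_rows)) {
  print(summary_rows, row.names = FALSE)
  write.csv(summary_rows, file.path(out_dir, "clusters.csv"),
            row.names = FALSE)
  cat("Each item's decodable window should track its presentation interval\n")
  cat("(items appear at 0, 1.5 and 3.0 s with 0.8 s envelopes).\n")
}
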