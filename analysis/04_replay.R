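#!/usr/bin/env Rscript
# Stage 4 — sequential replay during the recall period: simulate recall epochs
# with a planted forward replay of the color sequence (130 ms inter-item lag),
# decode the three color items per subject, and quantify the sequence with the
# forward-minus-reverse cross-correlation asymmetry, peak-lag estimate,
# transition-matrix similarity, and the label-shuffle permutation threshold.
# Writes results/04_replay/.

suppressPackageStartupMessages(library(ringmem))

out_dir <- "results/04_replay"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(seed = 4000, n_subjects = 8, n_trials = 96,
                       replay_lag = 0.13, n_perm = 1000)
res <- suppressWarnings(run_pipeline(cfg, out_dir = out_dir))

prof <- res$replay$profile
cat(sprintf("Planted inter-item lag: %.0f ms\n", cfg$replay_lag * 1000))
cat(sprintf("Recovered peak lag:     %.0f ms\n", res$replay$peak_lag * 1000))
cat(sprintf("Transition-matrix similarity r = %.3f\n", res$replay$similarity))
cat(sprintf("Peak asymmetry %.3f vs permutation threshold %.3f (p = %.4g)\n",
            res$replay$permutation$observed, res$replay$permutation$threshold,
            res$replay$permutation$p))
cat("\nEmpirical transition matrix at the peak lag (rows = leading item):\n")
print(round(res$replay$empirical_matrix, 3))
cat("\nA clean forward replay concentrates correlation in the (1,2) and (2,3)\n")
cat("cells, matching the theoretical superdiagonal pattern.\n")
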