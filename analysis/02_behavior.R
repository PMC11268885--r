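#!/usr/bin/env Rscript
# Stage 2 — behavioral analysis of the simulated cohort: memory precision
# (1/sigma) per domain x condition x serial position, within-subject circular
# correlations of location vs. color trajectory errors, and the group-level
# binned trajectory correlation for AT and MAT. Reads stage-1 tables, writes
# results/02_behavior/.

suppressPackageStartupMessages(library(ringmem))

in_dir <- "results/01_simulate"
out_dir <- "results/02_behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

subjects <- sort(sub("design_(s[0-9]+)\\.csv", "\\1",
                     list.files(in_dir, pattern = "^design_")))

prec_all <- NULL
cors_all <- NULL
binned_tabs <- list(AT = NULL, MAT = NULL)

for (s in seq_along(subjects)) {
  d <- read.csv(file.path(in_dir, sprintf("design_%s.csv", subjects[s])))
  r <- read.csv(file.path(in_dir, sprintf("reports_%s.csv", subjects[s])))
  err <- response_errors(d, r)
  tr <- trajectory_errors(err)

  p <- precision_summary(err)
  p$subject <- s
  prec_all <- rbind(prec_all, p)

  for (cond in c("AT", "MAT")) for (lg in c("12", "23", "13")) {
    le <- tr$error[tr$condition == cond & tr$leg == lg &
                     tr$domain == "location"]
    ce <- tr$error[tr$condition == cond & tr$leg == lg & tr$domain == "color"]
    cors_all <- rbind(cors_all, data.frame(
      subject = s, condition = cond, leg = lg,
      r = subject_trajectory_correlation(le, ce)))
  }
  for (cond in c("AT", "MAT")) {
    sel <- tr$condition == cond & tr$leg == "12"
    binned_tabs[[cond]] <- rbind(binned_tabs[[cond]], data.frame(
      subject = s,
      loc_err = tr$error[sel & tr$domain == "location"],
      col_err = tr$error[sel & tr$domain == "color"]))
  }
}

write.csv(prec_all, file.path(out_dir, "precision.csv"), row.names = FALSE)
write.csv(cors_all, file.path(out_dir, "subject_correlations.csv"),
          row.names = FALSE)

g_at <- group_binned_correlation(binned_tabs$AT)
g_mat <- group_binned_correlation(binned_tabs$MAT)
write.csv(rbind(cbind(condition = "AT", g_at$points),
                cbind(condition = "MAT", g_mat$points)),
          file.path(out_dir, "binned_points.csv"), row.names = FALSE)
jsonlite::write_json(
  list(AT = list(r = g_at$r, p = g_at$p, n_points = g_at$n_points),
       MAT = list(r = g_mat$r, p = g_mat$p, n_points = g_mat$n_points)),
  file.path(out_dir, "binned_correlation.json"), auto_unbox = TRUE, digits = NA)

agg <- aggregate(precision ~ domain + condition,
                 prec_all[prec_all$position == "all", ], mean)
cat("Mean memory precision (1/sigma, radians^-1):\n")
print(agg, row.names = FALSE)
cat(sprintf("\nGroup binned trajectory correlation (leg 1-2, %d points each):\n",
            g_at$n_points))
cat(sprintf("  AT:  r = %.3f (p = %.4g)\n  MAT: r = %.3f (p = %.4g)\n",
            g_at$r, g_at$p, g_mat$r, g_mat$p))
cat("The AT-only coupling planted in stage 1 lifts the AT correlation above the\n")
cat("MAT correlation, which stays near zero (cohort-to-cohort spread is wide at\n")
cat("this cohort size; the acceptance suite quantifies the recovery rate).\n")
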