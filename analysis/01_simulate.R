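#!/usr/bin/env Rscript
# Step 1: simulate a cohort of recording sessions.
#
# Three sessions of 8 simultaneously recorded units each, at the standard
# trial structure (20 tone-cloud frequencies x 50 repeats x LED on/off =
# 2000 trials, ~19% spontaneous movement) and the default condition
# modulation: movement multiplies baseline rates by 1.38 and the tuned
# evoked component by 0.5; VIP activation multiplies both by 1.5 during
# the LED. Raw event tables land under scratch/sessions/ (they run to
# megabytes); ground truth is stored alongside for later comparison.

suppressPackageStartupMessages(library(statecoding))

seed <- 20260929L
out_root <- "scratch/sessions"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(n_units = 8)
cohort <- generate_cohort(cfg, n_sessions = 3, seed = seed)

for (i in seq_along(cohort)) {
  sdir <- file.path(out_root, sprintf("session-%02d", i))
  write_session(cohort[[i]]$session, sdir)
  write_ground_truth(cohort[[i]]$ground_truth,
                     file.path(sdir, "ground_truth.json"))
  gt <- cohort[[i]]$ground_truth
  cat(sprintf("session %d: %d trials, %d units (%d NS / %d BS), %.1f%% movement trials\n",
              i, nrow(cohort[[i]]$session$trials), nrow(gt$units),
              sum(gt$units$unit_class == "NS"),
              sum(gt$units$unit_class == "BS"),
              100 * mean(gt$trials$movement)))
}
cat("wrote", length(cohort), "sessions under", out_root, "\n")
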