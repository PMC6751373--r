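#!/usr/bin/env Rscript
# Step 4: paired group comparisons with FDR control.
#
# Loads the per-unit metrics and pair correlations from steps 2-3, runs
# two-tailed Wilcoxon signed-rank tests of each non-Still condition
# against Still -- evoked rate, stimulus information and encoding
# efficiency as a three-test Benjamini-Hochberg family per unit class;
# signal and noise correlations as a two-test family pooled across
# classes -- and writes the canonical result trio (results.tsv,
# pairs.tsv, stats.json) with 1000-iteration bootstrap CIs.

suppressPackageStartupMessages(library(statecoding))

results <- read.table("results/unit_metrics.tsv", header = TRUE, sep = "\t")
pairs <- read.table("results/pair_correlations.tsv", header = TRUE, sep = "\t")

set.seed(29)
stats <- group_statistics(results, pairs, q = 0.05, n_boot = 1000)
paths <- write_results(results, pairs, stats, "results")
cat("wrote", paste(basename(paths), collapse = ", "), "under results/\n\n")

for (cmp in names(stats)) {
  cat(cmp, "\n")
  for (cls in setdiff(names(stats[[cmp]]), "correlations")) {
    for (ms in names(stats[[cmp]][[cls]])) {
      r <- stats[[cmp]][[cls]][[ms]]
      cat(sprintf("  %-3s %-12s n=%2d  p=%7.4f  r=%5.3f  %s  mean %% change %+6.1f (CI %+.1f to %+.1f)\n",
                  cls, ms, r$n, r$p, r$r_effect,
                  ifelse(r$significant_after_fdr, "sig.", "ns  "),
                  r$pct_change$mean_pct, r$pct_change$ci[1],
                  r$pct_change$ci[2]))
    }
  }
  if (!is.null(stats[[cmp]][["correlations"]])) {
    for (ms in names(stats[[cmp]][["correlations"]])) {
      r <- stats[[cmp]][["correlations"]][[ms]]
      cat(sprintf("  %-16s n=%3d  p=%7.4f  r=%5.3f  %s  mean diff %+7.4f (CI %+.4f to %+.4f)\n",
                  paste0(ms, " corr"), r$n, r$p, r$r_effect,
                  ifelse(r$significant_after_fdr, "sig.", "ns  "),
                  r$mean_diff$mean, r$mean_diff$ci[1], r$mean_diff$ci[2]))
    }
  }
  cat("\n")
}
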