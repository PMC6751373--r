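#!/usr/bin/env Rscript
# Step 3: pairwise signal/noise correlation decomposition.
#
# For every simultaneously recorded pair within a session and every
# condition, computes the total spike-count correlation in preserved
# trial order, the signal correlation (mean over within-stimulus trial
# shuffles), and the noise correlation (total minus signal), on the same
# equalizing trial subsamples as step 2. Pooled across NS/BS classes.

suppressPackageStartupMessages(library(statecoding))

dirs <- sort(list.dirs("scratch/sessions", recursive = FALSE))
stopifnot(length(dirs) > 0)
dir.create("results", showWarnings = FALSE)

all_pairs <- list()
for (d in dirs) {
  s <- read_session(file.path(d, "spikes.tsv"), file.path(d, "trials.tsv"),
                    file.path(d, "velocity.tsv"), file.path(d, "units.tsv"))
  annot <- annotate_trials(s)
  counts <- count_spikes(s)
  set.seed(23)
  p <- pair_correlations(counts, annot, n_iter = 20, n_signal_shuffles = 100)
  p$session <- s$session_id
  p$unit_a <- paste(s$session_id, p$unit_a, sep = ":")
  p$unit_b <- paste(s$session_id, p$unit_b, sep = ":")
  all_pairs[[d]] <- p
  cat(sprintf("%s: %d pairs x %d conditions\n", basename(d),
              length(unique(paste(p$unit_a, p$unit_b))),
              length(unique(p$condition))))
}
pairs <- do.call(rbind, all_pairs)
rownames(pairs) <- NULL

write.table(pairs, "results/pair_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/pair_correlations.tsv (", nrow(pairs), "rows )\n")

agg <- aggregate(cbind(r_total, r_signal, r_noise) ~ condition, pairs, mean,
                 na.action = na.omit)
cat("\ncondition means across pairs:\n")
print(agg, digits = 3)
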