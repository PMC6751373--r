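# Signal/noise decomposition of pairwise spike-count correlations.
#
# Total correlation: Pearson r between the two units' single-trial
# evoked-window counts in preserved trial order. Signal correlation: the
# same after shuffling trial order within each stimulus label (averaged
# over shuffle iterations), which destroys trial-by-trial co-variability
# but preserves shared tuning. Noise correlation: total minus signal.

#' Total spike-count correlation of a unit pair
#'
#' Pearson correlation between the spike-count vectors of two
#' simultaneously recorded units across trials in their preserved order.
#' Undefined (\code{NA}) when either vector has zero variance; such pairs
#' are excluded for that condition.
#'
#' @param counts_a,counts_b Equal-length numeric vectors (length >= 3) of
#'   per-trial evoked-window spike counts.
#' @return Pearson r, or \code{NA} if undefined.
#' @export
total_correlation <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 3)
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) return(NA_real_)
  stats::cor(counts_a, counts_b)
}

#' Signal correlation by within-stimulus trial shuffling
#'
#' On each iteration the trial order of each unit's counts is permuted
#' independently within every stimulus label, the Pearson correlation of
#' the re-paired vectors is computed, and the mean across iterations is
#' returned. Re-pairing within stimulus removes trial-to-trial noise
#' coupling while preserving each unit's stimulus tuning, so what survives
#' is correlation attributable to shared stimulus preference.
#'
#' @inheritParams total_correlation
#' @param stimulus_labels Vector of stimulus labels aligned with the counts.
#' @param n_iter Number of shuffle iterations (default 100).
#' @return Mean Pearson r over iterations, or \code{NA} if undefined.
#' @export
signal_correlation <- function(counts_a, counts_b, stimulus_labels,
                               n_iter = 100) {
  stopifnot(length(stimulus_labels) == length(counts_a), n_iter >= 1)
  if (is.na(total_correlation(counts_a, counts_b))) return(NA_real_)
  groups <- split(seq_along(stimulus_labels), stimulus_labels)
  rs <- vapply(seq_len(n_iter), function(i) {
    pa <- permute_within(groups, length(counts_a))
    pb <- permute_within(groups, length(counts_b))
    stats::cor(counts_a[pa], counts_b[pb])
  }, numeric(1))
  mean(rs)
}

permute_within <- function(groups, n) {
  p <- integer(n)
  for (g in groups) p[g] <- g[sample.int(length(g))]
  p
}

#' Noise correlation as total minus signal
#'
#' Exact subtraction; \code{NA} if either component is undefined.
#'
#' @param r_total,r_signal Correlation estimates for the same pair and
#'   condition.
#' @return \code{r_total - r_signal}.
#' @export
noise_correlation <- function(r_total, r_signal) {
  r_total - r_signal
}

#' Pairwise correlations per condition on trial-equalized subsamples
#'
#' For every simultaneously recorded unit pair and every usable condition,
#' computes total, signal and noise correlations on the same equalizing
#' trial subsamples used for the single-unit estimates, averaged across
#' subsample iterations. The analysis is agnostic to NS/BS class. Counts
#' are raw evoked-window counts (Pearson r is translation invariant, so
#' baseline subtraction would not change it).
#'
#' A pair is reported \code{NA} for a condition if any iteration leaves
#' either unit with zero count variance.
#'
#' @param counts Count table from [count_spikes()].
#' @param annot Trial annotation from [annotate_trials()].
#' @param n_iter Subsample iterations (default 100).
#' @param n_signal_shuffles Within-stimulus shuffle iterations per
#'   subsample iteration (default 100).
#' @return data.frame: \code{unit_a}, \code{unit_b}, \code{condition},
#'   \code{r_total}, \code{r_signal}, \code{r_noise}, \code{n_trials}.
#' @export
pair_correlations <- function(counts, annot, n_iter = 100,
                              n_signal_shuffles = 100) {
  eq <- equalize_trials(annot, n_iter)
  units <- sort(unique(counts$unit_id))
  nu <- length(units)
  if (nu < 2)
    return(data.frame(unit_a = integer(0), unit_b = integer(0),
                      condition = character(0), r_total = numeric(0),
                      r_signal = numeric(0), r_noise = numeric(0),
                      n_trials = integer(0)))
  ev <- matrix(0L, nrow(annot), nu)
  ev[cbind(match(counts$trial_id, annot$trial_id),
           match(counts$unit_id, units))] <- counts$evoked_count
  conds <- eq$usable_conditions
  pair_idx <- which(upper.tri(matrix(0, nu, nu)), arr.ind = TRUE)

  out <- list()
  for (cond in conds) {
    tot_acc <- matrix(0, nu, nu); sig_acc <- matrix(0, nu, nu)
    na_mask <- matrix(FALSE, nu, nu)
    n_trials <- NA_integer_
    for (it in seq_len(n_iter)) {
      draw <- eq$draws[[it]]
      rows <- draw[annot$condition[draw] == cond]
      n_trials <- length(rows)
      m <- ev[rows, , drop = FALSE]
      sds <- apply(m, 2, stats::sd)
      degenerate <- sds == 0
      rt <- suppressWarnings(stats::cor(m))
      groups <- split(seq_along(rows), annot$stimulus_bin[rows])
      sig <- matrix(0, nu, nu)
      for (s in seq_len(n_signal_shuffles)) {
        mp <- m
        for (j in seq_len(nu)) mp[, j] <- m[permute_within(groups, nrow(m)), j]
        sig <- sig + suppressWarnings(stats::cor(mp))
      }
      sig <- sig / n_signal_shuffles
      bad <- outer(degenerate, degenerate, "|")
      rt[bad] <- NA; sig[bad] <- NA
      tot_acc <- tot_acc + rt
      sig_acc <- sig_acc + sig
      na_mask <- na_mask | bad
    }
    tot <- tot_acc / n_iter; sig <- sig_acc / n_iter
    tot[na_mask] <- NA; sig[na_mask] <- NA
    out[[cond]] <- data.frame(
      unit_a = units[pair_idx[, 1]], unit_b = units[pair_idx[, 2]],
      condition = cond,
      r_total = tot[pair_idx], r_signal = sig[pair_idx],
      r_noise = tot[pair_idx] - sig[pair_idx],
      n_trials = n_trials, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
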