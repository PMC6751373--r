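# Paired nonparametric group comparisons: Wilcoxon signed-rank with the
# normal approximation, effect size r = |z|/sqrt(n), Benjamini-Hochberg
# FDR within test families, percentile bootstrap CIs, and percent-change
# summaries.

#' Paired two-tailed Wilcoxon signed-rank test (normal approximation)
#'
#' Tests the paired differences \code{y - x}. Zero differences are dropped
#' (Wilcoxon's original treatment); ranks of the absolute differences use
#' midranks, the normal-approximation variance carries the tie correction,
#' and a continuity correction of 1/2 is applied to the rank-sum deviation
#' (this keeps the approximate p within a few hundredths of exact
#' enumeration down to five informative pairs). \code{z} is signed by the
#' direction of the rank sum (positive when \code{y} tends to exceed
#' \code{x}); the p-value is two-tailed. If all differences are zero the
#' result is degenerate (\code{p = 1}, \code{z = 0}).
#'
#' @param x,y Equal-length paired samples.
#' @return List with \code{p}, \code{z}, \code{n_effective} (pairs with a
#'   nonzero difference) and \code{w} (positive-rank sum).
#' @export
wsr_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(list(p = 1, z = 0, n_effective = 0L, w = 0))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(list(p = 1, z = 0, n_effective = n, w = w_pos))
  dev <- w_pos - mu
  dev <- sign(dev) * max(abs(dev) - 0.5, 0)  # continuity correction
  z <- dev / sqrt(sigma2)
  list(p = 2 * stats::pnorm(-abs(z)), z = z, n_effective = as.integer(n),
       w = w_pos)
}

#' Wilcoxon effect size r
#'
#' \eqn{r = \sqrt{z^2 / n} = |z| / \sqrt{n}}, where \code{z} is the
#' approximate signed-rank statistic and \code{n} the number of paired
#' comparisons. Sign-invariant and non-negative.
#'
#' @param z Approximate WSR statistic.
#' @param n Number of paired comparisons (>= 1).
#' @return Effect size r.
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n >= 1)
  sqrt(z^2 / n)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Sorts the p-values ascending, finds the largest k with
#' \eqn{p_{(k)} \le k q / m}, and flags every p-value at or below
#' \eqn{p_{(k)}}. Used with m = 3 for the rate/information/efficiency
#' family and m = 2 for the signal/noise correlation family, per unit
#' class.
#'
#' @param p_values Numeric vector of p-values for one family.
#' @param q FDR level (default 0.05).
#' @param m Number of tests in the family (default \code{length(p_values)}).
#' @return Logical vector of significance flags aligned with
#'   \code{p_values}.
#' @export
bh_fdr <- function(p_values, q = 0.05, m = length(p_values)) {
  o <- order(p_values)
  ps <- p_values[o]
  k <- which(ps <= seq_along(ps) * q / m)
  if (!length(k)) return(rep(FALSE, length(p_values)))
  p_values <= ps[max(k)]
}

#' Percentile bootstrap confidence interval
#'
#' 95\% CI from the 2.5 and 97.5 percentiles of the statistic over
#' \code{n_boot} resamples drawn with replacement.
#'
#' @param values Numeric sample (length >= 2; NAs dropped).
#' @param statistic \code{"mean"} or \code{"median"}.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param level Confidence level (default 0.95).
#' @return Numeric c(lo, hi).
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "median"),
                         n_boot = 1000, level = 0.95) {
  statistic <- match.arg(statistic)
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  f <- if (statistic == "mean") mean else stats::median
  n <- length(values)
  boots <- vapply(seq_len(n_boot),
                  function(i) f(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(boots, c(a, 1 - a)))
}

#' Mean percent change between paired conditions
#'
#' Per-unit percent change \eqn{100 (b - a) / |a|} for units with a nonzero
#' reference value, averaged across units, with a bootstrap CI over units.
#' Units whose reference value is zero are excluded from the percent
#' summary only (they still enter the signed-rank test).
#'
#' @param ref_values Reference-condition values (e.g. Still), one per unit.
#' @param other_values Comparison-condition values, paired.
#' @param n_boot Bootstrap iterations for the CI (default 1000).
#' @return List with \code{mean_pct}, \code{ci} (length 2), \code{n_used}.
#' @export
pct_change <- function(ref_values, other_values, n_boot = 1000) {
  stopifnot(length(ref_values) == length(other_values))
  keep <- !is.na(ref_values) & !is.na(other_values) & ref_values != 0
  if (!any(keep))
    return(list(mean_pct = NA_real_, ci = c(NA_real_, NA_real_), n_used = 0L))
  pc <- 100 * (other_values[keep] - ref_values[keep]) / abs(ref_values[keep])
  ci <- if (length(pc) >= 2) bootstrap_ci(pc, "mean", n_boot)
        else c(NA_real_, NA_real_)
  list(mean_pct = mean(pc), ci = ci, n_used = as.integer(sum(keep)))
}

summarize_condition <- function(v, n_boot) {
  v <- v[!is.na(v)]
  if (length(v) < 2) {
    val <- if (length(v)) v else NA_real_
    return(list(mean = val, mean_ci = c(NA_real_, NA_real_),
                median = val, median_ci = c(NA_real_, NA_real_)))
  }
  list(mean = mean(v), mean_ci = bootstrap_ci(v, "mean", n_boot),
       median = stats::median(v),
       median_ci = bootstrap_ci(v, "median", n_boot))
}

compare_measure <- function(wide_a, wide_b, n_boot, pct = TRUE) {
  keep <- !is.na(wide_a) & !is.na(wide_b)
  a <- wide_a[keep]; b <- wide_b[keep]
  ts <- wsr_test(a, b)
  rec <- list(
    n = length(a), z = ts$z, p = ts$p,
    r_effect = if (length(a) >= 1) effect_size_r(ts$z, length(a)) else NA_real_,
    ref = summarize_condition(a, n_boot),
    other = summarize_condition(b, n_boot))
  if (pct) {
    rec$pct_change <- pct_change(a, b, n_boot)
  } else {
    dd <- b - a
    rec$mean_diff <- list(
      mean = if (length(dd)) mean(dd) else NA_real_,
      ci = if (length(dd) >= 2) bootstrap_ci(dd, "mean", n_boot)
           else c(NA_real_, NA_real_))
  }
  rec
}

#' Group statistics across conditions with FDR control
#'
#' For each requested comparison (a condition against the \code{Still}
#' reference or any other pair) and each unit class, runs paired
#' signed-rank tests on the three single-unit measures (evoked rate,
#' bias-corrected information, encoding efficiency) and applies
#' Benjamini-Hochberg FDR within that three-test family. If a pair table
#' is supplied, signal and noise correlations are tested as a two-test
#' family, pooled across unit classes, and summarized by the mean
#' difference between correlation coefficients rather than percent change.
#'
#' @param results Per-unit-by-condition table from [equalized_estimates()],
#'   with a \code{unit_class} column (add one from the session's unit
#'   table).
#' @param pairs Optional pair-correlation table from [pair_correlations()].
#' @param comparisons List of length-2 character vectors
#'   \code{c(reference, other)}; default compares every non-Still
#'   condition against Still.
#' @param q FDR level (default 0.05).
#' @param n_boot Bootstrap iterations (default 1000).
#' @return Nested list of test records, suitable for [write_results()].
#' @export
group_statistics <- function(results, pairs = NULL, comparisons = NULL,
                             q = 0.05, n_boot = 1000) {
  if (is.null(comparisons)) {
    conds <- setdiff(unique(as.character(results$condition)), "Still")
    comparisons <- lapply(conds, function(cc) c("Still", cc))
  }
  if (is.null(results$unit_class)) results$unit_class <- "all"
  measures <- c(evoked_rate = "evoked_rate", information = "mi_corrected",
                efficiency = "efficiency")
  out <- list()
  for (cmp in comparisons) {
    ra <- results[results$condition == cmp[1], ]
    rb <- results[results$condition == cmp[2], ]
    common <- intersect(ra$unit_id, rb$unit_id)
    ra <- ra[match(common, ra$unit_id), ]
    rb <- rb[match(common, rb$unit_id), ]
    label <- paste(cmp[2], "vs", cmp[1])
    for (cls in unique(ra$unit_class)) {
      sel <- ra$unit_class == cls
      recs <- lapply(measures, function(mm)
        compare_measure(ra[[mm]][sel], rb[[mm]][sel], n_boot))
      flags <- bh_fdr(vapply(recs, `[[`, numeric(1), "p"), q, length(recs))
      for (i in seq_along(recs)) recs[[i]]$significant_after_fdr <- flags[i]
      out[[label]][[cls]] <- recs
    }
    if (!is.null(pairs) && nrow(pairs)) {
      pa <- pairs[pairs$condition == cmp[1], ]
      pb <- pairs[pairs$condition == cmp[2], ]
      key <- function(p) paste(p$unit_a, p$unit_b)
      common_p <- intersect(key(pa), key(pb))
      pa <- pa[match(common_p, key(pa)), ]
      pb <- pb[match(common_p, key(pb)), ]
      precs <- list(
        signal = compare_measure(pa$r_signal, pb$r_signal, n_boot, pct = FALSE),
        noise = compare_measure(pa$r_noise, pb$r_noise, n_boot, pct = FALSE))
      flags <- bh_fdr(vapply(precs, `[[`, numeric(1), "p"), q, length(precs))
      for (i in seq_along(precs))
        precs[[i]]$significant_after_fdr <- flags[i]
      out[[label]][["correlations"]] <- precs
    }
  }
  out
}
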