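# End-to-end drivers: one call from a session to the per-unit result
# table, the pair-correlation table, and the group statistics summary.

#' Analyze one session
#'
#' Runs the full single-session pipeline: movement classification from the
#' treadmill trace, condition assignment, frequency binning, spike
#' counting in the spontaneous and evoked windows, trial-equalized
#' information estimates per unit and condition, and (optionally) the
#' signal/noise correlation decomposition per simultaneously recorded
#' pair. All randomness (subsample draws, information shuffles,
#' within-stimulus shuffles) flows from \code{seed}.
#'
#' @param session A \code{session}.
#' @param movement_threshold_cm_s Movement threshold in cm/s (default 1;
#'   per-experiment setting).
#' @param n_subsample_iter Equalizing subsample iterations (default 100).
#' @param n_shuffles Information-null shuffle iterations (default 1000).
#' @param n_signal_shuffles Within-stimulus shuffles for signal
#'   correlations (default 100).
#' @param compute_pairs Whether to compute pair correlations (default
#'   TRUE).
#' @param seed Seed for all stochastic steps (default 1).
#' @return List with \code{results} (per unit x condition; includes
#'   \code{session} and \code{unit_class} columns), \code{pairs} (per pair
#'   x condition, or an empty table), and \code{annot} (the trial
#'   annotation).
#' @export
analyze_session <- function(session, movement_threshold_cm_s = 1,
                            n_subsample_iter = 100, n_shuffles = 1000,
                            n_signal_shuffles = 100, compute_pairs = TRUE,
                            seed = 1) {
  session <- classify_session_units(session)
  annot <- annotate_trials(session, movement_threshold_cm_s)
  counts <- count_spikes(session)
  set.seed(seed)
  results <- equalized_estimates(counts, annot, n_subsample_iter, n_shuffles)
  results$session <- session$session_id
  results$unit_class <- session$units$unit_class[
    match(results$unit_id, session$units$unit_id)]
  pairs <- if (compute_pairs) {
    set.seed(seed + 1)
    p <- pair_correlations(counts, annot, n_subsample_iter, n_signal_shuffles)
    if (nrow(p)) p$session <- session$session_id
    p
  } else {
    data.frame()
  }
  list(results = results, pairs = pairs, annot = annot)
}

#' Analyze a cohort of sessions
#'
#' Applies [analyze_session()] to each session and row-binds the result
#' and pair tables. Unit ids are qualified by session in the combined
#' tables.
#'
#' @param sessions List of \code{session} objects.
#' @inheritParams analyze_session
#' @return List with combined \code{results} and \code{pairs} tables.
#' @export
analyze_cohort <- function(sessions, movement_threshold_cm_s = 1,
                           n_subsample_iter = 100, n_shuffles = 1000,
                           n_signal_shuffles = 100, compute_pairs = TRUE,
                           seed = 1) {
  res <- lapply(seq_along(sessions), function(i)
    analyze_session(sessions[[i]], movement_threshold_cm_s,
                    n_subsample_iter, n_shuffles, n_signal_shuffles,
                    compute_pairs, seed = seed + i - 1))
  results <- do.call(rbind, lapply(res, `[[`, "results"))
  results$unit_id <- paste(results$session, results$unit_id, sep = ":")
  pairs <- do.call(rbind, Filter(nrow, lapply(res, `[[`, "pairs")))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs$unit_a <- paste(pairs$session, pairs$unit_a, sep = ":")
    pairs$unit_b <- paste(pairs$session, pairs$unit_b, sep = ":")
  } else {
    pairs <- data.frame()
  }
  list(results = results, pairs = pairs)
}
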