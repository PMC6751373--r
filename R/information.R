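# Stimulus-response mutual information with shuffle bias correction,
# encoding efficiency, and the trial-equalizing subsampling wrapper.

# Integer-code a vector against its sorted unique values.
code_levels <- function(v) {
  u <- sort(unique(v))
  list(code = match(v, u), k = length(u))
}

entropy_bits <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Plug-in mutual information of a stimulus-response table
#'
#' Computes \eqn{I(X;Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}}
#' over the empirical joint distribution of stimulus labels \code{x} and
#' responses \code{y} (evoked-window spike counts), in bits. Cells with
#' \eqn{p(x,y) = 0} contribute zero. Computed as
#' \eqn{H(X) + H(Y) - H(X,Y)}, which is algebraically identical to the
#' double sum.
#'
#' @param x Vector of stimulus labels (any discrete type).
#' @param y Vector of responses, same length (raw spike counts; the
#'   response alphabet is the set of observed counts, unbinned).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  cx <- code_levels(x); cy <- code_levels(y)
  n <- length(x)
  hx <- entropy_bits(tabulate(cx$code, cx$k), n)
  hy <- entropy_bits(tabulate(cy$code, cy$k), n)
  hxy <- entropy_bits(tabulate(cx$code + cx$k * (cy$code - 1L), cx$k * cy$k), n)
  max(hx + hy - hxy, 0)
}

#' Shuffle-corrected mutual information
#'
#' Estimates the finite-sampling bias of the plug-in estimator by randomly
#' re-pairing stimuli and responses: \code{y} is permuted uniformly
#' relative to \code{x} on each of \code{n_shuffles} iterations, producing
#' a null distribution of information values. The null mean is subtracted
#' from the raw estimate. The corrected value may be negative and is not
#' clipped, so that averages over uninformative units remain unbiased.
#'
#' Also records the mean spike count per trial and the encoding efficiency
#' (corrected bits divided by mean count; \code{NA} when no spikes were
#' fired).
#'
#' @inheritParams mutual_information
#' @param n_shuffles Number of shuffle iterations (default 1000).
#' @return Object of class \code{info_estimate}: list with \code{mi_raw},
#'   \code{null_mean}, \code{mi_corrected}, \code{mean_count},
#'   \code{efficiency}, \code{n_trials}, \code{n_shuffles}.
#' @export
shuffle_corrected_mi <- function(x, y, n_shuffles = 1000) {
  stopifnot(length(x) == length(y), length(x) >= 1, n_shuffles >= 1)
  cx <- code_levels(x); cy <- code_levels(y)
  n <- length(x)
  hx <- entropy_bits(tabulate(cx$code, cx$k), n)
  hy <- entropy_bits(tabulate(cy$code, cy$k), n)
  hxy <- entropy_bits(tabulate(cx$code + cx$k * (cy$code - 1L), cx$k * cy$k), n)
  mi_raw <- max(hx + hy - hxy, 0)
  null_h <- shuffle_joint_entropy(cx$code, cy$code, cx$k, cy$k,
                                  as.integer(n_shuffles))
  null_mean <- mean(hx + hy - null_h)
  mean_count <- mean(y)
  mi_corrected <- mi_raw - null_mean
  structure(list(
    mi_raw = mi_raw, null_mean = null_mean, mi_corrected = mi_corrected,
    mean_count = mean_count,
    efficiency = if (mean_count > 0) mi_corrected / mean_count else NA_real_,
    n_trials = n, n_shuffles = n_shuffles), class = "info_estimate")
}

#' Encoding efficiency in bits per spike
#'
#' Bias-corrected mutual information divided by the mean spike count across
#' trials. Undefined (\code{NA}) when the unit fired no spikes; such units
#' are excluded pairwise from downstream efficiency comparisons.
#'
#' @param estimate An \code{info_estimate} from [shuffle_corrected_mi()].
#' @return Efficiency in bits/spike, or \code{NA}.
#' @export
encoding_efficiency <- function(estimate) {
  if (!is.finite(estimate$mean_count) || estimate$mean_count <= 0)
    return(NA_real_)
  estimate$mi_corrected / estimate$mean_count
}

#' Draw trial subsamples that equalize stimulus-by-condition cell counts
#'
#' Finds the stimulus-bin-by-condition cell with the fewest trials and, on
#' each iteration, draws that number of trials without replacement from
#' every cell. Conditions containing an empty cell are flagged unusable and
#' excluded before the minimum is taken.
#'
#' @param annot Trial annotation (from [annotate_trials()]): needs columns
#'   \code{condition} and \code{stimulus_bin}.
#' @param n_iter Number of subsample iterations.
#' @return List with \code{draws} (list of \code{n_iter} integer vectors of
#'   row indices into \code{annot}), \code{m} (the equalized per-cell
#'   count), and \code{usable_conditions}.
#' @export
equalize_trials <- function(annot, n_iter) {
  stopifnot(n_iter >= 1)
  conds <- levels(annot$condition)
  bins <- sort(unique(annot$stimulus_bin))
  cells <- split(seq_len(nrow(annot)),
                 list(annot$condition, annot$stimulus_bin), drop = FALSE)
  sizes <- vapply(cells, length, integer(1))
  cell_cond <- sub("\\..*$", "", names(cells))
  unusable <- unique(cell_cond[sizes == 0])
  usable <- setdiff(conds, unusable)
  if (!length(usable))
    stop("every condition has at least one empty stimulus cell", call. = FALSE)
  keep <- cell_cond %in% usable
  m <- min(sizes[keep])
  draws <- lapply(seq_len(n_iter), function(i) {
    unlist(lapply(cells[keep], function(idx) {
      if (length(idx) == m) idx else idx[sample.int(length(idx), m)]
    }), use.names = FALSE)
  })
  list(draws = draws, m = m, usable_conditions = usable)
}

#' Per-unit, per-condition estimates on trial-equalized subsamples
#'
#' The core single-unit pipeline. Stimulus-by-condition trial counts are
#' equalized by repeated subsampling ([equalize_trials()]); on every
#' iteration and for every unit and usable condition it computes the
#' baseline-corrected evoked rate (mean evoked-window rate minus mean
#' spontaneous-window rate), the spontaneous rate, and the
#' shuffle-corrected mutual information between stimulus bin and raw
#' evoked-window spike count, with efficiency taken as the per-iteration
#' ratio. All reported quantities are means across iterations.
#'
#' @param counts Count table from [count_spikes()].
#' @param annot Trial annotation from [annotate_trials()], rows aligned
#'   with the session's trial table.
#' @param n_iter Subsample iterations (default 100).
#' @param n_shuffles Shuffle iterations for the information null
#'   (default 1000).
#' @param window_s Analysis window duration in seconds (default 0.5).
#' @return data.frame with one row per unit x usable condition:
#'   \code{unit_id}, \code{condition}, \code{n_trials} (per iteration),
#'   \code{n_iter}, \code{evoked_rate}, \code{spont_rate}, \code{mi_raw},
#'   \code{null_mean}, \code{mi_corrected}, \code{mean_count},
#'   \code{efficiency}. Attribute \code{m}: the equalized cell count.
#' @export
equalized_estimates <- function(counts, annot, n_iter = 100,
                                n_shuffles = 1000, window_s = 0.5) {
  eq <- equalize_trials(annot, n_iter)
  units <- sort(unique(counts$unit_id))
  n_tr <- nrow(annot)
  # counts in unit x trial matrix form for fast subsetting
  ev <- matrix(0L, n_tr, length(units))
  sp <- matrix(0L, n_tr, length(units))
  uidx <- match(counts$unit_id, units)
  tidx <- match(counts$trial_id, annot$trial_id)
  ev[cbind(tidx, uidx)] <- counts$evoked_count
  sp[cbind(tidx, uidx)] <- counts$spont_count
  conds <- eq$usable_conditions

  acc <- list()
  for (cond in conds) {
    for (u in seq_along(units)) {
      acc[[paste(cond, u)]] <- numeric(7)
    }
  }
  n_per_cond <- NULL
  for (it in seq_len(n_iter)) {
    draw <- eq$draws[[it]]
    cond_of <- annot$condition[draw]
    for (cond in conds) {
      rows <- draw[cond_of == cond]
      xbin <- annot$stimulus_bin[rows]
      if (is.null(n_per_cond)) n_per_cond <- length(rows)
      for (u in seq_along(units)) {
        yev <- ev[rows, u]
        est <- shuffle_corrected_mi(xbin, yev, n_shuffles)
        er <- mean(yev) / window_s - mean(sp[rows, u]) / window_s
        srate <- mean(sp[rows, u]) / window_s
        effv <- if (is.na(est$efficiency)) 0 else est$efficiency
        effn <- as.numeric(!is.na(est$efficiency))
        a <- acc[[paste(cond, u)]]
        acc[[paste(cond, u)]] <- a + c(er, srate, est$mi_raw, est$null_mean,
                                       est$mi_corrected, effv, effn)
      }
    }
  }
  out <- do.call(rbind, lapply(conds, function(cond) {
    do.call(rbind, lapply(seq_along(units), function(u) {
      a <- acc[[paste(cond, u)]]
      eff <- if (a[7] > 0) a[6] / a[7] else NA_real_
      data.frame(unit_id = units[u], condition = cond,
                 n_trials = eq$m * length(unique(annot$stimulus_bin)),
                 n_iter = n_iter,
                 evoked_rate = a[1] / n_iter, spont_rate = a[2] / n_iter,
                 mi_raw = a[3] / n_iter, null_mean = a[4] / n_iter,
                 mi_corrected = a[5] / n_iter,
                 mean_count = NA_real_, efficiency = eff,
                 stringsAsFactors = FALSE)
    }))
  }))
  # mean evoked count per trial, averaged over iterations, per unit x cond
  mc <- vapply(seq_len(nrow(out)), function(i) {
    u <- match(out$unit_id[i], units)
    mean(vapply(eq$draws, function(draw) {
      rows <- draw[annot$condition[draw] == out$condition[i]]
      mean(ev[rows, u])
    }, numeric(1)))
  }, numeric(1))
  out$mean_count <- mc
  attr(out, "m") <- eq$m
  attr(out, "usable_conditions") <- conds
  rownames(out) <- NULL
  out
}
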