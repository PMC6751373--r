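# Independent oracles and small fixture builders, kept deliberately naive.

# Mutual information by direct double summation over the joint histogram.
mi_oracle <- function(x, y) {
  p <- table(x, y) / length(x)
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (p[i, j] > 0)
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(total)
}

# Exact two-tailed signed-rank p-value by enumerating all 2^n sign
# patterns of the nonzero differences (midranks for ties).
wsr_exact_p <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Brute-force Benjamini-Hochberg step-up flags via the adjusted p-value
# route (independent of the sorted-threshold route in the package).
bh_oracle <- function(p, q, m) {
  stats::p.adjust(p, method = "BH", n = m) <= q
}

# A hand-built two-trial, one-unit session around constant velocity.
tiny_session <- function(velocity_value = 0) {
  freqs <- default_stimulus_set()
  new_session(
    "tiny",
    spikes = data.frame(unit_id = c(1L, 1L, 1L),
                        spike_time_s = c(2.1, 2.35, 5.9)),
    trials = data.frame(trial_id = 1:2, onset_s = c(2, 5.5),
                        frequency_hz = freqs[c(1, 20)],
                        led_on = c(FALSE, TRUE)),
    velocity = data.frame(time_s = seq(0, 8, by = 0.1),
                          velocity_cm_s = velocity_value))
}

# Counts table + annotation with controllable cell sizes, for the
# equalization machinery. cell_sizes: matrix [condition x bin].
fake_annot <- function(cell_sizes,
                       conditions = condition_levels()) {
  rows <- list()
  tid <- 0L
  for (ci in seq_len(nrow(cell_sizes))) {
    for (bi in seq_len(ncol(cell_sizes))) {
      k <- cell_sizes[ci, bi]
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid + seq_len(k),
        condition = conditions[ci], stimulus_bin = bi)
      tid <- tid + k
    }
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = conditions)
  out
}

poisson_counts_for <- function(annot, unit_id = 1L, rate_per_bin = NULL,
                               window_s = 0.5) {
  if (is.null(rate_per_bin)) rate_per_bin <- rep(4, max(annot$stimulus_bin))
  lam <- rate_per_bin[annot$stimulus_bin] * window_s
  data.frame(unit_id = unit_id, trial_id = annot$trial_id,
             evoked_count = rpois(nrow(annot), lam),
             spont_count = rpois(nrow(annot), 2 * window_s))
}
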