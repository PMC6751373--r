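test_that("plug-in mutual information matches hand-checkable cases", {
  # degenerate response: no information
  expect_equal(mutual_information(c("A", "A", "B", "B"), c(3, 3, 3, 3)), 0)
  # identity mapping over 4 equiprobable stimuli: log2(4) bits
  expect_equal(mutual_information(rep(1:4, each = 5), rep(c(0, 2, 5, 9), each = 5)), 2)
  # 2x2 joint histograms worked by hand
  expect_equal(mutual_information(c("A", "A", "B", "B"), c(0, 1, 0, 1)), 0)
  expect_equal(mutual_information(c("A", "A", "B", "B"), c(0, 0, 1, 1)), 1)
})

test_that("plug-in MI equals direct joint-histogram summation on random tables", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- rpois(n, 2)
    expect_equal(mutual_information(x, y), mi_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("MI is invariant under injective relabeling and bounded by marginals", {
  set.seed(7)
  for (i in 1:25) {
    n <- 50
    x <- sample(1:5, n, replace = TRUE)
    y <- rpois(n, 3)
    mi <- mutual_information(x, y)
    # injective relabelings of either alphabet
    expect_equal(mutual_information(6 - x, y), mi, tolerance = 1e-12)
    expect_equal(mutual_information(x, 2 * y + 7), mi, tolerance = 1e-12)
    hx <- mi_oracle(x, x); hy <- mi_oracle(y, y)  # self-MI = entropy
    expect_gte(mi, 0)
    expect_lte(mi, min(hx, hy) + 1e-12)
    expect_lte(mi, log2(5) + 1e-12)
  }
})

test_that("the shuffle null mean is non-negative and corrected MI <= raw", {
  set.seed(11)
  x <- sample(1:5, 60, replace = TRUE)
  y <- rpois(60, 2)
  est <- shuffle_corrected_mi(x, y, n_shuffles = 200)
  expect_gte(est$null_mean, 0)     # plug-in MI of shuffled data is >= 0
  expect_lte(est$mi_corrected, est$mi_raw)
  expect_equal(est$mi_corrected, est$mi_raw - est$null_mean)
  expect_equal(est$n_trials, 60)
})

test_that("near-deterministic tuning recovers the 5-bin information ceiling", {
  set.seed(13)
  x <- rep(1:5, each = 50)
  y <- x * 3  # distinct deterministic count per bin
  est <- shuffle_corrected_mi(x, y, n_shuffles = 1000)
  expect_equal(est$mi_raw, log2(5), tolerance = 1e-12)
  expect_lt(abs(est$mi_corrected - log2(5)), 0.05)
})

test_that("stimulus-independent tables are corrected to zero on average", {
  set.seed(17)
  vals <- replicate(120, {
    x <- rep(1:5, each = 10)
    y <- rpois(50, 2)
    shuffle_corrected_mi(x, y, n_shuffles = 100)$mi_corrected
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("efficiency is corrected MI per spike and halves when counts double", {
  est <- structure(list(mi_corrected = 1, mean_count = 2), class = "info_estimate")
  expect_equal(encoding_efficiency(est), 0.5)
  est$mi_corrected <- 0
  expect_equal(encoding_efficiency(est), 0)
  est$mean_count <- 0
  expect_true(is.na(encoding_efficiency(est)))

  # doubling every count preserves MI (injective map) and halves efficiency
  set.seed(19)
  x <- rep(1:5, each = 30)
  y <- rpois(150, x)  # tuned counts
  set.seed(23); e1 <- shuffle_corrected_mi(x, y, 500)
  set.seed(23); e2 <- shuffle_corrected_mi(x, 2 * y, 500)
  expect_equal(e2$mi_raw, e1$mi_raw, tolerance = 1e-12)
  expect_equal(encoding_efficiency(e2), encoding_efficiency(e1) / 2,
               tolerance = 1e-12)
})

test_that("corrected MI increases with tuning-curve contrast", {
  set.seed(29)
  contrasts <- seq(0, 3, length.out = 20)
  mi <- vapply(contrasts, function(cc) {
    x <- rep(1:5, each = 100)
    y <- rpois(500, 2 + cc * (x - 1))
    shuffle_corrected_mi(x, y, n_shuffles = 100)$mi_corrected
  }, numeric(1))
  expect_gt(cor(contrasts, mi, method = "spearman"), 0.9)
})

test_that("subsampling equalizes every stimulus-by-condition cell", {
  sizes <- matrix(10, nrow = 4, ncol = 5)
  sizes[2, 4] <- 3  # the global minimum cell
  annot <- fake_annot(sizes)
  set.seed(3)
  eq <- equalize_trials(annot, n_iter = 7)
  expect_equal(eq$m, 3)
  for (draw in eq$draws) {
    tab <- table(annot$condition[draw], annot$stimulus_bin[draw])
    expect_true(all(tab == 3))
  }
})

test_that("conditions with an empty cell are flagged unusable", {
  sizes <- matrix(8, nrow = 4, ncol = 5)
  sizes[3, 2] <- 0
  annot <- fake_annot(sizes)
  eq <- equalize_trials(annot, n_iter = 2)
  expect_false("Still+VIP" %in% eq$usable_conditions)
  expect_setequal(eq$usable_conditions, c("Still", "Mvmt", "Mvmt+VIP"))
  expect_equal(eq$m, 8)
})

test_that("equalization is a no-op when cells are already balanced", {
  sizes <- matrix(6, nrow = 4, ncol = 5)
  annot <- fake_annot(sizes)
  set.seed(41)
  counts <- poisson_counts_for(annot, rate_per_bin = c(2, 4, 8, 12, 16))
  set.seed(43)
  res <- equalized_estimates(counts, annot, n_iter = 3, n_shuffles = 50)
  # every iteration uses all trials, so rate and raw-MI means equal the
  # direct single-pass estimates
  for (cond in condition_levels()) {
    rows <- annot$condition == cond
    y <- counts$evoked_count[rows]
    sp <- counts$spont_count[rows]
    direct_rate <- mean(y) / 0.5 - mean(sp) / 0.5
    direct_mi <- mutual_information(annot$stimulus_bin[rows], y)
    got <- res[res$condition == cond, ]
    expect_equal(got$evoked_rate, direct_rate, tolerance = 1e-12)
    expect_equal(got$mi_raw, direct_mi, tolerance = 1e-12)
    expect_equal(got$n_trials, 30)
  }
})

test_that("equalized estimates are means across iterations", {
  sizes <- matrix(c(10, 10, 10, 3), nrow = 4, ncol = 5)
  annot <- fake_annot(sizes)
  set.seed(47)
  counts <- poisson_counts_for(annot)
  res <- equalized_estimates(counts, annot, n_iter = 4, n_shuffles = 20)
  expect_equal(unique(res$n_iter), 4)
  expect_equal(unique(res$n_trials), 5 * 3)
  expect_true(all(res$mi_corrected <= res$mi_raw + 1e-12))
})
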