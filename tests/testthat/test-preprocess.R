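test_that("movement classification thresholds the stimulus-window mean speed", {
  expect_false(any(classify_movement(tiny_session(0), 1)))
  # paper-scale speeds: classified-Mvmt trials average 7.83 cm/s,
  # classified-Still trials 0.18 cm/s, against the ~1 cm/s tracker floor
  expect_true(all(classify_movement(tiny_session(7.83), 1)))
  expect_false(any(classify_movement(tiny_session(0.18), 1)))

  # direction is rectified: backward rolling counts as movement
  expect_true(all(classify_movement(tiny_session(-7.83), 1)))

  # uncovered stimulus window names the offending trial
  s <- tiny_session(0)
  s$velocity <- data.frame(time_s = c(0, 3), velocity_cm_s = 0)
  expect_error(classify_movement(s, 1), "trial")
})

test_that("the velocity window mean is time-weighted under irregular sampling", {
  s <- tiny_session(0)
  # step from 0 to 10 cm/s at t = 2.4, sampled irregularly; trial 1 window
  # is [2, 2.5) so the true mean is (0.4*0 + 0.1*10)/0.5 = 2
  s$velocity <- data.frame(time_s = c(0, 1.7, 2.4, 6.5),
                           velocity_cm_s = c(0, 0, 10, 10))
  expect_true(classify_movement(s, 1)[1])
  expect_false(classify_movement(s, 2.5)[1])
})

test_that("condition assignment covers all four flag combinations", {
  mv <- c(FALSE, TRUE, FALSE, TRUE)
  led <- c(FALSE, FALSE, TRUE, TRUE)
  cond <- assign_conditions(mv, led)
  expect_equal(as.character(cond),
               c("Still", "Mvmt", "Still+VIP", "Mvmt+VIP"))
  expect_equal(nlevels(cond), 4)
  # condition counts partition the trial count
  expect_equal(sum(table(cond)), 4)
})

test_that("frequency binning groups four adjacent frequencies per bin", {
  freqs <- default_stimulus_set()
  expect_equal(length(freqs), 20)
  expect_equal(freqs[1], 4000)
  expect_equal(freqs[20], 64000, tolerance = 1e-12)
  bins <- bin_frequencies(freqs)
  expect_equal(bins, rep(1:5, each = 4))
  expect_equal(bin_frequencies(4000), 1L)
  expect_equal(bin_frequencies(64000), 5L)
  expect_equal(bin_frequencies(freqs[5]), 2L)
  expect_true(all(table(bins) == 4))
  expect_error(bin_frequencies(12345), "not in the stimulus set")
})

test_that("spike counts use half-open windows and the stated offsets", {
  freqs <- default_stimulus_set()
  mk <- function(spike_times) new_session(
    "w",
    spikes = data.frame(unit_id = rep(1L, length(spike_times)),
                        spike_time_s = sort(spike_times)),
    trials = data.frame(trial_id = 1L, onset_s = 2, frequency_hz = freqs[1],
                        led_on = FALSE),
    velocity = data.frame(time_s = c(0, 5), velocity_cm_s = 0))

  # spikes at onset+0.1, +0.2, +0.6: the third lies outside [onset, onset+0.5)
  cm <- count_spikes(mk(2 + c(0.1, 0.2, 0.6)))
  expect_equal(cm$evoked_count, 2L)
  # right edge excluded, left edge included
  cm <- count_spikes(mk(c(2, 2.5)))
  expect_equal(cm$evoked_count, 1L)
  # spontaneous window is [onset-0.7, onset-0.2)
  cm <- count_spikes(mk(2 + c(-0.7, -0.45, -0.2)))
  expect_equal(cm$spont_count, 2L)
  expect_equal(cm$evoked_count, 0L)
})

test_that("a unit with no spikes yields zero counts and zero evoked rate", {
  s <- tiny_session(0)
  s$units <- data.frame(unit_id = 1:2, unit_class = "unknown")
  cm <- count_spikes(s)
  u2 <- cm[cm$unit_id == 2, ]
  expect_true(all(u2$evoked_count == 0))
  expect_true(all(u2$spont_count == 0))
  er <- mean(u2$evoked_count) / 0.5 - mean(u2$spont_count) / 0.5
  expect_equal(er, 0)
})

test_that("a homogeneous Poisson unit has near-zero mean evoked rate", {
  set.seed(31)
  n_tr <- 400
  onsets <- 3 + (seq_len(n_tr) - 1) * 2.5
  lambda <- 8
  t_end <- max(onsets) + 2
  nsp <- rpois(1, lambda * t_end)
  s <- new_session(
    "poisson",
    spikes = data.frame(unit_id = 1L, spike_time_s = sort(runif(nsp, 0, t_end))),
    trials = data.frame(trial_id = seq_len(n_tr), onset_s = onsets,
                        frequency_hz = default_stimulus_set()[1],
                        led_on = FALSE),
    velocity = data.frame(time_s = c(0, t_end), velocity_cm_s = 0))
  cm <- count_spikes(s)
  er <- mean(cm$evoked_count) / 0.5 - mean(cm$spont_count) / 0.5
  # sd of the difference of two window-rate means ~ sqrt(2*lambda/0.5/n)
  expect_lt(abs(er), 4 * sqrt(2 * lambda / 0.5 / n_tr))
})

test_that("counts are invariant under a common time translation", {
  cfg <- generator_config(n_units = 3, n_repeats = 2, seed = 5)
  s <- generate_session(cfg)$session
  cm1 <- count_spikes(s)
  shift <- 11.3
  s2 <- s
  s2$spikes$spike_time_s <- s$spikes$spike_time_s + shift
  s2$trials$onset_s <- s$trials$onset_s + shift
  s2$velocity$time_s <- s$velocity$time_s + shift
  cm2 <- count_spikes(s2)
  expect_identical(cm1$evoked_count, cm2$evoked_count)
  expect_identical(cm1$spont_count, cm2$spont_count)
})

test_that("waveform classification splits NS/BS at 600 us trough-to-peak", {
  sr <- 30000  # 1 sample = 33.3 us
  mk_wf <- function(t2p_samples) {
    i <- 1:60
    -exp(-((i - 20) / 2)^2) + 0.5 * exp(-((i - 20 - t2p_samples) / 3)^2)
  }
  ns <- classify_unit(mk_wf(12), sr)   # 400 us
  expect_equal(ns$unit_class, "NS")
  expect_equal(ns$trough_to_peak_us, 400)
  bs <- classify_unit(mk_wf(18), sr)   # exactly 600 us is BS
  expect_equal(bs$unit_class, "BS")
  expect_equal(bs$trough_to_peak_us, 600)

  # symmetric biphasic template, equal amplitudes, 750 us separation
  sr2 <- 40000  # 25 us per sample puts 750 us on the grid
  i <- 1:100
  sym <- -exp(-((i - 30) / 4)^2) + exp(-((i - 60) / 4)^2)
  res <- classify_unit(sym, sr2)
  expect_equal(res$unit_class, "BS")
  expect_equal(res$trough_to_peak_us, 750)
  expect_equal(res$peak_trough_ratio, 1.0, tolerance = 1e-6)

  # trough at the last sample: nothing to measure
  expect_error(classify_unit(c(0.2, 0, -1), sr), "last sample")
})

test_that("generated units are classified back to their assigned class", {
  cfg <- generator_config(n_units = 8, n_repeats = 2, seed = 9)
  gs <- generate_session(cfg)
  s <- gs$session
  s$units$unit_class <- "unknown"
  s <- classify_session_units(s)
  expect_equal(s$units$unit_class, gs$ground_truth$units$unit_class)
})
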