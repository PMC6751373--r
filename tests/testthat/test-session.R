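test_that("a minimal well-formed set of tables reads into a session", {
  dir <- withr::local_tempdir()
  writeLines(c("unit_id\tspike_time_s", "1\t0.5", "1\t1.2", "1\t2.0"),
             file.path(dir, "spikes.tsv"))
  writeLines(c("trial_id\tonset_s\tfrequency_hz\tled_on",
               "1\t1.0\t4000\t0", "2\t3.0\t64000\t1"),
             file.path(dir, "trials.tsv"))
  writeLines(c("time_s\tvelocity_cm_s", "0\t0", "5\t0"),
             file.path(dir, "velocity.tsv"))
  s <- read_session(file.path(dir, "spikes.tsv"), file.path(dir, "trials.tsv"),
                    file.path(dir, "velocity.tsv"))
  expect_s3_class(s, "session")
  expect_equal(nrow(s$trials), 2)
  expect_equal(nrow(s$units), 1)
  expect_equal(s$spikes$spike_time_s, c(0.5, 1.2, 2.0))
})

test_that("invariant violations are rejected, not silently dropped", {
  dir <- withr::local_tempdir()
  writeLines(c("unit_id\tspike_time_s", "1\t0.5"), file.path(dir, "spikes.tsv"))
  writeLines(c("trial_id\tonset_s\tfrequency_hz\tled_on",
               "1\t5.0\t4000\t0", "2\t3.0\t64000\t1"),
             file.path(dir, "trials.tsv"))
  writeLines(c("time_s\tvelocity_cm_s", "0\t0", "9\t0"),
             file.path(dir, "velocity.tsv"))
  expect_error(
    read_session(file.path(dir, "spikes.tsv"), file.path(dir, "trials.tsv"),
                 file.path(dir, "velocity.tsv")),
    "strictly increasing")

  # missing column is named in the error
  writeLines(c("trial_id\tonset_s\tled_on", "1\t1.0\t0"),
             file.path(dir, "trials_bad.tsv"))
  expect_error(
    read_session(file.path(dir, "spikes.tsv"),
                 file.path(dir, "trials_bad.tsv"),
                 file.path(dir, "velocity.tsv")),
    "frequency_hz")

  expect_error(new_session("x",
    data.frame(unit_id = 1L, spike_time_s = -0.1),
    data.frame(trial_id = 1L, onset_s = 1, frequency_hz = 4000,
               led_on = FALSE),
    data.frame(time_s = 0:2, velocity_cm_s = 0)),
    "non-negative")

  expect_error(new_session("x",
    data.frame(unit_id = 1L, spike_time_s = c(1, 0.5)),
    data.frame(trial_id = 1L, onset_s = 1, frequency_hz = 4000,
               led_on = FALSE),
    data.frame(time_s = 0:2, velocity_cm_s = 0)),
    "sorted")
})

test_that("a generated session survives a write/read round trip", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_units = 3, n_repeats = 2, seed = 42)
  s <- generate_session(cfg)$session
  paths <- write_session(s, dir)
  s2 <- read_session(paths["spikes"], paths["trials"], paths["velocity"],
                     paths["units"], session_id = s$session_id)
  tol <- 1e-5  # 6 significant digits
  expect_equal(s2$spikes$unit_id, s$spikes$unit_id)
  expect_equal(s2$spikes$spike_time_s, s$spikes$spike_time_s,
               tolerance = tol)
  expect_equal(s2$trials$frequency_hz, s$trials$frequency_hz,
               tolerance = tol)
  expect_equal(s2$trials$led_on, s$trials$led_on)
  expect_equal(s2$velocity$velocity_cm_s, s$velocity$velocity_cm_s,
               tolerance = tol)
  expect_equal(s2$units$unit_class, s$units$unit_class)
  expect_equal(s2$waveforms[["1"]], s$waveforms[["1"]], tolerance = tol)
  # reader preserves within-unit spike order exactly
  for (u in s2$units$unit_id) {
    expect_false(is.unsorted(
      s2$spikes$spike_time_s[s2$spikes$unit_id == u]))
  }
})

test_that("result tables round-trip at 6 significant digits", {
  dir <- withr::local_tempdir()
  results <- data.frame(unit_id = 1L, condition = "Still", n_trials = 10L,
                        n_iter = 2L, evoked_rate = 1.2345678,
                        spont_rate = 0.99999999, mi_raw = 0.123456789,
                        null_mean = 0.01, mi_corrected = 0.113456789,
                        mean_count = 2, efficiency = 0.0567283945)
  pairs <- data.frame(unit_a = integer(0), unit_b = integer(0),
                      condition = character(0), r_total = numeric(0),
                      r_signal = numeric(0), r_noise = numeric(0),
                      n_trials = integer(0))
  stats <- list(example = list(p = 0.5))
  paths <- write_results(results, pairs, stats, dir)
  back <- read.table(paths["results"], header = TRUE, sep = "\t")
  expect_equal(nrow(back), 1)
  expect_equal(back$evoked_rate, results$evoked_rate, tolerance = 1e-5)
  expect_equal(back$efficiency, results$efficiency, tolerance = 1e-5)
  # empty pair list: header only
  plines <- readLines(paths["pairs"])
  expect_length(plines, 1)
  expect_match(plines, "^unit_a\t")
  expect_true(jsonlite::validate(paste(readLines(paths["stats"]),
                                       collapse = "\n")))
  expect_error(write_results(results[0, ], pairs, stats, dir), "empty")
})
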