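# Synthetic session generator. Emulates the structure of the recordings
# the pipeline analyzes -- 20 tone-cloud frequencies x 50 repeats x LED
# on/off in pseudorandom order, spontaneous movement on a minority of
# trials, log-Gaussian frequency tuning, condition-dependent rate
# modulation, and a trial-level multiplicative noise latent shared across
# simultaneously recorded units -- and records the ground truth needed for
# parameter-recovery tests.

#' Gaussian frequency tuning on the log2 axis
#'
#' Rate contribution of a stimulus at \code{frequency_hz} for a unit tuned
#' to \code{center_hz}: \code{gain * exp(-d^2 / (2 * bandwidth^2))} with
#' \code{d} the distance in octaves. Peaks at \code{gain} on center and is
#' symmetric in octave distance.
#'
#' @param frequency_hz Stimulus frequency (Hz, > 0).
#' @param center_hz Preferred frequency (Hz).
#' @param bandwidth_oct Tuning bandwidth in octaves.
#' @param gain Peak evoked-rate contribution (spikes/s).
#' @return Rate contribution in spikes/s.
#' @export
tuning <- function(frequency_hz, center_hz, bandwidth_oct, gain) {
  d <- log2(frequency_hz / center_hz)
  gain * exp(-d^2 / (2 * bandwidth_oct^2))
}

#' Generator configuration
#'
#' Defaults reproduce the study conditions the pipeline expects: 20
#' frequencies x 50 repeats x LED on/off (2000 trials), movement on ~19\%
#' of trials with mean treadmill speeds of 7.83 (movement) and 0.18
#' (still) cm/s, movement multiplying baseline rates by 1.38 and evoked
#' tuning by 0.5, VIP activation multiplying both by 1.5 during the LED,
#' and a shared multiplicative noise latent (sd 0.15) that induces noise
#' correlations. Rates are floored at zero after modulation.
#'
#' @param n_units Number of simultaneously recorded units.
#' @param fraction_ns Fraction of narrow-spiking units (default 0.26,
#'   i.e. about a quarter of the population).
#' @param n_frequencies Number of nominal tone-cloud frequencies.
#' @param n_repeats Repeats per frequency per LED state.
#' @param p_movement Per-trial movement probability.
#' @param stimulus_duration_s Tone-cloud duration (s).
#' @param iti_s Inter-trial interval (s).
#' @param mvmt_baseline_gain,mvmt_evoked_gain Multiplicative movement
#'   modulation of baseline and of the tuned evoked component.
#' @param vip_baseline_gain,vip_evoked_gain Multiplicative modulation
#'   applied while the LED is on.
#' @param shared_noise_sd SD of the zero-mean trial latent multiplying the
#'   evoked-window rate of every unit.
#' @param mvmt_speed_cm_s,still_speed_cm_s Treadmill speeds emitted on
#'   movement and still trials.
#' @param baseline_rate_ns,baseline_rate_bs Median baseline rates
#'   (spikes/s) per class; individual units jitter log-normally around
#'   them.
#' @param evoked_gain_range_ns,evoked_gain_range_bs Uniform ranges for the
#'   peak tuned gain per class (spikes/s).
#' @param bandwidth_range_oct Uniform range for tuning bandwidth (octaves).
#' @param seed Master seed.
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(n_units = 12, fraction_ns = 0.26,
                             n_frequencies = 20, n_repeats = 50,
                             p_movement = 0.19,
                             stimulus_duration_s = 0.5, iti_s = 2,
                             mvmt_baseline_gain = 1.38,
                             mvmt_evoked_gain = 0.5,
                             vip_baseline_gain = 1.5,
                             vip_evoked_gain = 1.5,
                             shared_noise_sd = 0.15,
                             mvmt_speed_cm_s = 7.83,
                             still_speed_cm_s = 0.18,
                             baseline_rate_ns = 12, baseline_rate_bs = 4,
                             evoked_gain_range_ns = c(10, 30),
                             evoked_gain_range_bs = c(5, 15),
                             bandwidth_range_oct = c(0.5, 1.5),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$p_movement >= 0, cfg$p_movement <= 1,
            cfg$fraction_ns >= 0, cfg$fraction_ns <= 1,
            cfg$shared_noise_sd >= 0)
  structure(cfg, class = "generator_config")
}

make_waveform <- function(unit_class, sample_rate_hz = 30000, n = 48,
                          trough_idx = 16) {
  t2p_samples <- if (unit_class == "NS") 12L else 23L  # 400 vs ~767 us
  ratio <- if (unit_class == "NS") 0.45 else 0.55
  i <- seq_len(n)
  w <- -exp(-((i - trough_idx) / 2.2)^2) +
    ratio * exp(-((i - trough_idx - t2p_samples) / 4)^2)
  # keep the post-trough maximum exactly at the intended peak sample
  w
}

#' Generate a synthetic recording session
#'
#' Builds the trial schedule (all frequency x LED combinations repeated
#' and shuffled, constant inter-onset spacing), draws per-trial movement
#' flags and the shared noise latent, simulates every unit as a
#' piecewise-constant-rate Poisson process, synthesizes a smoothed
#' step-function treadmill trace, and attaches class-consistent waveform
#' templates.
#'
#' Rate model for unit u on trial t (all rates floored at 0):
#' \itemize{
#'   \item background before LED onset: \code{baseline * mvmt_baseline_gain^[moving]}
#'   \item background during LED (from 200 ms before the tone cloud):
#'     additionally \code{* vip_baseline_gain} on LED trials
#'   \item evoked window: \code{(background + tuning(freq) *
#'     mvmt_evoked_gain^[moving] * vip_evoked_gain^[LED]) * (1 + nu_t)}
#'     with \code{nu_t} the shared latent.
#' }
#' The spontaneous analysis window (700-200 ms before onset) precedes LED
#' onset, so VIP gains never touch it; movement gains do.
#'
#' @param config A [generator_config()].
#' @param seed Seed overriding \code{config$seed}.
#' @param session_id Session identifier.
#' @return List with \code{session} (a \code{session}) and
#'   \code{ground_truth} (unit parameters, condition gains, per-trial
#'   movement flags and latents).
#' @export
generate_session <- function(config = generator_config(), seed = config$seed,
                             session_id = "synthetic") {
  set.seed(seed)
  cfg <- config
  freqs <- 2^seq(log2(4000), log2(64000), length.out = cfg$n_frequencies)
  sched <- expand.grid(frequency_hz = freqs, led_on = c(FALSE, TRUE),
                       rep = seq_len(cfg$n_repeats))
  sched <- sched[sample.int(nrow(sched)), c("frequency_hz", "led_on")]
  n_tr <- nrow(sched)
  spacing <- cfg$stimulus_duration_s + cfg$iti_s
  trials <- data.frame(trial_id = seq_len(n_tr),
                       onset_s = 3 + (seq_len(n_tr) - 1) * spacing,
                       frequency_hz = sched$frequency_hz,
                       led_on = sched$led_on)
  movement <- stats::runif(n_tr) < cfg$p_movement
  nu <- stats::rnorm(n_tr, 0, cfg$shared_noise_sd)

  n_ns <- round(cfg$n_units * cfg$fraction_ns)
  cls <- c(rep("NS", n_ns), rep("BS", cfg$n_units - n_ns))
  g_rng <- function(k) if (cls[k] == "NS") cfg$evoked_gain_range_ns
                       else cfg$evoked_gain_range_bs
  units <- data.frame(
    unit_id = seq_len(cfg$n_units),
    unit_class = cls,
    center_hz = 2^stats::runif(cfg$n_units, log2(4000), log2(64000)),
    bandwidth_oct = stats::runif(cfg$n_units, cfg$bandwidth_range_oct[1],
                                 cfg$bandwidth_range_oct[2]),
    baseline_rate = stats::rlnorm(cfg$n_units,
                                  log(ifelse(cls == "NS", cfg$baseline_rate_ns,
                                             cfg$baseline_rate_bs)), 0.4),
    evoked_gain = vapply(seq_len(cfg$n_units),
                         function(k) stats::runif(1, g_rng(k)[1], g_rng(k)[2]),
                         numeric(1)),
    stringsAsFactors = FALSE)

  g_mv_b <- ifelse(movement, cfg$mvmt_baseline_gain, 1)
  g_mv_e <- ifelse(movement, cfg$mvmt_evoked_gain, 1)
  g_led_b <- ifelse(trials$led_on, cfg$vip_baseline_gain, 1)
  g_led_e <- ifelse(trials$led_on, cfg$vip_evoked_gain, 1)
  dur <- cfg$stimulus_duration_s

  spikes <- lapply(seq_len(cfg$n_units), function(k) {
    bg_pre <- pmax(units$baseline_rate[k] * g_mv_b, 0)
    bg_led <- pmax(bg_pre * g_led_b, 0)
    tun <- tuning(trials$frequency_hz, units$center_hz[k],
                  units$bandwidth_oct[k], units$evoked_gain[k])
    r_ev <- pmax((bg_led + tun * g_mv_e * g_led_e) * (1 + nu), 0)
    # piecewise-constant segments tiling [onset-1.5, onset+1.0)
    seg_start <- c(trials$onset_s - 1.5, trials$onset_s - 0.2,
                   trials$onset_s, trials$onset_s + dur)
    seg_dur <- rep(c(1.3, 0.2, dur, 1.0 - dur), each = n_tr)
    seg_rate <- c(bg_pre, bg_led, r_ev, bg_led)
    counts <- stats::rpois(length(seg_rate), seg_rate * seg_dur)
    tot <- sum(counts)
    if (tot == 0) return(numeric(0))
    t0 <- rep(seg_start, counts)
    d0 <- rep(seg_dur, counts)
    sort(t0 + stats::runif(tot) * d0)
  })
  spike_df <- data.frame(
    unit_id = rep(seq_len(cfg$n_units), vapply(spikes, length, integer(1))),
    spike_time_s = unlist(spikes))

  # treadmill trace: smoothed step function
  dt <- 0.02
  t_end <- max(trials$onset_s) + spacing
  tg <- seq(0, t_end, by = dt)
  v <- pmax(cfg$still_speed_cm_s + stats::rnorm(length(tg), 0, 0.05), 0)
  for (i in which(movement)) {
    on <- trials$onset_s[i]
    idx <- which(tg >= on - 0.5 & tg < on + 1.0)
    v[idx] <- pmax(cfg$mvmt_speed_cm_s + stats::rnorm(length(idx), 0, 1.0), 0)
  }
  vs <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  v <- ifelse(is.na(vs), v, as.numeric(vs))
  velocity <- data.frame(time_s = tg, velocity_cm_s = v)

  waveforms <- lapply(cls, make_waveform)
  names(waveforms) <- as.character(units$unit_id)

  session <- new_session(session_id, spike_df, trials, velocity,
                         units[, c("unit_id", "unit_class")], waveforms,
                         stimulus_duration_s = dur)
  truth <- list(
    session_id = session_id, seed = seed,
    condition_gains = list(mvmt_baseline_gain = cfg$mvmt_baseline_gain,
                           mvmt_evoked_gain = cfg$mvmt_evoked_gain,
                           vip_baseline_gain = cfg$vip_baseline_gain,
                           vip_evoked_gain = cfg$vip_evoked_gain),
    shared_noise_sd = cfg$shared_noise_sd,
    p_movement = cfg$p_movement,
    units = units,
    trials = data.frame(trial_id = trials$trial_id, movement = movement,
                        shared_noise = nu))
  list(session = session, ground_truth = truth)
}

#' Generate a cohort of independent sessions
#'
#' Repeatedly calls [generate_session()] with derived seeds
#' \code{seed, seed + 1, ...}, mimicking multiple penetrations.
#'
#' @param config A [generator_config()].
#' @param n_sessions Number of sessions.
#' @param seed Base seed (default \code{config$seed}).
#' @return List of \code{list(session, ground_truth)} elements.
#' @export
generate_cohort <- function(config = generator_config(), n_sessions = 3,
                            seed = config$seed) {
  lapply(seq_len(n_sessions), function(i)
    generate_session(config, seed = seed + i - 1,
                     session_id = sprintf("synthetic-%02d", i)))
}

#' Write generator ground truth as JSON
#'
#' @param ground_truth Ground-truth element from [generate_session()].
#' @param path Output file (conventionally \code{ground_truth.json}).
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  json <- jsonlite::toJSON(ground_truth, auto_unbox = TRUE, digits = 10,
                           dataframe = "columns", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
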