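# Trial annotation: movement classification from the treadmill trace,
# condition assignment, frequency binning, spike counting in the analysis
# windows, and waveform-based unit classification.

# Time-weighted mean of |velocity| over [a, b), treating the trace as
# piecewise-constant between samples (last observation carried forward).
window_mean_speed <- function(time_s, v, a, b) {
  n <- length(time_s)
  i0 <- findInterval(a, time_s)           # sample at or before a
  i1 <- findInterval(b, time_s, left.open = TRUE)  # last sample < b
  idx <- i0:i1
  t0 <- pmax(time_s[idx], a)
  t1 <- c(time_s[idx[-1]], b)
  sum(abs(v[idx]) * (t1 - t0)) / (b - a)
}

#' Classify trials as movement or still
#'
#' A trial counts as movement when the time-weighted mean treadmill speed
#' over the stimulus window \code{[onset, onset + 0.5)} exceeds a threshold
#' set by the noise floor of the optical tracker (about 1 cm/s). The
#' threshold is a per-experiment setting, so it can be overridden per
#' session.
#'
#' @param session A \code{session}.
#' @param threshold_cm_s Movement threshold in cm/s (default 1).
#' @return Logical vector, one element per trial (TRUE = movement).
#' @export
classify_movement <- function(session, threshold_cm_s = 1) {
  stopifnot(threshold_cm_s > 0)
  tr <- session$trials
  vel <- session$velocity
  dur <- session$stimulus_duration_s
  lo <- min(vel$time_s); hi <- max(vel$time_s)
  bad <- tr$onset_s < lo | (tr$onset_s + dur) > hi
  if (any(bad))
    stop(sprintf("velocity trace does not cover the stimulus window of trial(s): %s",
                 paste(tr$trial_id[bad], collapse = ", ")), call. = FALSE)
  vapply(seq_len(nrow(tr)), function(i) {
    window_mean_speed(vel$time_s, vel$velocity_cm_s,
                      tr$onset_s[i], tr$onset_s[i] + dur) > threshold_cm_s
  }, logical(1))
}

condition_levels <- function() c("Still", "Mvmt", "Still+VIP", "Mvmt+VIP")

#' Assign behavioral/optogenetic condition labels
#'
#' Maps the two per-trial flags onto the four conditions:
#' (still, LED off) = \code{Still}; (moving, LED off) = \code{Mvmt};
#' (still, LED on) = \code{Still+VIP}; (moving, LED on) = \code{Mvmt+VIP}.
#'
#' @param movement Logical vector of movement flags.
#' @param led_on Logical vector of optogenetic flags, same length.
#' @return Factor with levels \code{Still}, \code{Mvmt}, \code{Still+VIP},
#'   \code{Mvmt+VIP}.
#' @export
assign_conditions <- function(movement, led_on) {
  stopifnot(length(movement) == length(led_on))
  lab <- ifelse(led_on,
                ifelse(movement, "Mvmt+VIP", "Still+VIP"),
                ifelse(movement, "Mvmt", "Still"))
  factor(lab, levels = condition_levels())
}

#' Collapse nominal frequencies into stimulus bins
#'
#' The 20 nominal tone-cloud frequencies are collapsed into groups of four
#' adjacent frequencies, yielding five bins: frequencies 1-4 in ascending
#' order map to bin 1, ..., 17-20 to bin 5.
#'
#' @param frequency_hz Numeric vector of per-trial nominal frequencies.
#' @param stimulus_set The nominal frequency set, ascending (default
#'   [default_stimulus_set()]).
#' @param per_bin Number of adjacent frequencies per bin (default 4).
#' @return Integer vector of bin labels in \code{1..length(stimulus_set)/per_bin}.
#' @export
bin_frequencies <- function(frequency_hz, stimulus_set = default_stimulus_set(),
                            per_bin = 4) {
  stopifnot(length(stimulus_set) %% per_bin == 0)
  # tolerance admits tables stored at 6 significant digits; adjacent
  # nominal frequencies are ~15% apart so matching stays unambiguous
  idx <- vapply(frequency_hz, function(f) {
    j <- which(abs(stimulus_set - f) <= 1e-5 * f)
    if (length(j) != 1) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    stop(sprintf("frequency not in the stimulus set: %s",
                 paste(unique(frequency_hz[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  (idx - 1L) %/% as.integer(per_bin) + 1L
}

#' Count spikes in the spontaneous and evoked windows
#'
#' For every unit and trial, counts spikes in the evoked window
#' \code{[onset, onset + 0.5)} and the spontaneous window
#' \code{[onset - 0.7, onset - 0.2)} (700-200 ms before tone-cloud onset,
#' i.e. ending at LED onset). Both windows last 0.5 s, so rates are
#' count / 0.5. Windows are half-open: a spike exactly at the right edge is
#' excluded.
#'
#' @param session A \code{session}.
#' @param spont_window Numeric length-2 offset of the spontaneous window
#'   relative to onset (default \code{c(-0.7, -0.2)}).
#' @return data.frame with columns \code{unit_id}, \code{trial_id},
#'   \code{evoked_count}, \code{spont_count}; one row per unit x trial.
#' @export
count_spikes <- function(session, spont_window = c(-0.7, -0.2)) {
  tr <- session$trials
  dur <- session$stimulus_duration_s
  ids <- session$units$unit_id
  n_lt <- function(t, x) findInterval(x, t, left.open = TRUE)  # #{t < x}
  res <- lapply(ids, function(u) {
    t <- session$spikes$spike_time_s[session$spikes$unit_id == u]
    ev <- n_lt(t, tr$onset_s + dur) - n_lt(t, tr$onset_s)
    sp <- n_lt(t, tr$onset_s + spont_window[2]) -
          n_lt(t, tr$onset_s + spont_window[1])
    data.frame(unit_id = u, trial_id = tr$trial_id,
               evoked_count = ev, spont_count = sp)
  })
  do.call(rbind, res)
}

#' Classify a unit as narrow- or broad-spiking from its waveform
#'
#' The trough is the global minimum of the template (earliest sample on
#' ties); the trough-to-peak time is the interval from the trough to the
#' subsequent maximum. Units with trough-to-peak below 600 microseconds are
#' narrow spiking (NS, putative inhibitory); at or above, broad spiking
#' (BS, putative excitatory). Also reports the peak/trough ratio (peak
#' height divided by trough depth).
#'
#' @param waveform Numeric voltage template, arbitrary units.
#' @param sample_rate_hz Sampling rate of the template in Hz.
#' @param threshold_us NS/BS boundary in microseconds (default 600).
#' @return List with \code{unit_class} (\code{"NS"} or \code{"BS"}),
#'   \code{trough_to_peak_us} and \code{peak_trough_ratio}.
#' @export
classify_unit <- function(waveform, sample_rate_hz, threshold_us = 600) {
  stopifnot(length(waveform) >= 2, sample_rate_hz > 0)
  trough <- which.min(waveform)
  if (trough == length(waveform))
    stop("waveform trough is the last sample; no post-trough peak to measure",
         call. = FALSE)
  after <- waveform[(trough + 1L):length(waveform)]
  peak <- trough + which.max(after)
  t2p_us <- (peak - trough) / sample_rate_hz * 1e6
  ratio <- waveform[peak] / abs(waveform[trough])
  list(unit_class = if (t2p_us < threshold_us) "NS" else "BS",
       trough_to_peak_us = t2p_us,
       peak_trough_ratio = ratio)
}

#' Annotate the trial table with condition and stimulus bin
#'
#' Convenience wrapper running movement classification, condition
#' assignment and frequency binning on one session. If the unit table
#' carries waveforms but no NS/BS labels, units are classified from their
#' templates.
#'
#' @param session A \code{session}.
#' @param movement_threshold_cm_s Movement threshold in cm/s.
#' @param waveform_sample_rate_hz Sampling rate of waveform templates.
#' @return data.frame: \code{trial_id}, \code{condition} (factor),
#'   \code{stimulus_bin}, \code{movement}, \code{led_on}.
#' @export
annotate_trials <- function(session, movement_threshold_cm_s = 1,
                            waveform_sample_rate_hz = 30000) {
  mv <- classify_movement(session, movement_threshold_cm_s)
  data.frame(trial_id = session$trials$trial_id,
             condition = assign_conditions(mv, session$trials$led_on),
             stimulus_bin = bin_frequencies(session$trials$frequency_hz),
             movement = mv,
             led_on = session$trials$led_on)
}

#' Fill in NS/BS labels from waveform templates
#'
#' Units whose class is missing or \code{"unknown"} and that have a
#' waveform template are classified with [classify_unit()]; supplied labels
#' are kept untouched.
#'
#' @inheritParams annotate_trials
#' @param sample_rate_hz Waveform sampling rate in Hz (default 30 kHz).
#' @return The session with \code{units$unit_class} completed.
#' @export
classify_session_units <- function(session, sample_rate_hz = 30000) {
  u <- session$units
  for (i in seq_len(nrow(u))) {
    cls <- u$unit_class[i]
    if (!is.na(cls) && cls %in% c("NS", "BS")) next
    wf <- session$waveforms[[as.character(u$unit_id[i])]]
    if (is.null(wf)) next
    u$unit_class[i] <- classify_unit(wf, sample_rate_hz)$unit_class
  }
  session$units <- u
  session
}
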