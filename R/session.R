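#' @useDynLib statecoding, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Nominal tone-cloud stimulus set
#'
#' The 20 nominal tone-cloud center frequencies, log-spaced from 4 to 64 kHz
#' (four octaves, 20 steps).
#'
#' @return Numeric vector of 20 frequencies in Hz, ascending.
#' @export
default_stimulus_set <- function() {
  2^seq(log2(4000), log2(64000), length.out = 20)
}

#' Construct a recording session
#'
#' Bundles the event tables of one recording: sorted spike times per unit,
#' the trial schedule (stimulus onset, tone-cloud center frequency, LED
#' flag), the treadmill velocity trace, and unit metadata. All times are in
#' seconds relative to session start; analysis windows are half-open
#' \code{[a, b)}.
#'
#' @param session_id Character scalar identifying the recording.
#' @param spikes data.frame with columns \code{unit_id}, \code{spike_time_s}.
#' @param trials data.frame with columns \code{trial_id}, \code{onset_s},
#'   \code{frequency_hz}, \code{led_on} (logical).
#' @param velocity data.frame with columns \code{time_s},
#'   \code{velocity_cm_s}; sampling may be irregular.
#' @param units data.frame with column \code{unit_id} and optionally
#'   \code{unit_class} (\code{"NS"}, \code{"BS"} or \code{"unknown"}). If
#'   \code{NULL}, built from the unit ids present in \code{spikes}.
#' @param waveforms Optional named list of numeric waveform templates, one
#'   per unit id.
#' @param stimulus_duration_s Tone-cloud duration in seconds (default 0.5).
#'
#' @return An object of class \code{session}.
#' @export
new_session <- function(session_id, spikes, trials, velocity, units = NULL,
                        waveforms = NULL, stimulus_duration_s = 0.5) {
  if (is.null(units)) {
    ids <- sort(unique(spikes$unit_id))
    units <- data.frame(unit_id = ids, unit_class = rep("unknown", length(ids)),
                        stringsAsFactors = FALSE)
  }
  if (is.null(units$unit_class)) units$unit_class <- "unknown"
  s <- structure(
    list(session_id = as.character(session_id),
         spikes = spikes, trials = trials, velocity = velocity,
         units = units, waveforms = waveforms,
         stimulus_duration_s = stimulus_duration_s),
    class = "session")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks that spike times are non-negative and sorted within unit, trial
#' onsets are strictly increasing with inter-onset interval at least the
#' stimulus duration, and every spike's unit id appears in the unit table.
#' Violations raise an error; rows are never silently dropped.
#'
#' @param session A \code{session} object.
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  sp <- session$spikes
  tr <- session$trials
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing required column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(sp, c("unit_id", "spike_time_s"), "spike")
  need(tr, c("trial_id", "onset_s", "frequency_hz", "led_on"), "trial")
  need(session$velocity, c("time_s", "velocity_cm_s"), "velocity")
  need(session$units, "unit_id", "units")

  if (nrow(sp)) {
    if (any(sp$spike_time_s < 0))
      stop("spike times must be non-negative", call. = FALSE)
    unsorted <- tapply(sp$spike_time_s, sp$unit_id, function(t) is.unsorted(t))
    if (any(unsorted))
      stop(sprintf("spike times not sorted within unit(s): %s",
                   paste(names(unsorted)[unsorted], collapse = ", ")),
           call. = FALSE)
    if (!all(sp$unit_id %in% session$units$unit_id))
      stop("spike table contains unit ids absent from the unit table",
           call. = FALSE)
  }
  if (nrow(tr) > 1) {
    d <- diff(tr$onset_s)
    if (any(d <= 0))
      stop("trial onsets must be strictly increasing", call. = FALSE)
    if (any(d < session$stimulus_duration_s))
      stop("inter-onset interval shorter than the stimulus duration",
           call. = FALSE)
  }
  if (any(is.na(tr$led_on)))
    stop("led_on must be defined (TRUE/FALSE) for every trial", call. = FALSE)
  invisible(session)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s table %s is missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read a session from delimited event tables
#'
#' Reads the four tab-separated session tables (spikes, trials, velocity and
#' optionally units with waveform samples) and returns a validated
#' \code{session}. Rows violating the session invariants raise an error
#' rather than being dropped.
#'
#' @param spikes_path TSV with columns \code{unit_id}, \code{spike_time_s}.
#' @param trials_path TSV with columns \code{trial_id}, \code{onset_s},
#'   \code{frequency_hz}, \code{led_on}.
#' @param velocity_path TSV with columns \code{time_s}, \code{velocity_cm_s}.
#' @param units_path Optional TSV with \code{unit_id}, optionally
#'   \code{unit_class}, then one column per waveform sample (\code{w1},
#'   \code{w2}, ...).
#' @param session_id Session identifier; defaults to the spikes file's
#'   directory name.
#' @return A validated \code{session}.
#' @export
read_session <- function(spikes_path, trials_path, velocity_path,
                         units_path = NULL, session_id = NULL) {
  spikes <- read_tsv_checked(spikes_path, c("unit_id", "spike_time_s"), "spike")
  trials <- read_tsv_checked(trials_path,
                             c("trial_id", "onset_s", "frequency_hz", "led_on"),
                             "trial")
  trials$led_on <- as.logical(trials$led_on)
  velocity <- read_tsv_checked(velocity_path, c("time_s", "velocity_cm_s"),
                               "velocity")
  units <- NULL
  waveforms <- NULL
  if (!is.null(units_path)) {
    u <- read_tsv_checked(units_path, "unit_id", "units")
    wcols <- grep("^w[0-9]+$", names(u), value = TRUE)
    units <- u[, setdiff(names(u), wcols), drop = FALSE]
    if (length(wcols)) {
      wcols <- wcols[order(as.integer(sub("^w", "", wcols)))]
      waveforms <- lapply(seq_len(nrow(u)),
                          function(i) as.numeric(u[i, wcols]))
      names(waveforms) <- as.character(u$unit_id)
    }
  }
  if (is.null(session_id))
    session_id <- basename(dirname(normalizePath(spikes_path)))
  new_session(session_id, spikes, trials, velocity, units, waveforms)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_tsv_6g <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  path
}

#' Write a session to delimited event tables
#'
#' Inverse of [read_session()]: writes \code{spikes.tsv}, \code{trials.tsv},
#' \code{velocity.tsv} and \code{units.tsv} (unit id, class, then waveform
#' sample columns) into a directory. Numeric values are written with 6
#' significant digits so a read/write round trip is lossless at that
#' precision.
#'
#' @param session A \code{session}.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    spikes = file.path(dir, "spikes.tsv"),
    trials = file.path(dir, "trials.tsv"),
    velocity = file.path(dir, "velocity.tsv"),
    units = file.path(dir, "units.tsv"))
  write_tsv_6g(session$spikes, paths[["spikes"]])
  tr <- session$trials
  tr$led_on <- as.integer(tr$led_on)
  write_tsv_6g(tr, paths[["trials"]])
  write_tsv_6g(session$velocity, paths[["velocity"]])
  u <- session$units
  if (!is.null(session$waveforms)) {
    w <- do.call(rbind, session$waveforms[as.character(u$unit_id)])
    colnames(w) <- paste0("w", seq_len(ncol(w)))
    u <- cbind(u, as.data.frame(w))
  }
  write_tsv_6g(u, paths[["units"]])
  paths
}

#' Write pipeline result tables
#'
#' Writes the per-unit-by-condition results table (\code{results.tsv}), the
#' per-pair correlation table (\code{pairs.tsv}) and the group statistics
#' summary (\code{stats.json}). Numeric values carry 6 significant digits;
#' tables re-read with [utils::read.table()] reproduce the values at that
#' precision. An empty pair table yields a header-only file.
#'
#' @param results data.frame of per-unit, per-condition estimates
#'   (from [equalized_estimates()]).
#' @param pairs data.frame of pair correlations (from [pair_correlations()]);
#'   may have zero rows.
#' @param stats List of statistics records (from [group_statistics()]), or
#'   \code{NULL}.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths.
#' @export
write_results <- function(results, pairs, stats, out_dir) {
  if (is.null(results) || !nrow(results))
    stop("results table is empty; nothing to write", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(out_dir, "results.tsv"),
             pairs = file.path(out_dir, "pairs.tsv"),
             stats = file.path(out_dir, "stats.json"))
  write_tsv_6g(results, paths[["results"]])
  write_tsv_6g(pairs, paths[["pairs"]])
  if (is.null(stats)) stats <- list()
  json <- jsonlite::toJSON(stats, auto_unbox = TRUE, digits = 6,
                           na = "null", pretty = TRUE)
  writeLines(json, paths[["stats"]])
  paths
}
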