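#' Assemble a binocular gaze recording
#'
#' A gaze recording holds ordered binocular samples at a nominal rate with a
#' per-eye validity code per sample.  Validity follows the eye-tracker export
#' convention: 0 means the eye was identified with high confidence, any
#' nonzero code means the sample is invalid for that eye (the simulator uses
#' code 4, "eye not found").  Coordinates may be missing (`NA`) only where
#' the corresponding validity code is nonzero.
#'
#' @param samples A data frame with columns `t` (ms since recording start),
#'   `lx`, `ly`, `lval`, `rx`, `ry`, `rval`.  Timestamps must be strictly
#'   increasing.
#' @param subject_id Subject identifier.
#' @param nominal_rate_hz Nominal sampling rate (250 Hz for the study
#'   hardware).
#' @param geometry The [screen_geometry()] the recording was made on.
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, subject_id = "unknown",
                           nominal_rate_hz = 250,
                           geometry = screen_geometry()) {
  required <- c("t", "lx", "ly", "lval", "rx", "ry", "rval")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(samples)[required]
  if (nrow(samples)) {
    if (!all(is.finite(samples$t)) || any(samples$t < 0)) {
      stop("timestamps must be finite and non-negative")
    }
    if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
      stop("timestamps must be strictly increasing (first offence at row ",
           which(diff(samples$t) <= 0)[1] + 1, ")")
    }
    bad_l <- (is.na(samples$lx) | is.na(samples$ly)) & samples$lval == 0
    bad_r <- (is.na(samples$rx) | is.na(samples$ry)) & samples$rval == 0
    if (any(bad_l | bad_r)) {
      stop("coordinates may be missing only when the validity code is nonzero")
    }
    if (nrow(samples) > 1) {
      med <- stats::median(diff(samples$t))
      if (abs(med - 1000 / nominal_rate_hz) > 0.1 * 1000 / nominal_rate_hz) {
        warning(sprintf(
          "median inter-sample interval %.3f ms deviates >10%% from nominal %g Hz",
          med, nominal_rate_hz))
      }
    }
  }
  structure(list(subject_id = subject_id, samples = samples,
                 nominal_rate_hz = nominal_rate_hz, geometry = geometry),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> subject %s: %d samples @ %g Hz nominal",
              x$subject_id, nrow(x$samples), x$nominal_rate_hz))
  if (nrow(x$samples)) {
    cat(sprintf(", span %.0f-%.0f ms", x$samples$t[1],
                x$samples$t[nrow(x$samples)]))
  }
  cat("\n")
  invisible(x)
}

gaze_tsv_columns <- c(
  t = "RecordingTimestamp",
  lx = "GazePointXLeft", ly = "GazePointYLeft", lval = "ValidityLeft",
  rx = "GazePointXRight", ry = "GazePointYRight", rval = "ValidityRight")

#' Read a gaze-sample TSV export
#'
#' Reads the tab-separated gaze dialect written by [write_gaze_tsv()]
#' (modelled on a Tobii-Studio-style export): one header row with columns
#' `RecordingTimestamp`, `GazePointXLeft`, `GazePointYLeft`, `ValidityLeft`,
#' `GazePointXRight`, `GazePointYRight`, `ValidityRight`.  Coordinate cells
#' may be empty when the corresponding validity code is nonzero.  Rows that
#' fail to parse (unreadable timestamp or validity, or a blank coordinate on
#' a valid eye) are dropped, counted, and reported via a warning and the
#' `n_malformed` attribute.
#'
#' @param path Path to the TSV file.
#' @param subject_id Subject identifier for the resulting recording.
#' @param nominal_rate_hz Nominal sampling rate.
#' @param geometry The [screen_geometry()] of the display.
#'
#' @return A [gaze_recording()] with attribute `n_malformed`.
#' @export
read_gaze_tsv <- function(path, subject_id = "unknown",
                          nominal_rate_hz = 250,
                          geometry = screen_geometry()) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(unname(gaze_tsv_columns), names(raw))
  if (length(missing_cols)) {
    stop("gaze TSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  smp <- data.frame(
    t = num("RecordingTimestamp"),
    lx = num("GazePointXLeft"), ly = num("GazePointYLeft"),
    lval = num("ValidityLeft"),
    rx = num("GazePointXRight"), ry = num("GazePointYRight"),
    rval = num("ValidityRight"))
  blank <- function(col) !nzchar(trimws(raw[[col]]))
  # blank coordinate cells are legitimate absences, not parse failures
  coord_ok <- function(v, b) !(is.na(v) & !b)
  malformed <- is.na(smp$t) | is.na(smp$lval) | is.na(smp$rval) |
    !coord_ok(smp$lx, blank("GazePointXLeft")) |
    !coord_ok(smp$ly, blank("GazePointYLeft")) |
    !coord_ok(smp$rx, blank("GazePointXRight")) |
    !coord_ok(smp$ry, blank("GazePointYRight")) |
    ((is.na(smp$lx) | is.na(smp$ly)) & smp$lval %in% 0) |
    ((is.na(smp$rx) | is.na(smp$ry)) & smp$rval %in% 0)
  n_malformed <- sum(malformed)
  if (n_malformed) {
    warning(n_malformed, " malformed row(s) dropped from ", path)
    smp <- smp[!malformed, , drop = FALSE]
  }
  if (nrow(smp) > 1 && any(diff(smp$t) <= 0)) {
    stop("non-monotone timestamps in ", path, ": first offending row ",
         which(diff(smp$t) <= 0)[1] + 1)
  }
  rownames(smp) <- NULL
  rec <- gaze_recording(smp, subject_id = subject_id,
                        nominal_rate_hz = nominal_rate_hz,
                        geometry = geometry)
  attr(rec, "n_malformed") <- n_malformed
  rec
}

#' Write a gaze recording as a TSV export
#'
#' Inverse of [read_gaze_tsv()].  Numbers are written with `%.17g` so that a
#' read/write round trip reproduces the recording exactly and two writes of
#' the same recording are byte-identical.  Missing coordinates are written
#' as empty cells.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  smp <- recording$samples
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- paste(unname(gaze_tsv_columns), collapse = "\t")
  if (nrow(smp)) {
    body <- paste(fmt(smp$t), fmt(smp$lx), fmt(smp$ly), fmt(smp$lval),
                  fmt(smp$rx), fmt(smp$ry), fmt(smp$rval), sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Sampling-quality report for a recording
#'
#' Estimates the effective sampling rate as `1000 / median inter-sample
#' interval`, counts timing gaps (intervals longer than 1.5x the median) and
#' the fraction of samples lost to them, and flags the recording when the
#' rate estimate deviates more than 10% from the nominal rate.
#'
#' @param recording A [gaze_recording()] with at least 2 samples.
#' @return A list with elements `rate_hz_estimate`, `median_interval_ms`,
#'   `n_gaps`, `dropped_fraction` and `flagged`.
#' @export
check_sampling <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  t <- recording$samples$t
  if (length(t) < 2) {
    stop("insufficient data: at least 2 samples required")
  }
  dt <- diff(t)
  med <- stats::median(dt)
  rate <- 1000 / med
  gaps <- dt > 1.5 * med
  expected_n <- (t[length(t)] - t[1]) / med + 1
  list(rate_hz_estimate = rate,
       median_interval_ms = med,
       n_gaps = sum(gaps),
       dropped_fraction = max(0, 1 - length(t) / expected_n),
       flagged = abs(rate - recording$nominal_rate_hz) >
         0.1 * recording$nominal_rate_hz)
}

#' Read and write the pipeline YAML configuration
#'
#' The configuration file mirrors the package's parameter objects under the
#' keys `geometry`, `ivt`, `validity` and `simulation`.  Keys that are
#' absent fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return For `read_config()`, a list with elements `geometry`
#'   ([screen_geometry()]), `ivt` ([ivt_params()]), `validity`
#'   ([trial_validity_params()]) and `simulation` ([simulation_params()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(fun, values) do.call(fun, as.list(values))
  list(geometry = build(screen_geometry, cfg$geometry),
       ivt = build(ivt_params, cfg$ivt),
       validity = build(trial_validity_params, cfg$validity),
       simulation = build(simulation_params, cfg$simulation))
}

#' @rdname read_config
#' @param config A list as returned by [read_config()]; components default
#'   to the package defaults when omitted.
#' @export
write_config <- function(config = list(), path) {
  defaults <- list(geometry = screen_geometry(), ivt = ivt_params(),
                   validity = trial_validity_params(),
                   simulation = simulation_params())
  out <- lapply(names(defaults), function(k) {
    v <- if (is.null(config[[k]])) defaults[[k]] else config[[k]]
    lapply(unclass(v), function(x) if (is.null(x)) NULL else unname(x))
  })
  names(out) <- names(defaults)
  yaml::write_yaml(out, path)
  invisible(path)
}
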