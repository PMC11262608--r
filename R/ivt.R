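#' I-VT filter parameters
#'
#' Parameters of the velocity-threshold (I-VT) event-detection chain.  The
#' defaults are the settings used for the clinical VGS recordings: averaged
#' binocular eye selection, a 20 ms velocity window, 75 ms gap-fill
#' interpolation, fixation merging at <= 75 ms / <= 0.5 degrees, a 60 ms
#' minimum fixation duration, a 30 deg/s classifier threshold, and noise
#' reduction disabled.  `noise_reduction` is carried for configuration
#' fidelity only and is a no-op.
#'
#' All threshold comparisons in the chain are inclusive: velocity >= the
#' threshold classifies as saccadic, inter-fixation intervals <= the merge
#' maximum merge, and fixations >= the minimum duration are kept.
#'
#' @param velocity_window_ms Velocity window length (ms).
#' @param gap_fill_max_ms Longest data gap bridged by linear interpolation
#'   (ms).
#' @param merge_max_interval_ms Maximum interval between adjacent fixations
#'   that may merge (ms).
#' @param merge_max_angle_deg Maximum centroid separation of merging
#'   fixations (degrees).
#' @param min_fixation_ms Minimum fixation duration (ms); shorter fixations
#'   are reclassified as gaps.
#' @param velocity_threshold_deg_s I-VT classifier threshold (deg/s).
#' @param noise_reduction Logical flag, retained but inactive.
#' @param eye_selection Eye-selection mode; only `"average"` is
#'   implemented.
#'
#' @return An object of class `ivt_params`.
#' @export
ivt_params <- function(velocity_window_ms = 20, gap_fill_max_ms = 75,
                       merge_max_interval_ms = 75, merge_max_angle_deg = 0.5,
                       min_fixation_ms = 60, velocity_threshold_deg_s = 30,
                       noise_reduction = FALSE, eye_selection = "average") {
  durs <- c(velocity_window_ms = velocity_window_ms,
            gap_fill_max_ms = gap_fill_max_ms,
            merge_max_interval_ms = merge_max_interval_ms,
            min_fixation_ms = min_fixation_ms)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all I-VT durations must be positive")
  }
  if (!is.finite(velocity_threshold_deg_s) || velocity_threshold_deg_s <= 0) {
    stop("velocity threshold must be positive")
  }
  if (!is.finite(merge_max_angle_deg) || merge_max_angle_deg <= 0) {
    stop("merge_max_angle_deg must be positive")
  }
  eye_selection <- match.arg(eye_selection, "average")
  structure(list(velocity_window_ms = velocity_window_ms,
                 gap_fill_max_ms = gap_fill_max_ms,
                 merge_max_interval_ms = merge_max_interval_ms,
                 merge_max_angle_deg = merge_max_angle_deg,
                 min_fixation_ms = min_fixation_ms,
                 velocity_threshold_deg_s = velocity_threshold_deg_s,
                 noise_reduction = noise_reduction,
                 eye_selection = eye_selection),
            class = "ivt_params")
}

#' Combine the two eyes into a cyclopean gaze trace
#'
#' When both eyes are valid the cyclopean position is the midpoint; when
#' exactly one eye is valid that eye's position is used (tagged
#' `left-only` / `right-only`); when neither is valid the sample is
#' `missing`.
#'
#' @param recording A [gaze_recording()].
#' @return A data frame of cyclopean samples with columns `t`, `x`, `y`,
#'   `source` (one of `both`, `left-only`, `right-only`, `missing`;
#'   [fill_gaps()] adds `interpolated`).
#' @export
average_eyes <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  lok <- s$lval == 0 & !is.na(s$lx) & !is.na(s$ly)
  rok <- s$rval == 0 & !is.na(s$rx) & !is.na(s$ry)
  x <- ifelse(lok & rok, (s$lx + s$rx) / 2, ifelse(lok, s$lx, s$rx))
  y <- ifelse(lok & rok, (s$ly + s$ry) / 2, ifelse(lok, s$ly, s$ry))
  x[!lok & !rok] <- NA_real_
  y[!lok & !rok] <- NA_real_
  source <- ifelse(lok & rok, "both",
                   ifelse(lok, "left-only",
                          ifelse(rok, "right-only", "missing")))
  data.frame(t = s$t, x = x, y = y, source = source,
             stringsAsFactors = FALSE)
}

median_dt <- function(t) {
  if (length(t) < 2) return(NA_real_)
  stats::median(diff(t))
}

#' Interpolate short tracking gaps
#'
#' Runs of missing cyclopean samples no longer than `gap_fill_max_ms`,
#' flanked on both sides by samples with valid positions, are linearly
#' interpolated in time and tagged `interpolated`.  Longer runs, runs at
#' either edge of the recording, and runs overlapping any interval in
#' `exclude_intervals` (used to keep interpolation from bridging detected
#' blinks) are left missing.  The duration of a run of `k` missing samples
#' is taken as `k` sample periods.
#'
#' @param samples Cyclopean samples from [average_eyes()].
#' @param params [ivt_params()].
#' @param exclude_intervals Optional data frame with columns `t_start`,
#'   `t_end` (half-open, ms) that interpolation must not bridge.
#' @return The samples with fillable gaps interpolated.
#' @export
fill_gaps <- function(samples, params = ivt_params(),
                      exclude_intervals = NULL) {
  n <- nrow(samples)
  if (n == 0) return(samples)
  dt <- median_dt(samples$t)
  miss <- is.na(samples$x) | is.na(samples$y)
  if (!any(miss)) return(samples)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    if (i == 1 || j == n) next                       # no flanking anchor
    dur <- samples$t[j] - samples$t[i] + dt
    if (dur > params$gap_fill_max_ms) next
    if (!is.null(exclude_intervals) && nrow(exclude_intervals)) {
      overlaps <- exclude_intervals$t_start < samples$t[j] + dt &
        exclude_intervals$t_end > samples$t[i]
      if (any(overlaps)) next
    }
    t0 <- samples$t[i - 1]; t1 <- samples$t[j + 1]
    f <- (samples$t[i:j] - t0) / (t1 - t0)
    samples$x[i:j] <- samples$x[i - 1] + f * (samples$x[j + 1] - samples$x[i - 1])
    samples$y[i:j] <- samples$y[i - 1] + f * (samples$y[j + 1] - samples$y[i - 1])
    samples$source[i:j] <- "interpolated"
  }
  samples
}

#' Windowed angular velocity of the cyclopean trace
#'
#' The velocity at sample `i` is the angular distance between the samples
#' at the two ends of a window of length `velocity_window_ms` centred on
#' `i`, divided by their time separation.  At 250 Hz with the 20 ms default
#' this uses the samples two positions either side (a 16 ms endpoint
#' separation).  Velocity is left `NA` wherever the full symmetric window
#' does not fit (the first and last samples of the recording) or either
#' endpoint position is missing: a shrunken window would divide the noise
#' by a shorter time base and systematically misclassify edge samples as
#' saccadic.
#'
#' @param samples Gap-filled cyclopean samples.
#' @param geometry [screen_geometry()].
#' @param params [ivt_params()].
#' @return A data frame with columns `t` and `velocity` (deg/s, `NA` where
#'   undefined).
#' @export
compute_velocity <- function(samples, geometry = screen_geometry(),
                             params = ivt_params()) {
  n <- nrow(samples)
  v <- rep(NA_real_, n)
  if (n >= 3) {
    dt <- median_dt(samples$t)
    k <- max(1L, floor((params$velocity_window_ms / 2) / dt))
    idx <- seq_len(n)
    ok <- idx - k >= 1L & idx + k <= n
    lo <- pmax(idx - k, 1L)
    hi <- pmin(idx + k, n)
    ang <- rep(NA_real_, n)
    ang[ok] <- angular_distance_deg(samples$x[lo[ok]], samples$y[lo[ok]],
                                    samples$x[hi[ok]], samples$y[hi[ok]],
                                    geometry)
    sep <- samples$t[pmax(hi, 1L)] - samples$t[pmax(lo, 1L)]
    v[ok] <- ang[ok] / sep[ok] * 1000
  }
  data.frame(t = samples$t, velocity = v)
}

#' Classify samples by the I-VT velocity threshold
#'
#' Samples with angular velocity at or above the threshold are saccadic,
#' below it fixational; samples with undefined velocity are `missing`.
#'
#' @param vel Velocity trace from [compute_velocity()].
#' @param params [ivt_params()].
#' @return Character vector of per-sample labels (`"fixation"`,
#'   `"saccade"`, `"missing"`).
#' @export
classify_ivt <- function(vel, params = ivt_params()) {
  ifelse(is.na(vel$velocity), "missing",
         ifelse(vel$velocity >= params$velocity_threshold_deg_s,
                "saccade", "fixation"))
}

#' Detect blinks from raw validity codes
#'
#' Blinks are maximal runs in the raw (pre-interpolation) recording where
#' BOTH eyes are invalid, with a duration inside the physiological bounds.
#' Shorter both-eyes-invalid runs are treated as data gaps, longer ones as
#' tracking loss; runs where only one eye is invalid are never blinks.  The
#' duration of a run of `k` samples is `k` sample periods.
#'
#' @param recording A raw [gaze_recording()].
#' @param min_blink_ms,max_blink_ms Duration bounds (ms); the defaults
#'   bracket physiological blinks.
#' @return A data frame of blink events with columns `kind` (`"blink"`),
#'   `t_start`, `t_end` (half-open, ms).
#' @export
detect_blinks <- function(recording, min_blink_ms = 50, max_blink_ms = 500) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  empty <- data.frame(kind = character(), t_start = numeric(),
                      t_end = numeric(), stringsAsFactors = FALSE)
  if (!nrow(s)) return(empty)
  dt <- median_dt(s$t)
  if (is.na(dt)) dt <- 1000 / recording$nominal_rate_hz
  both_bad <- s$lval != 0 & s$rval != 0
  if (!any(both_bad)) return(empty)
  r <- rle(both_bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  t_start <- s$t[starts[keep]]
  t_end <- ifelse(ends[keep] < nrow(s), s$t[pmin(ends[keep] + 1, nrow(s))],
                  s$t[ends[keep]] + dt)
  dur <- t_end - t_start
  ok <- dur >= min_blink_ms & dur <= max_blink_ms
  data.frame(kind = rep("blink", sum(ok)), t_start = t_start[ok],
             t_end = t_end[ok], stringsAsFactors = FALSE)
}

#' Assemble per-sample labels into an event stream
#'
#' Maximal runs of identically labelled samples become events: saccade runs
#' carry start/end times and positions, fixation runs carry a centroid, and
#' missing runs become gap events, so that the event spans tile the
#' recording's time span.  Detected blink intervals take precedence over
#' the I-VT labels: samples inside a blink are relabelled `blink` before
#' run-length assembly (truncating any overlapping saccade or fixation
#' run).
#'
#' @param labels Per-sample labels from [classify_ivt()].
#' @param samples The cyclopean samples the labels align to.
#' @param blinks Optional blink events from [detect_blinks()].
#' @return An event-stream data frame with columns `kind`, `t_start`,
#'   `t_end`, `x_start`, `y_start`, `x_end`, `y_end`, `centroid_x`,
#'   `centroid_y`, `n_samples` (positional fields `NA` where inapplicable).
#' @export
extract_saccades <- function(labels, samples, blinks = NULL) {
  n <- nrow(samples)
  stopifnot(length(labels) == n)
  empty <- event_stream_skeleton(0)
  if (n == 0) return(empty)
  labels[labels == "missing"] <- "gap"
  if (!is.null(blinks) && nrow(blinks)) {
    for (b in seq_len(nrow(blinks))) {
      labels[samples$t >= blinks$t_start[b] &
               samples$t < blinks$t_end[b]] <- "blink"
    }
  }
  dt <- median_dt(samples$t)
  if (is.na(dt)) dt <- 4
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  ev <- event_stream_skeleton(m)
  ev$kind <- r$values
  ev$t_start <- samples$t[starts]
  ev$t_end <- c(samples$t[starts[-1]], samples$t[n] + dt)
  ev$n_samples <- r$lengths
  for (k in seq_len(m)) {
    i <- starts[k]; j <- ends[k]
    if (r$values[k] == "saccade") {
      ev$x_start[k] <- samples$x[i]; ev$y_start[k] <- samples$y[i]
      ev$x_end[k] <- samples$x[j]; ev$y_end[k] <- samples$y[j]
    } else if (r$values[k] == "fixation") {
      ev$centroid_x[k] <- mean(samples$x[i:j], na.rm = TRUE)
      ev$centroid_y[k] <- mean(samples$y[i:j], na.rm = TRUE)
    }
  }
  ev
}

event_stream_skeleton <- function(n) {
  data.frame(kind = character(n), t_start = numeric(n), t_end = numeric(n),
             x_start = rep(NA_real_, n), y_start = rep(NA_real_, n),
             x_end = rep(NA_real_, n), y_end = rep(NA_real_, n),
             centroid_x = rep(NA_real_, n), centroid_y = rep(NA_real_, n),
             n_samples = rep(NA_integer_, n), stringsAsFactors = FALSE)
}

#' Merge adjacent fixations
#'
#' Adjacent fixations whose inter-fixation interval is at most
#' `merge_max_interval_ms` and whose centroids are at most
#' `merge_max_angle_deg` apart are combined: the merged span is the union,
#' the centroid the duration-weighted mean.  Events lying between the two
#' fixations (gaps, or isolated noise-induced saccade fragments) are
#' absorbed into the merged fixation -- except blinks, which always block a
#' merge.  The pass repeats until stable, so the operation is idempotent.
#'
#' @param events An event stream from [extract_saccades()].
#' @param params [ivt_params()].
#' @param geometry [screen_geometry()] used for the centroid angle test.
#' @return The merged event stream.
#' @export
merge_fixations <- function(events, params = ivt_params(),
                            geometry = screen_geometry()) {
  repeat {
    fix_idx <- which(events$kind == "fixation")
    if (length(fix_idx) < 2) return(events)
    merged_any <- FALSE
    drop <- logical(nrow(events))
    cur <- fix_idx[1]
    for (nxt in fix_idx[-1]) {
      if (drop[nxt]) next
      between <- if (nxt > cur + 1) (cur + 1):(nxt - 1) else integer(0)
      blocked <- any(events$kind[between] == "blink")
      interval <- events$t_start[nxt] - events$t_end[cur]
      ang <- angular_distance_deg(events$centroid_x[cur],
                                  events$centroid_y[cur],
                                  events$centroid_x[nxt],
                                  events$centroid_y[nxt], geometry)
      if (!blocked && interval <= params$merge_max_interval_ms &&
          ang <= params$merge_max_angle_deg) {
        w1 <- events$t_end[cur] - events$t_start[cur]
        w2 <- events$t_end[nxt] - events$t_start[nxt]
        events$centroid_x[cur] <-
          (events$centroid_x[cur] * w1 + events$centroid_x[nxt] * w2) /
          (w1 + w2)
        events$centroid_y[cur] <-
          (events$centroid_y[cur] * w1 + events$centroid_y[nxt] * w2) /
          (w1 + w2)
        events$t_end[cur] <- events$t_end[nxt]
        events$n_samples[cur] <- events$n_samples[cur] + events$n_samples[nxt]
        drop[between] <- TRUE
        drop[nxt] <- TRUE
        merged_any <- TRUE
      } else {
        cur <- nxt
      }
    }
    events <- events[!drop, , drop = FALSE]
    rownames(events) <- NULL
    if (!merged_any) return(events)
  }
}

#' Discard fixations below the minimum duration
#'
#' Fixations shorter than `min_fixation_ms` are reclassified as gaps
#' (the duration comparison is inclusive: a fixation exactly at the
#' minimum is kept).  Other events are unchanged.
#'
#' @param events An event stream (normally after [merge_fixations()]).
#' @param params [ivt_params()].
#' @return The filtered event stream.
#' @export
drop_short_fixations <- function(events, params = ivt_params()) {
  short <- events$kind == "fixation" &
    (events$t_end - events$t_start) < params$min_fixation_ms
  events$kind[short] <- "gap"
  events$centroid_x[short] <- NA_real_
  events$centroid_y[short] <- NA_real_
  events
}

#' Run the full I-VT event-detection chain
#'
#' Applies, in order: blink detection on the raw validity codes, binocular
#' averaging, blink excision (so interpolation never bridges a blink),
#' gap-fill interpolation, windowed velocity computation, velocity-threshold
#' classification, run-length event assembly with blink precedence,
#' fixation merging, and minimum-fixation-duration filtering.
#'
#' @param recording A [gaze_recording()].
#' @param params [ivt_params()].
#' @param min_blink_ms,max_blink_ms Blink duration bounds passed to
#'   [detect_blinks()].
#' @return An object of class `vgs_events`: a list with elements `events`
#'   (the final event stream), `samples` (gap-filled cyclopean samples),
#'   `velocity` (the velocity trace), `blinks` and `labels`.
#' @export
detect_events <- function(recording, params = ivt_params(),
                          min_blink_ms = 50, max_blink_ms = 500) {
  stopifnot(inherits(recording, "gaze_recording"))
  blinks <- detect_blinks(recording, min_blink_ms, max_blink_ms)
  cyc <- average_eyes(recording)
  if (nrow(blinks)) {
    for (b in seq_len(nrow(blinks))) {
      inside <- cyc$t >= blinks$t_start[b] & cyc$t < blinks$t_end[b]
      cyc$x[inside] <- NA_real_
      cyc$y[inside] <- NA_real_
      cyc$source[inside] <- "missing"
    }
  }
  cyc <- fill_gaps(cyc, params, exclude_intervals = blinks)
  vel <- compute_velocity(cyc, recording$geometry, params)
  labels <- classify_ivt(vel, params)
  events <- extract_saccades(labels, cyc, blinks)
  events <- merge_fixations(events, params, recording$geometry)
  events <- drop_short_fixations(events, params)
  structure(list(events = events, samples = cyc, velocity = vel,
                 blinks = blinks, labels = labels,
                 geometry = recording$geometry),
            class = "vgs_events")
}

#' @export
print.vgs_events <- function(x, ...) {
  tab <- table(x$events$kind)
  cat("<vgs_events>", nrow(x$events), "events over",
      sprintf("%.1f s:", (max(x$events$t_end) - min(x$events$t_start)) / 1000),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export an event stream as CSV
#'
#' @param events An event-stream data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("kind", "t_start", "t_end", "x_start", "y_start",
            "x_end", "y_end", "centroid_x", "centroid_y")
  utils::write.csv(events[cols], path, row.names = FALSE, na = "")
  invisible(path)
}
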