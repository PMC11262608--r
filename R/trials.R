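#' Gap-paradigm stimulus protocol
#'
#' One trial presents a central dot for 1500 ms, a 200 ms blank gap, then
#' an eccentric dot for 1500 ms (trial period 3200 ms).  The horizontal
#' task places targets at -18, -10, +10 and +18 degrees along the
#' horizontal meridian, ten presentations each (40 per task); the vertical
#' task places them at 8 degrees above and below centre, twenty
#' presentations each.  Signed amplitudes follow the screen convention
#' (origin top-left, y downward): a negative vertical amplitude is an
#' upward target.
#'
#' @param task `"horizontal"` or `"vertical"`.
#' @param central_ms,gap_ms,target_ms Phase durations (ms).
#' @param amplitudes_deg Signed target eccentricities (degrees); defaults
#'   by task as above.
#' @param reps_per_amplitude Presentations per amplitude; defaults to 10
#'   (horizontal) or 20 (vertical) so that both tasks total 40.
#'
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(task = c("horizontal", "vertical"),
                              central_ms = 1500, gap_ms = 200,
                              target_ms = 1500, amplitudes_deg = NULL,
                              reps_per_amplitude = NULL) {
  task <- match.arg(task)
  if (is.null(amplitudes_deg)) {
    amplitudes_deg <- if (task == "horizontal") c(-18, -10, 10, 18)
                      else c(-8, 8)
  }
  if (is.null(reps_per_amplitude)) {
    reps_per_amplitude <- if (task == "horizontal") 10 else 20
  }
  stopifnot(central_ms > 0, gap_ms > 0, target_ms > 0,
            length(amplitudes_deg) >= 1, reps_per_amplitude >= 1)
  structure(list(task = task, central_ms = central_ms, gap_ms = gap_ms,
                 target_ms = target_ms, amplitudes_deg = amplitudes_deg,
                 reps_per_amplitude = reps_per_amplitude),
            class = "stimulus_protocol")
}

#' Classify a target amplitude into an eccentricity class
#'
#' Horizontal targets are `near` (10 deg) or `far` (18 deg); vertical
#' targets are `up` (negative screen-y amplitude) or `down` (positive).
#'
#' @param amplitude_deg Signed amplitude (degrees).
#' @param task Task name.
#' @return Character vector of classes.
#' @export
eccentricity_class <- function(amplitude_deg, task) {
  if (task == "horizontal") {
    ifelse(abs(amplitude_deg) <= 14, "near", "far")
  } else {
    ifelse(amplitude_deg < 0, "up", "down")
  }
}

#' Build a randomized stimulus schedule
#'
#' Each amplitude is presented `reps_per_amplitude` times in a uniformly
#' random order determined by `seed`; trials are laid back-to-back on the
#' 1500/200/1500 ms template.  The global RNG state is left untouched.
#'
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed for the permutation.
#' @param geometry [screen_geometry()] used to place targets in pixels.
#' @return A data frame of stimulus events with columns `trial_index`,
#'   `task`, `central_onset`, `central_offset`, `target_onset`,
#'   `target_offset` (ms), `target_amplitude_deg`, `eccentricity_class`,
#'   `target_x_px`, `target_y_px`.
#' @export
build_schedule <- function(protocol, seed = 1,
                           geometry = screen_geometry()) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  amps <- rep(protocol$amplitudes_deg, each = protocol$reps_per_amplitude)
  amps <- amps[with_seed(seed, sample.int(length(amps)))]
  n <- length(amps)
  period <- protocol$central_ms + protocol$gap_ms + protocol$target_ms
  onset <- (seq_len(n) - 1) * period
  ctr <- screen_center(geometry)
  off_px <- degrees_to_pixels(abs(amps), geometry) * sign(amps)
  if (protocol$task == "horizontal") {
    tx <- ctr[["x"]] + off_px; ty <- rep(ctr[["y"]], n)
  } else {
    tx <- rep(ctr[["x"]], n); ty <- ctr[["y"]] + off_px
  }
  data.frame(trial_index = seq_len(n), task = protocol$task,
             central_onset = onset,
             central_offset = onset + protocol$central_ms,
             target_onset = onset + protocol$central_ms + protocol$gap_ms,
             target_offset = onset + period,
             target_amplitude_deg = amps,
             eccentricity_class = eccentricity_class(amps, protocol$task),
             target_x_px = tx, target_y_px = ty,
             stringsAsFactors = FALSE)
}

#' Trial validity parameters
#'
#' The acceptance rules applied to each gap-paradigm trial: no saccade or
#' blink in the 60 ms before central-dot offset, gaze within 100 px of the
#' screen centre at central-dot offset, and a first centre-originating
#' saccade with latency in `[min_latency_ms, max_latency_ms)` after target
#' onset (shorter latencies are anticipatory).  Subjects need at least
#' `min_valid_trials` valid trials per task to be included.
#'
#' @param pre_offset_exclusion_ms Pre-offset exclusion window (ms).
#' @param start_radius_px Start-point radius around centre (px).
#' @param min_latency_ms Anticipatory latency cut-off (ms).
#' @param max_latency_ms Upper latency bound (ms); defaults to the target
#'   presentation time so the saccade must begin while the target is shown.
#' @param min_valid_trials Minimum valid trials per task for inclusion.
#' @return An object of class `trial_validity_params`.
#' @export
trial_validity_params <- function(pre_offset_exclusion_ms = 60,
                                  start_radius_px = 100,
                                  min_latency_ms = 100,
                                  max_latency_ms = 1500,
                                  min_valid_trials = 6) {
  stopifnot(pre_offset_exclusion_ms > 0, start_radius_px > 0,
            min_latency_ms >= 0, max_latency_ms > min_latency_ms,
            min_valid_trials >= 1)
  structure(list(pre_offset_exclusion_ms = pre_offset_exclusion_ms,
                 start_radius_px = start_radius_px,
                 min_latency_ms = min_latency_ms,
                 max_latency_ms = max_latency_ms,
                 min_valid_trials = min_valid_trials),
            class = "trial_validity_params")
}

#' Segment a detected recording into trials
#'
#' One trial per stimulus event, holding the event-stream slice over
#' `[central_onset, target_offset)` (events overlapping the window).
#'
#' @param detection A `vgs_events` object from [detect_events()], or a bare
#'   event-stream data frame.
#' @param schedule A schedule from [build_schedule()].
#' @return A list of trials, each a list with elements `stimulus` (one
#'   schedule row) and `events` (the overlapping slice).
#' @export
segment_trials <- function(detection, schedule) {
  events <- if (inherits(detection, "vgs_events")) detection$events
            else detection
  if (nrow(events)) {
    span_end <- max(events$t_end)
    short <- schedule$trial_index[schedule$target_offset > span_end + 1e-9]
  } else {
    short <- schedule$trial_index
  }
  if (length(short)) {
    stop("recording shorter than schedule; missing trial(s): ",
         paste(short, collapse = ", "))
  }
  lapply(seq_len(nrow(schedule)), function(i) {
    st <- schedule[i, , drop = FALSE]
    slice <- events[events$t_end > st$central_onset &
                      events$t_start < st$target_offset, , drop = FALSE]
    rownames(slice) <- NULL
    list(stimulus = st, events = slice)
  })
}

gaze_at_time <- function(samples, t) {
  idx <- which(samples$t < t)
  if (!length(idx)) return(c(NA_real_, NA_real_))
  i <- idx[length(idx)]
  c(samples$x[i], samples$y[i])
}

#' Select the first target-directed saccade of a trial
#'
#' The earliest saccade event starting at or after target onset whose start
#' position lies within the start radius of the screen centre; `NULL` if no
#' such saccade begins before target offset.
#'
#' @param trial A trial from [segment_trials()].
#' @param params [trial_validity_params()].
#' @param geometry [screen_geometry()].
#' @return A one-row saccade event data frame, or `NULL`.
#' @export
select_first_saccade <- function(trial, params = trial_validity_params(),
                                 geometry = screen_geometry()) {
  st <- trial$stimulus
  ev <- trial$events
  ctr <- screen_center(geometry)
  cand <- ev[ev$kind == "saccade" &
               ev$t_start >= st$target_onset &
               ev$t_start < st$target_offset, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  d <- sqrt((cand$x_start - ctr[["x"]])^2 + (cand$y_start - ctr[["y"]])^2)
  cand <- cand[!is.na(d) & d <= params$start_radius_px, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[which.min(cand$t_start), , drop = FALSE]
}

#' Compute the saccadic parameters of a selected saccade
#'
#' Latency is measured from target onset to saccade onset; amplitude is
#' the angular distance between the gaze positions at saccade start and
#' end; mean and peak velocity are taken over the velocity trace within
#' the saccade span; gain is amplitude divided by the absolute target
#' amplitude.
#'
#' @param saccade A one-row saccade event.
#' @param vel The velocity trace from [compute_velocity()].
#' @param stimulus The stimulus-event row of the trial.
#' @param geometry [screen_geometry()].
#' @return A one-row data frame with columns `latency_ms`, `duration_ms`,
#'   `amplitude_deg`, `mean_velocity_deg_s`, `peak_velocity_deg_s`,
#'   `gain`.
#' @export
compute_saccade_metrics <- function(saccade, vel, stimulus,
                                    geometry = screen_geometry()) {
  duration <- saccade$t_end - saccade$t_start
  if (duration <= 0) stop("zero-duration saccade event")
  amplitude <- angular_distance_deg(saccade$x_start, saccade$y_start,
                                    saccade$x_end, saccade$y_end, geometry)
  inside <- vel$t >= saccade$t_start & vel$t < saccade$t_end
  vspan <- vel$velocity[inside]
  vspan <- vspan[!is.na(vspan)]
  data.frame(latency_ms = saccade$t_start - stimulus$target_onset,
             duration_ms = duration,
             amplitude_deg = amplitude,
             mean_velocity_deg_s = if (length(vspan)) mean(vspan) else NA_real_,
             peak_velocity_deg_s = if (length(vspan)) max(vspan) else NA_real_,
             gain = amplitude / abs(stimulus$target_amplitude_deg))
}

#' Apply the trial validity criteria
#'
#' Checks, in order: (a) no saccade or blink event overlapping the 60 ms
#' window before central-dot offset; (b) gaze within the start radius of
#' the screen centre at central-dot offset (a missing position is tracking
#' loss); (c) a first centre-originating saccade beginning within the
#' latency window after target onset.  The first failing check becomes the
#' trial's `invalid_reason`; valid trials get their saccadic metrics.
#'
#' @param trial A trial from [segment_trials()].
#' @param detection The `vgs_events` object (for gaze samples and the
#'   velocity trace).
#' @param params [trial_validity_params()].
#' @param geometry [screen_geometry()].
#' @return The trial with elements `verdict` (`"valid"`/`"invalid"`),
#'   `invalid_reason` (`NA` when valid) and `metrics` (one-row data frame
#'   when valid, else `NULL`).
#' @export
validate_trial <- function(trial, detection,
                           params = trial_validity_params(),
                           geometry = screen_geometry()) {
  st <- trial$stimulus
  ev <- trial$events
  fail <- function(reason) {
    trial$verdict <- "invalid"
    trial$invalid_reason <- reason
    trial$metrics <- NULL
    trial
  }
  win_start <- st$central_offset - params$pre_offset_exclusion_ms
  overlapping <- ev$t_end > win_start & ev$t_start < st$central_offset
  if (any(overlapping & ev$kind == "saccade")) return(fail("pre_offset_saccade"))
  if (any(overlapping & ev$kind == "blink"))   return(fail("pre_offset_blink"))
  pos <- gaze_at_time(detection$samples, st$central_offset)
  if (any(is.na(pos))) return(fail("tracking_loss"))
  ctr <- screen_center(geometry)
  if (sqrt((pos[1] - ctr[["x"]])^2 + (pos[2] - ctr[["y"]])^2) >
      params$start_radius_px) {
    return(fail("off_center_start"))
  }
  sac <- select_first_saccade(trial, params, geometry)
  if (is.null(sac)) return(fail("no_saccade"))
  latency <- sac$t_start - st$target_onset
  if (latency < params$min_latency_ms) return(fail("anticipatory"))
  if (latency >= params$max_latency_ms) return(fail("no_saccade"))
  trial$verdict <- "valid"
  trial$invalid_reason <- NA_character_
  trial$metrics <- compute_saccade_metrics(sac, detection$velocity, st,
                                           geometry)
  trial$saccade <- sac
  trial
}

#' Analyze a full session into a trial table
#'
#' Runs [segment_trials()] and [validate_trial()] over a schedule and
#' returns one row per trial with the verdict and (for valid trials) the
#' saccadic parameters.
#'
#' @param detection A `vgs_events` object from [detect_events()].
#' @param schedule A schedule from [build_schedule()].
#' @param params [trial_validity_params()].
#' @param geometry [screen_geometry()].
#' @param subject_id Subject identifier carried into the table.
#' @return A data frame with columns `subject_id`, `task`, `trial_index`,
#'   `eccentricity_class`, `target_amplitude_deg`, `verdict`,
#'   `invalid_reason`, `latency_ms`, `duration_ms`, `amplitude_deg`,
#'   `mean_velocity_deg_s`, `peak_velocity_deg_s`, `gain`.
#' @export
analyze_trials <- function(detection, schedule,
                           params = trial_validity_params(),
                           geometry = screen_geometry(),
                           subject_id = "unknown") {
  trials <- segment_trials(detection, schedule)
  rows <- lapply(trials, function(tr) {
    tr <- validate_trial(tr, detection, params, geometry)
    metrics <- if (is.null(tr$metrics)) {
      data.frame(latency_ms = NA_real_, duration_ms = NA_real_,
                 amplitude_deg = NA_real_, mean_velocity_deg_s = NA_real_,
                 peak_velocity_deg_s = NA_real_, gain = NA_real_)
    } else {
      tr$metrics
    }
    cbind(data.frame(subject_id = subject_id,
                     task = tr$stimulus$task,
                     trial_index = tr$stimulus$trial_index,
                     eccentricity_class = tr$stimulus$eccentricity_class,
                     target_amplitude_deg = tr$stimulus$target_amplitude_deg,
                     verdict = tr$verdict,
                     invalid_reason = tr$invalid_reason,
                     stringsAsFactors = FALSE),
          metrics)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Blink rate over a task
#'
#' @param blinks Blink events from [detect_blinks()] (a data frame; only
#'   the row count is used).
#' @param task_span_ms Duration of the task (ms), strictly positive.
#' @return Blinks per minute.
#' @export
blink_rate <- function(blinks, task_span_ms) {
  if (!is.finite(task_span_ms) || task_span_ms <= 0) {
    stop("task_span_ms must be strictly positive")
  }
  nrow(blinks) * 60000 / task_span_ms
}

metric_cols <- c("latency_ms", "duration_ms", "amplitude_deg",
                 "mean_velocity_deg_s", "peak_velocity_deg_s", "gain")

#' Aggregate a subject's trials
#'
#' Per-task, per-eccentricity-class means and sample SDs (n-1 denominator)
#' of the six saccadic parameters over valid trials, the percentage of
#' valid trials per task, the per-task blink rate, and the inclusion flag
#' (at least `min_valid_trials` valid trials in the task).
#'
#' @param trials A trial table from [analyze_trials()] (may span several
#'   tasks).
#' @param blink_rate_by_task Named numeric vector of blink rates
#'   (blinks/min) keyed by task, or `NULL`.
#' @param params [trial_validity_params()].
#' @return An object of class `subject_summary`: a list with `by_class`
#'   (one row per task x class with `n_valid` and `<metric>_mean` /
#'   `<metric>_sd` columns) and `by_task` (one row per task with
#'   `n_trials`, `n_valid`, `percent_valid`, `blink_rate`, `included`).
#' @export
aggregate_subject <- function(trials, blink_rate_by_task = NULL,
                              params = trial_validity_params()) {
  stopifnot(nrow(trials) > 0)
  subject_id <- trials$subject_id[1]
  valid <- trials[trials$verdict == "valid", , drop = FALSE]
  by_task <- do.call(rbind, lapply(unique(trials$task), function(tk) {
    n_trials <- sum(trials$task == tk)
    n_valid <- sum(valid$task == tk)
    data.frame(subject_id = subject_id, task = tk, n_trials = n_trials,
               n_valid = n_valid,
               percent_valid = 100 * n_valid / n_trials,
               blink_rate = if (!is.null(blink_rate_by_task) &&
                                tk %in% names(blink_rate_by_task))
                 unname(blink_rate_by_task[[tk]]) else NA_real_,
               included = n_valid >= params$min_valid_trials,
               stringsAsFactors = FALSE)
  }))
  combos <- unique(trials[c("task", "eccentricity_class")])
  by_class <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- valid[valid$task == combos$task[i] &
                   valid$eccentricity_class == combos$eccentricity_class[i],
                 , drop = FALSE]
    stats_row <- lapply(metric_cols, function(cl) {
      c(mean = if (nrow(sel)) mean(sel[[cl]]) else NA_real_,
        sd = if (nrow(sel) > 1) stats::sd(sel[[cl]]) else NA_real_)
    })
    out <- data.frame(subject_id = subject_id, task = combos$task[i],
                      eccentricity_class = combos$eccentricity_class[i],
                      n_valid = nrow(sel), stringsAsFactors = FALSE)
    for (k in seq_along(metric_cols)) {
      out[[paste0(metric_cols[k], "_mean")]] <- stats_row[[k]][["mean"]]
      out[[paste0(metric_cols[k], "_sd")]] <- stats_row[[k]][["sd"]]
    }
    out
  }))
  rownames(by_task) <- rownames(by_class) <- NULL
  structure(list(by_class = by_class, by_task = by_task),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat("<subject_summary>", x$by_task$subject_id[1], "\n")
  print(x$by_task, row.names = FALSE)
  invisible(x)
}
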