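#' Synthetic oculomotor simulation parameters
#'
#' Controls the gap-paradigm session simulator.  Saccade kinematics follow
#' a saturating main-sequence model with a raised-cosine velocity profile;
#' latencies are shifted-gamma distributed; gains are Gaussian (truncated
#' to a physical range); blinks arrive as a Poisson process with uniform
#' durations; tracking loss is per-sample, per-eye Bernoulli.  The default
#' values are literature-norm choices for adult saccades on a 250 Hz
#' screen-based tracker: a 600 deg/s velocity ceiling with an 8 deg
#' amplitude constant, latencies of roughly 230 +/- 50 ms (shift 130 ms,
#' gamma shape 4 x scale 25 ms), mildly hypometric gain 0.9 +/- 0.08,
#' 0.15 deg position noise, 12 blinks/min lasting 100-300 ms, a 5%
#' anticipatory-saccade probability and 0.2% per-eye sample loss.
#'
#' @param main_sequence_vmax Asymptotic peak velocity (deg/s).
#' @param main_sequence_a0 Main-sequence amplitude constant (deg).
#' @param latency_shape,latency_scale,latency_shift Shifted-gamma latency
#'   parameters (scale and shift in ms).
#' @param gain_mean,gain_sd Saccadic gain distribution (dimensionless);
#'   `gain_mean` must lie in (0, 1.5].
#' @param noise_sd_deg Additive Gaussian gaze-position noise SD (degrees).
#' @param blink_rate_per_min Poisson blink rate (1/min).
#' @param blink_duration_ms_range Uniform blink duration bounds (ms).
#' @param p_anticipatory Probability of an anticipatory saccade (latency
#'   drawn uniformly on `[0, 100)` ms).
#' @param data_loss_rate Per-sample, per-eye probability of tracking loss.
#' @param interocular_offset_deg Fixed horizontal offset between the two
#'   simulated eyes (degrees), so eye averaging is exercised nontrivially.
#' @param return_latency_range_ms Uniform bounds for the latency of the
#'   recentring saccade after central-dot onset (ms).
#' @param sample_rate_hz Sampling rate of the simulated recording.
#' @param seed Default session seed (optional).
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(main_sequence_vmax = 600,
                              main_sequence_a0 = 8,
                              latency_shape = 4, latency_scale = 25,
                              latency_shift = 130,
                              gain_mean = 0.9, gain_sd = 0.08,
                              noise_sd_deg = 0.15,
                              blink_rate_per_min = 12,
                              blink_duration_ms_range = c(100, 300),
                              p_anticipatory = 0.05,
                              data_loss_rate = 0.002,
                              interocular_offset_deg = 0.3,
                              return_latency_range_ms = c(150, 400),
                              sample_rate_hz = 250,
                              seed = NULL) {
  nonneg <- c(latency_shape, latency_scale, latency_shift, gain_sd,
              noise_sd_deg, blink_rate_per_min, p_anticipatory,
              data_loss_rate, interocular_offset_deg)
  if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
    stop("rates, SDs and shifts must be non-negative")
  }
  if (gain_mean <= 0 || gain_mean > 1.5) stop("gain_mean must lie in (0, 1.5]")
  if (p_anticipatory > 1 || data_loss_rate > 1) {
    stop("probabilities must not exceed 1")
  }
  stopifnot(main_sequence_vmax > 0, main_sequence_a0 > 0, sample_rate_hz > 0,
            length(blink_duration_ms_range) == 2,
            blink_duration_ms_range[1] > 0,
            diff(blink_duration_ms_range) >= 0,
            length(return_latency_range_ms) == 2)
  structure(list(main_sequence_vmax = main_sequence_vmax,
                 main_sequence_a0 = main_sequence_a0,
                 latency_shape = latency_shape,
                 latency_scale = latency_scale,
                 latency_shift = latency_shift,
                 gain_mean = gain_mean, gain_sd = gain_sd,
                 noise_sd_deg = noise_sd_deg,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_duration_ms_range = blink_duration_ms_range,
                 p_anticipatory = p_anticipatory,
                 data_loss_rate = data_loss_rate,
                 interocular_offset_deg = interocular_offset_deg,
                 return_latency_range_ms = return_latency_range_ms,
                 sample_rate_hz = sample_rate_hz,
                 seed = seed),
            class = "simulation_params")
}

#' Main-sequence peak velocity
#'
#' Saturating exponential main sequence:
#' `vmax * (1 - exp(-amplitude / a0))`.  Strictly increasing in amplitude
#' and saturating at `vmax`.
#'
#' @param amplitude Saccade amplitude in degrees, strictly positive
#'   (vectorised).
#' @param params [simulation_params()].
#' @return Peak velocity in deg/s.
#' @export
main_sequence <- function(amplitude, params = simulation_params()) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0)) {
    stop("amplitude must be strictly positive")
  }
  params$main_sequence_vmax * (1 - exp(-amplitude / params$main_sequence_a0))
}

#' Raised-cosine saccade waveform
#'
#' Velocity profile `v(t) = Vp * (1 - cos(2*pi*t/D)) / 2` with duration
#' `D = 2 * amplitude / Vp`, sampled at `rate_hz` (the exact endpoint `D`
#' is always included).  The position is the closed-form integral, so the
#' sampled displacement spans exactly `amplitude` and the time-mean of
#' `v(t)` over the profile is exactly `Vp / 2`.
#'
#' @param amplitude Saccade amplitude (degrees), positive.
#' @param peak_velocity Peak velocity `Vp` (deg/s), positive.
#' @param onset_ms Time of saccade onset added to the time axis (ms).
#' @param rate_hz Sampling rate.
#' @return A data frame with columns `t_ms`, `position_deg`,
#'   `velocity_deg_s`, and attribute `duration_ms` (`= 2 * amplitude /
#'   peak_velocity`, in ms).
#' @export
saccade_waveform <- function(amplitude, peak_velocity, onset_ms = 0,
                             rate_hz = 250) {
  stopifnot(amplitude > 0, peak_velocity > 0, rate_hz > 0)
  duration_ms <- 2 * amplitude / peak_velocity * 1000
  dt <- 1000 / rate_hz
  t <- seq(0, duration_ms, by = dt)
  if (t[length(t)] < duration_ms) t <- c(t, duration_ms)
  phase <- 2 * pi * t / duration_ms
  velocity <- peak_velocity * (1 - cos(phase)) / 2
  # closed-form integral of the raised cosine (t in ms -> /1000)
  position <- peak_velocity / 2 *
    (t / 1000 - duration_ms / 1000 / (2 * pi) * sin(phase))
  out <- data.frame(t_ms = onset_ms + t, position_deg = position,
                    velocity_deg_s = velocity)
  attr(out, "duration_ms") <- duration_ms
  out
}

raised_cosine_fraction <- function(t_ms, duration_ms) {
  # fraction of total displacement completed at time t of the profile
  t <- pmin(pmax(t_ms, 0), duration_ms)
  (t / duration_ms) - sin(2 * pi * t / duration_ms) / (2 * pi)
}

#' Simulate a single gap-paradigm trial
#'
#' Generates the cyclopean gaze path for one stimulus presentation --
#' fixation at the centre (with a recentring saccade first if the gaze
#' starts away from centre), a latency draw (anticipatory with probability
#' `p_anticipatory`), a raised-cosine saccade to `gain x target
#' eccentricity`, and post-saccadic fixation -- then derives binocular
#' samples with a fixed interocular offset, inserts Poisson blinks as
#' both-eyes-invalid runs, and applies per-eye sample loss.  Uses the
#' current RNG state; [simulate_session()] wraps it in per-trial
#' substreams.
#'
#' @param stimulus A one-row stimulus event from [build_schedule()].
#' @param params [simulation_params()].
#' @param geometry [screen_geometry()].
#' @param start_xy Gaze position (px) at trial start; defaults to the
#'   screen centre.
#' @return A list with `samples` (binocular sample data frame), `truth`
#'   (one-row ground-truth data frame), `blink_times` (data frame of blink
#'   intervals), `return_saccade` (one-row data frame or `NULL`) and
#'   `end_xy` (noise-free gaze position at trial end, for chaining).
#' @export
simulate_trial <- function(stimulus, params = simulation_params(),
                           geometry = screen_geometry(), start_xy = NULL) {
  ctr <- screen_center(geometry)
  if (is.null(start_xy)) start_xy <- unname(ctr)
  dt <- 1000 / params$sample_rate_hz
  t0 <- stimulus$central_onset
  t1 <- stimulus$target_offset
  n <- round((t1 - t0) / dt)
  t <- t0 + (seq_len(n) - 1) * dt

  x <- rep(ctr[["x"]], n)
  y <- rep(ctr[["y"]], n)

  # recentring saccade during the central-dot period, if needed
  return_saccade <- NULL
  start_off <- sqrt((start_xy[1] - ctr[["x"]])^2 +
                      (start_xy[2] - ctr[["y"]])^2)
  if (start_off > degrees_to_pixels(0.5, geometry)) {
    amp_ret <- angular_distance_deg(start_xy[1], start_xy[2],
                                    ctr[["x"]], ctr[["y"]], geometry)
    vp_ret <- main_sequence(amp_ret, params)
    d_ret <- 2 * amp_ret / vp_ret * 1000
    lat_ret <- stats::runif(1, params$return_latency_range_ms[1],
                            params$return_latency_range_ms[2])
    lat_ret <- min(lat_ret, stimulus$central_offset - t0 - d_ret - 100)
    on_ret <- t0 + lat_ret
    before <- t < on_ret
    x[before] <- start_xy[1]
    y[before] <- start_xy[2]
    during <- t >= on_ret & t < on_ret + d_ret
    f <- raised_cosine_fraction(t[during] - on_ret, d_ret)
    x[during] <- start_xy[1] + f * (ctr[["x"]] - start_xy[1])
    y[during] <- start_xy[2] + f * (ctr[["y"]] - start_xy[2])
    return_saccade <- data.frame(trial_index = stimulus$trial_index,
                                 onset_ms = on_ret,
                                 offset_ms = on_ret + d_ret,
                                 amplitude_deg = amp_ret,
                                 peak_velocity_deg_s = vp_ret)
  }

  # target saccade
  anticipatory <- stats::runif(1) < params$p_anticipatory
  latency <- if (anticipatory) {
    stats::runif(1, 0, 100)
  } else {
    params$latency_shift +
      stats::rgamma(1, shape = params$latency_shape,
                    scale = params$latency_scale)
  }
  gain <- stats::rnorm(1, params$gain_mean, params$gain_sd)
  gain <- min(max(gain, 0.1), 1.5)
  amp <- gain * abs(stimulus$target_amplitude_deg)
  vp <- main_sequence(amp, params)
  d_sac <- 2 * amp / vp * 1000
  latency <- min(latency,
                 stimulus$target_offset - stimulus$target_onset - d_sac -
                   3 * dt)
  onset <- stimulus$target_onset + latency
  u <- c(stimulus$target_x_px - ctr[["x"]], stimulus$target_y_px - ctr[["y"]])
  u <- u / sqrt(sum(u^2))
  during <- t >= onset & t < onset + d_sac
  f <- raised_cosine_fraction(t[during] - onset, d_sac)
  off_px <- degrees_to_pixels(f * amp, geometry)
  x[during] <- ctr[["x"]] + u[1] * off_px
  y[during] <- ctr[["y"]] + u[2] * off_px
  after <- t >= onset + d_sac
  end_px <- degrees_to_pixels(amp, geometry)
  x[after] <- ctr[["x"]] + u[1] * end_px
  y[after] <- ctr[["y"]] + u[2] * end_px
  end_xy <- c(ctr[["x"]] + u[1] * end_px, ctr[["y"]] + u[2] * end_px)

  # additive gaze noise
  if (params$noise_sd_deg > 0) {
    noise_px <- degrees_to_pixels(params$noise_sd_deg, geometry)
    x <- x + stats::rnorm(n, 0, noise_px)
    y <- y + stats::rnorm(n, 0, noise_px)
  }

  # binocular derivation with fixed interocular offset
  half_off <- degrees_to_pixels(params$interocular_offset_deg, geometry) / 2
  smp <- data.frame(t = t,
                    lx = x - half_off, ly = y, lval = 0,
                    rx = x + half_off, ry = y, rval = 0)

  # blinks: Poisson count, uniform placement and duration
  dur_min <- (t1 - t0) / 60000
  n_blinks <- stats::rpois(1, params$blink_rate_per_min * dur_min)
  blink_times <- data.frame(trial_index = integer(), t_start = numeric(),
                            t_end = numeric())
  if (n_blinks > 0) {
    bdur <- stats::runif(n_blinks, params$blink_duration_ms_range[1],
                         params$blink_duration_ms_range[2])
    bstart <- sort(stats::runif(n_blinks, t0, t1 - max(bdur)))
    bend <- bstart + bdur
    keep <- rep(TRUE, n_blinks)
    if (n_blinks > 1) {                      # discard overlapping blinks
      for (k in 2:n_blinks) keep[k] <- bstart[k] >= max(bend[seq_len(k - 1)][keep[seq_len(k - 1)]])
    }
    blink_times <- data.frame(trial_index = stimulus$trial_index,
                              t_start = bstart[keep], t_end = bend[keep])
    for (k in seq_len(nrow(blink_times))) {
      inside <- smp$t >= blink_times$t_start[k] & smp$t < blink_times$t_end[k]
      smp$lval[inside] <- 4; smp$rval[inside] <- 4
      smp$lx[inside] <- smp$ly[inside] <- NA_real_
      smp$rx[inside] <- smp$ry[inside] <- NA_real_
    }
  }

  # independent per-eye tracking loss
  if (params$data_loss_rate > 0) {
    lose_l <- stats::runif(n) < params$data_loss_rate
    lose_r <- stats::runif(n) < params$data_loss_rate
    smp$lval[lose_l] <- 4
    smp$lx[lose_l] <- smp$ly[lose_l] <- NA_real_
    smp$rval[lose_r] <- 4
    smp$rx[lose_r] <- smp$ry[lose_r] <- NA_real_
  }

  truth <- data.frame(trial_index = stimulus$trial_index,
                      task = stimulus$task,
                      eccentricity_class = stimulus$eccentricity_class,
                      target_amplitude_deg = stimulus$target_amplitude_deg,
                      true_latency_ms = latency,
                      true_onset_ms = onset,
                      true_offset_ms = onset + d_sac,
                      true_amplitude_deg = amp,
                      true_peak_velocity_deg_s = vp,
                      true_duration_ms = d_sac,
                      true_gain = gain,
                      anticipatory = anticipatory,
                      stringsAsFactors = FALSE)
  list(samples = smp, truth = truth, blink_times = blink_times,
       return_saccade = return_saccade, end_xy = end_xy)
}

#' Simulate a full gap-paradigm session
#'
#' Builds a randomized schedule, simulates each trial with the gaze
#' position chained across trial boundaries (so each trial begins with a
#' recentring saccade from the previous target), and assembles the
#' binocular recording plus a ground-truth sidecar.  Each trial draws from
#' its own RNG substream derived from the session seed, so the session is
#' reproducible and trial truths do not shift when the trial count
#' changes.
#'
#' @param protocol A [stimulus_protocol()].
#' @param params [simulation_params()].
#' @param geometry [screen_geometry()].
#' @param subject_id Subject identifier.
#' @param seed Session seed; defaults to `params$seed`, else 1.
#' @return A list with elements `recording` ([gaze_recording()]),
#'   `schedule`, and `truth` -- itself a list with `trials` (per-trial
#'   ground-truth data frame), `return_saccades`, `blinks` and `saccades`
#'   (all true saccades, target and recentring, with onsets/offsets).
#' @export
simulate_session <- function(protocol, params = simulation_params(),
                             geometry = screen_geometry(),
                             subject_id = "sim", seed = NULL) {
  if (is.null(seed)) seed <- if (!is.null(params$seed)) params$seed else 1
  schedule <- build_schedule(protocol, seed = seed, geometry = geometry)
  ctr <- screen_center(geometry)
  pos <- unname(ctr)
  parts <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    parts[[i]] <- with_seed(substream_seed(seed, i), {
      simulate_trial(schedule[i, , drop = FALSE], params, geometry,
                     start_xy = pos)
    })
    pos <- parts[[i]]$end_xy
  }
  samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
  rownames(samples) <- NULL
  truth_trials <- do.call(rbind, lapply(parts, `[[`, "truth"))
  blinks <- do.call(rbind, lapply(parts, `[[`, "blink_times"))
  returns <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(parts, `[[`, "return_saccade")))
  target_sac <- data.frame(trial_index = truth_trials$trial_index,
                           kind = "target",
                           onset_ms = truth_trials$true_onset_ms,
                           offset_ms = truth_trials$true_offset_ms,
                           amplitude_deg = truth_trials$true_amplitude_deg,
                           peak_velocity_deg_s =
                             truth_trials$true_peak_velocity_deg_s,
                           stringsAsFactors = FALSE)
  all_sac <- target_sac
  if (!is.null(returns) && nrow(returns)) {
    ret <- data.frame(trial_index = returns$trial_index, kind = "return",
                      onset_ms = returns$onset_ms,
                      offset_ms = returns$offset_ms,
                      amplitude_deg = returns$amplitude_deg,
                      peak_velocity_deg_s = returns$peak_velocity_deg_s,
                      stringsAsFactors = FALSE)
    all_sac <- rbind(all_sac, ret)
  }
  all_sac <- all_sac[order(all_sac$onset_ms), , drop = FALSE]
  rownames(all_sac) <- NULL
  recording <- gaze_recording(samples, subject_id = subject_id,
                              nominal_rate_hz = params$sample_rate_hz,
                              geometry = geometry)
  list(recording = recording, schedule = schedule,
       truth = list(trials = truth_trials,
                    return_saccades = returns,
                    blinks = blinks,
                    saccades = all_sac))
}

#' Write / read the ground-truth sidecar (JSON lines)
#'
#' One JSON object per trial mirroring the ground-truth fields, with
#' per-trial blink intervals nested.
#'
#' @param truth The `truth` element of a [simulate_session()] result.
#' @param path Output path.
#' @return `path` invisibly (writer); a ground-truth list (reader).
#' @export
write_ground_truth_jsonl <- function(truth, path) {
  trials <- truth$trials
  lines <- vapply(seq_len(nrow(trials)), function(i) {
    rec <- as.list(trials[i, , drop = FALSE])
    bt <- truth$blinks[truth$blinks$trial_index == trials$trial_index[i], ,
                       drop = FALSE]
    rec$blink_times <- unname(lapply(seq_len(nrow(bt)), function(k) {
      c(bt$t_start[k], bt$t_end[k])
    }))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ground_truth_jsonl
#' @export
read_ground_truth_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  trials <- do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r[setdiff(names(r), "blink_times")],
                  stringsAsFactors = FALSE)
  }))
  blinks <- do.call(rbind, lapply(recs, function(r) {
    bt <- r$blink_times
    if (is.null(bt) || !length(bt)) return(NULL)
    if (!is.matrix(bt)) bt <- do.call(rbind, bt)
    data.frame(trial_index = r$trial_index, t_start = bt[, 1],
               t_end = bt[, 2])
  }))
  list(trials = trials, blinks = blinks)
}
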