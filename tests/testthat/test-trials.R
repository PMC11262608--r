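geom <- screen_geometry()
ctr <- screen_center(geom)

one_trial_schedule <- function(amplitude = 10, task = "horizontal") {
  build_schedule(stimulus_protocol(task, amplitudes_deg = amplitude,
                                   reps_per_amplitude = 1), seed = 1)
}

# detection stub: fixation at centre except for the listed saccade events
scenario_detection <- function(events, span_ms = 3200) {
  t <- seq(0, span_ms - 4, by = 4)
  samples <- data.frame(t = t, x = rep(ctr[["x"]], length(t)),
                        y = rep(ctr[["y"]], length(t)), source = "both")
  fake_detection(events, samples)
}

test_that("schedules present each amplitude the prescribed number of times", {
  sched <- build_schedule(stimulus_protocol("horizontal"), seed = 42)
  expect_equal(nrow(sched), 40)
  expect_equal(as.integer(table(sched$target_amplitude_deg)[c("-18", "-10", "10", "18")]),
               rep(10L, 4))
  expect_equal(diff(sched$target_onset), rep(3200, 39))
  expect_equal(sched$central_offset - sched$central_onset, rep(1500, 40))
  expect_equal(sched$target_onset - sched$central_offset, rep(200, 40))

  vert <- build_schedule(stimulus_protocol("vertical"), seed = 42)
  expect_equal(nrow(vert), 40)
  expect_equal(as.integer(table(vert$target_amplitude_deg)), rep(20L, 2))
  expect_equal(unique(vert$eccentricity_class[vert$target_amplitude_deg < 0]),
               "up")
  expect_true(all(vert$target_y_px[vert$eccentricity_class == "up"] <
                    ctr[["y"]]))
})

test_that("schedule randomization is seed-deterministic", {
  p <- stimulus_protocol("horizontal")
  expect_identical(build_schedule(p, seed = 5), build_schedule(p, seed = 5))
  expect_false(identical(build_schedule(p, seed = 5)$target_amplitude_deg,
                         build_schedule(p, seed = 6)$target_amplitude_deg))
})

test_that("segmentation yields one trial per stimulus or a truncation error", {
  sched <- build_schedule(stimulus_protocol("horizontal"), seed = 1)
  full <- make_events(make_event("fixation", 0, 40 * 3200,
                                 centroid_x = ctr[["x"]],
                                 centroid_y = ctr[["y"]]))
  trials <- segment_trials(full, sched)
  expect_length(trials, 40)
  short <- make_events(make_event("fixation", 0, 50000,
                                  centroid_x = ctr[["x"]],
                                  centroid_y = ctr[["y"]]))
  expect_error(segment_trials(short, sched), "missing trial.*17")
  empty <- full[0, ]
  expect_error(segment_trials(empty, sched), "missing trial")
})

test_that("validity criteria fire in order with the documented reasons", {
  sched <- one_trial_schedule()
  st <- sched[1, ]
  base_fix <- function(until) {
    make_event("fixation", 0, until, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]])
  }
  target_sac <- make_event("saccade", st$target_onset + 250,
                           st$target_onset + 300,
                           x_start = ctr[["x"]], y_start = ctr[["y"]],
                           x_end = ctr[["x"]] + degrees_to_pixels(9, geom),
                           y_end = ctr[["y"]])

  # blink ending 30 ms before central-dot offset: inside the 60 ms window
  ev <- make_events(base_fix(1400),
                    make_event("blink", 1400, st$central_offset - 30),
                    target_sac)
  tr <- validate_trial(list(stimulus = st, events = ev),
                       scenario_detection(ev))
  expect_equal(tr$verdict, "invalid")
  expect_equal(tr$invalid_reason, "pre_offset_blink")

  # saccade overlapping the pre-offset window outranks everything later
  ev2 <- make_events(base_fix(1450),
                     make_event("saccade", 1450, 1480,
                                x_start = ctr[["x"]], y_start = ctr[["y"]],
                                x_end = ctr[["x"]] + 50, y_end = ctr[["y"]]),
                     target_sac)
  tr2 <- validate_trial(list(stimulus = st, events = ev2),
                        scenario_detection(ev2))
  expect_equal(tr2$invalid_reason, "pre_offset_saccade")

  # anticipatory: first saccade only 80 ms after target onset
  ant <- make_event("saccade", st$target_onset + 80, st$target_onset + 130,
                    x_start = ctr[["x"]], y_start = ctr[["y"]],
                    x_end = ctr[["x"]] + 400, y_end = ctr[["y"]])
  ev3 <- make_events(base_fix(st$target_onset + 80), ant)
  tr3 <- validate_trial(list(stimulus = st, events = ev3),
                        scenario_detection(ev3))
  expect_equal(tr3$invalid_reason, "anticipatory")

  # no saccade at all during the target window
  ev4 <- make_events(base_fix(st$target_offset))
  tr4 <- validate_trial(list(stimulus = st, events = ev4),
                        scenario_detection(ev4))
  expect_equal(tr4$invalid_reason, "no_saccade")
})

test_that("off-centre gaze at central-dot offset invalidates the trial", {
  sched <- one_trial_schedule()
  st <- sched[1, ]
  ev <- make_events(make_event("fixation", 0, st$target_offset,
                               centroid_x = ctr[["x"]] + 150,
                               centroid_y = ctr[["y"]]))
  det <- scenario_detection(ev)
  det$samples$x <- ctr[["x"]] + 150   # gaze parked 150 px off centre
  tr <- validate_trial(list(stimulus = st, events = ev), det)
  expect_equal(tr$invalid_reason, "off_center_start")
})

test_that("first centre-originating saccade is selected", {
  sched <- one_trial_schedule()
  st <- sched[1, ]
  sac <- function(latency, x0 = ctr[["x"]]) {
    make_event("saccade", st$target_onset + latency,
               st$target_onset + latency + 50,
               x_start = x0, y_start = ctr[["y"]],
               x_end = x0 + 400, y_end = ctr[["y"]])
  }
  tr <- list(stimulus = st, events = make_events(sac(150), sac(400)))
  pick <- select_first_saccade(tr)
  expect_equal(pick$t_start, st$target_onset + 150)

  off <- list(stimulus = st,
              events = make_events(sac(150, x0 = ctr[["x"]] + 300)))
  expect_null(select_first_saccade(off))
  expect_null(select_first_saccade(list(stimulus = st,
                                        events = make_events(sac(150))[0, ])))
})

test_that("saccadic parameters follow their definitions", {
  sched <- one_trial_schedule()   # target onset at 1700 ms
  st <- sched[1, ]
  expect_equal(st$target_onset, 1700)
  sac <- make_event("saccade", 1950, 2000,
                    x_start = ctr[["x"]], y_start = ctr[["y"]],
                    x_end = ctr[["x"]] + degrees_to_pixels(9, geom),
                    y_end = ctr[["y"]])
  vel <- data.frame(t = seq(0, 3196, by = 4), velocity = 0)
  m <- compute_saccade_metrics(sac, vel, st, geom)
  expect_equal(m$latency_ms, 250)
  expect_equal(m$duration_ms, 50)
  expect_equal(m$amplitude_deg, 9, tolerance = 1e-9)
  expect_equal(m$gain, 0.9, tolerance = 1e-9)
})

test_that("mean velocity of a raised-cosine saccade is half its peak", {
  vp <- main_sequence(10)
  wf <- saccade_waveform(10, vp, onset_ms = 1950, rate_hz = 250)
  sac <- make_event("saccade", 1950, max(wf$t_ms),
                    x_start = ctr[["x"]], y_start = ctr[["y"]],
                    x_end = ctr[["x"]] + degrees_to_pixels(10, geom),
                    y_end = ctr[["y"]])
  vel <- data.frame(t = wf$t_ms, velocity = wf$velocity_deg_s)
  st <- one_trial_schedule()[1, ]
  m <- compute_saccade_metrics(sac, vel, st, geom)
  expect_lt(abs(m$mean_velocity_deg_s - m$peak_velocity_deg_s / 2) /
              (m$peak_velocity_deg_s / 2), 0.05)
})

test_that("blink rate is blinks per minute over the task span", {
  twelve <- data.frame(t_start = seq_len(12), t_end = seq_len(12) + 100)
  expect_equal(blink_rate(twelve, 4 * 60000), 3.0)
  expect_equal(blink_rate(twelve[0, ], 4 * 60000), 0.0)
  expect_error(blink_rate(twelve, 0), "positive")
})

test_that("subject aggregation applies the 6-valid-trial inclusion rule", {
  fake_trials <- function(n_valid, n_total = 40) {
    data.frame(subject_id = "S1", task = "horizontal",
               trial_index = seq_len(n_total),
               eccentricity_class = rep(c("near", "far"),
                                        length.out = n_total),
               target_amplitude_deg = rep(c(10, 18), length.out = n_total),
               verdict = c(rep("valid", n_valid),
                           rep("invalid", n_total - n_valid)),
               invalid_reason = NA_character_,
               latency_ms = 250, duration_ms = 50, amplitude_deg = 9,
               mean_velocity_deg_s = 200, peak_velocity_deg_s = 400,
               gain = 0.9, stringsAsFactors = FALSE)
  }
  expect_false(aggregate_subject(fake_trials(5))$by_task$included)
  expect_true(aggregate_subject(fake_trials(6))$by_task$included)
  agg <- aggregate_subject(fake_trials(30),
                           blink_rate_by_task = c(horizontal = 7.5))
  expect_equal(agg$by_task$percent_valid, 75.0)
  expect_equal(agg$by_task$blink_rate, 7.5)
  # percent_valid is invariant to trial order
  shuffled <- fake_trials(30)[withr::with_seed(1, sample(40)), ]
  expect_equal(aggregate_subject(shuffled)$by_task$percent_valid, 75.0)
})

test_that("per-class means are computed over valid trials with n-1 SDs", {
  tr <- data.frame(subject_id = "S1", task = "horizontal",
                   trial_index = 1:4,
                   eccentricity_class = c("near", "near", "far", "near"),
                   target_amplitude_deg = c(10, 10, 18, 10),
                   verdict = c("valid", "valid", "valid", "invalid"),
                   invalid_reason = NA_character_,
                   latency_ms = c(200, 260, 300, 999),
                   duration_ms = 50, amplitude_deg = 9,
                   mean_velocity_deg_s = 200, peak_velocity_deg_s = 400,
                   gain = 0.9, stringsAsFactors = FALSE)
  agg <- aggregate_subject(tr)
  near <- agg$by_class[agg$by_class$eccentricity_class == "near", ]
  expect_equal(near$n_valid, 2)
  expect_equal(near$latency_ms_mean, 230)
  expect_equal(near$latency_ms_sd, stats::sd(c(200, 260)))
})

test_that("anticipatory rejection is complete away from the latency cutoff", {
  # An I-VT onset is the first supra-threshold sample, so a measured
  # latency exceeds the true motion-onset latency by the threshold
  # crossing time plus grid quantization (< 10 ms here).  Every clearly
  # anticipatory trial must be rejected as such; any accepted trial must
  # have a measured latency at or beyond the 100 ms cutoff.
  ses <- simulate_session(stimulus_protocol("horizontal"),
                          simulation_params(noise_sd_deg = 0,
                                            blink_rate_per_min = 0,
                                            p_anticipatory = 1,
                                            data_loss_rate = 0),
                          seed = 9)
  det <- detect_events(ses$recording)
  trials <- analyze_trials(det, ses$schedule)
  m <- merge(trials, ses$truth$trials, by = "trial_index")
  clear <- m$true_latency_ms <= 90
  expect_gt(sum(clear), 30)
  expect_true(all(m$invalid_reason[clear] == "anticipatory"))
  accepted <- m$verdict == "valid"
  expect_true(all(m$true_latency_ms[accepted] > 90))
  expect_true(all(m$latency_ms[accepted] >= 100))
})

test_that("detected blink rate calibrates against the simulated Poisson rate", {
  rates <- vapply(1:6, function(s) {
    ses <- simulate_session(stimulus_protocol("horizontal"),
                            simulation_params(blink_rate_per_min = 15,
                                              p_anticipatory = 0),
                            seed = 200 + s)
    blinks <- detect_blinks(ses$recording)
    span <- diff(range(ses$recording$samples$t)) + 4
    blink_rate(blinks, span)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 15), 3)
})
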