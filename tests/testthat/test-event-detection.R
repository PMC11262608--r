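geom <- screen_geometry()
ctr <- screen_center(geom)

test_that("eye averaging takes midpoints and falls back to the valid eye", {
  smp <- data.frame(t = c(0, 4, 8),
                    lx = c(100, 200, NA), ly = c(100, 300, NA),
                    lval = c(0, 0, 4),
                    rx = c(110, NA, NA), ry = c(100, NA, NA),
                    rval = c(0, 4, 4))
  cyc <- average_eyes(suppressWarnings(gaze_recording(smp)))
  expect_equal(cyc$x, c(105, 200, NA))
  expect_equal(cyc$y, c(100, 300, NA))
  expect_equal(cyc$source, c("both", "left-only", "missing"))
})

test_that("gap filling bridges short gaps only, and only with both flanks", {
  t <- seq(0, 396, by = 4)
  x <- rep(960, 100); y <- rep(540, 100)
  # 10 missing samples = 40 ms: fillable
  x[21:30] <- NA; y[21:30] <- NA
  # 25 missing samples = 100 ms: too long
  x[51:75] <- NA; y[51:75] <- NA
  # missing at the start: no left flank
  x[1:3] <- NA; y[1:3] <- NA
  cyc <- data.frame(t = t, x = x, y = y,
                    source = ifelse(is.na(x), "missing", "both"))
  cyc$x[20] <- 950; cyc$x[31] <- 970   # interpolation anchors
  filled <- fill_gaps(cyc, ivt_params())
  expect_false(anyNA(filled$x[21:30]))
  expect_equal(filled$source[21:30], rep("interpolated", 10))
  expect_equal(filled$x[25], 950 + (t[25] - t[20]) / (t[31] - t[20]) * 20)
  expect_true(all(is.na(filled$x[51:75])))
  expect_true(all(is.na(filled$x[1:3])))
})

test_that("gap filling never bridges an excluded blink interval", {
  t <- seq(0, 196, by = 4)
  x <- rep(960, 50); y <- rep(540, 50)
  x[11:20] <- NA; y[11:20] <- NA
  cyc <- data.frame(t = t, x = x, y = y,
                    source = ifelse(is.na(x), "missing", "both"))
  blk <- data.frame(t_start = t[12], t_end = t[18])
  filled <- fill_gaps(cyc, ivt_params(), exclude_intervals = blk)
  expect_true(all(is.na(filled$x[11:20])))
})

test_that("windowed velocity matches the chord-over-window definition", {
  # 100 Hz grid so the 20 ms window spans exactly one sample either side
  t <- seq(0, 190, by = 10)
  ecc <- seq_along(t) * 0.1   # 0.1 deg per 10 ms step along one ray
  x <- ctr[["x"]] + degrees_to_pixels(ecc, geom)
  y <- rep(ctr[["y"]], length(t))
  cyc <- data.frame(t = t, x = x, y = y, source = "both")
  vel <- compute_velocity(cyc, geom, ivt_params())
  inner <- 2:(length(t) - 1)
  expect_equal(vel$velocity[inner], rep(10, length(inner)), tolerance = 1e-9)
  expect_true(is.na(vel$velocity[1]))
  expect_true(is.na(vel$velocity[length(t)]))
})

test_that("stationary gaze has zero velocity and classifies as fixation", {
  t <- seq(0, 396, by = 4)
  cyc <- data.frame(t = t, x = rep(960, 100), y = rep(540, 100),
                    source = "both")
  vel <- compute_velocity(cyc, geom, ivt_params())
  inner <- !is.na(vel$velocity)
  expect_true(all(vel$velocity[inner] == 0))
  labels <- classify_ivt(vel, ivt_params())
  expect_true(all(labels[inner] == "fixation"))
  expect_true(all(labels[!inner] == "missing"))
})

test_that("classifier threshold is inclusive at 30 deg/s", {
  vel <- data.frame(t = c(0, 4, 8), velocity = c(30, 29.999999, NA))
  expect_equal(classify_ivt(vel, ivt_params()),
               c("saccade", "fixation", "missing"))
})

test_that("peak of the windowed velocity trace tracks a 10-degree saccade", {
  vp <- main_sequence(10)
  wf <- saccade_waveform(10, vp, onset_ms = 200, rate_hz = 250)
  t <- seq(0, 800, by = 4)
  pos <- rep(0, length(t))
  during <- t >= 200 & t <= max(wf$t_ms)
  pos[during] <- approx(wf$t_ms, wf$position_deg, t[during])$y
  pos[t > max(wf$t_ms)] <- 10
  cyc <- data.frame(t = t, x = ctr[["x"]] + degrees_to_pixels(pos, geom),
                    y = ctr[["y"]], source = "both")
  vel <- compute_velocity(cyc, geom, ivt_params())
  expect_lt(abs(max(vel$velocity, na.rm = TRUE) - vp) / vp, 0.10)
})

test_that("fixation merging honours both the interval and angle criteria", {
  p <- ivt_params()
  near <- ctr[["x"]] + degrees_to_pixels(0.3, geom)
  far <- ctr[["x"]] + degrees_to_pixels(0.6, geom)
  two_fix <- function(gap_ms, x2) make_events(
    make_event("fixation", 0, 100, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 25),
    make_event("gap", 100, 100 + gap_ms),
    make_event("fixation", 100 + gap_ms, 300 + gap_ms, centroid_x = x2,
               centroid_y = ctr[["y"]], n_samples = 50))

  merged <- merge_fixations(two_fix(50, near), p, geom)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$kind, "fixation")
  expect_equal(merged$t_start, 0)
  expect_equal(merged$t_end, 350)
  # duration-weighted centroid: 100 ms at centre, 200 ms at 0.3 deg
  expect_equal(merged$centroid_x,
               (ctr[["x"]] * 100 + near * 200) / 300)

  expect_equal(nrow(merge_fixations(two_fix(80, near), p, geom)), 3)
  expect_equal(nrow(merge_fixations(two_fix(50, far), p, geom)), 3)
})

test_that("merging is idempotent and never bridges a blink", {
  p <- ivt_params()
  evs <- make_events(
    make_event("fixation", 0, 100, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 25),
    make_event("blink", 100, 160),
    make_event("fixation", 160, 300, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 35))
  once <- merge_fixations(evs, p, geom)
  expect_equal(nrow(once), 3)  # blink blocks the merge
  evs2 <- make_events(
    make_event("fixation", 0, 100, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 25),
    make_event("gap", 100, 130),
    make_event("fixation", 130, 300, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 42),
    make_event("gap", 300, 330),
    make_event("fixation", 330, 500, centroid_x = ctr[["x"]],
               centroid_y = ctr[["y"]], n_samples = 42))
  m1 <- merge_fixations(evs2, p, geom)
  expect_equal(nrow(m1), 1)
  expect_identical(merge_fixations(m1, p, geom), m1)
  # total fixation duration never decreases
  fix_dur <- function(e) sum((e$t_end - e$t_start)[e$kind == "fixation"])
  expect_gte(fix_dur(m1), fix_dur(evs2))
})

test_that("minimum fixation duration is applied inclusively", {
  evs <- make_events(
    make_event("fixation", 0, 55, centroid_x = 1, centroid_y = 1),
    make_event("fixation", 100, 160, centroid_x = 1, centroid_y = 1),
    make_event("fixation", 200, 600, centroid_x = 1, centroid_y = 1))
  out <- drop_short_fixations(evs, ivt_params())
  expect_equal(out$kind, c("gap", "fixation", "fixation"))
})

test_that("blinks require both eyes invalid within duration bounds", {
  n <- 200
  t <- (seq_len(n) - 1) * 4
  lval <- rval <- rep(0, n)
  lval[51:80] <- 4; rval[51:80] <- 4      # 120 ms: a blink
  lval[101:105] <- 4; rval[101:105] <- 4  # 20 ms: too short
  lval[151:180] <- 4                      # left-only: not a blink
  rec <- make_recording(t, rep(960, n), rep(540, n), lval = lval,
                        rval = rval)
  blinks <- detect_blinks(rec)
  expect_equal(nrow(blinks), 1)
  expect_equal(blinks$t_start, t[51])
  expect_equal(blinks$t_end, t[81])
})

test_that("run-length assembly orders events and lets blinks win", {
  t <- seq(0, 116, by = 4)
  cyc <- data.frame(t = t, x = seq(100, 390, by = 10), y = 540,
                    source = "both")
  labels <- c(rep("fixation", 10), rep("saccade", 10), rep("fixation", 10))
  ev <- extract_saccades(labels, cyc)
  expect_equal(ev$kind, c("fixation", "saccade", "fixation"))
  expect_equal(ev$t_start, c(0, 40, 80))
  expect_equal(ev$t_end, c(40, 80, 120))
  expect_equal(ev$x_start[2], cyc$x[11])
  expect_equal(ev$x_end[2], cyc$x[20])

  blink <- data.frame(kind = "blink", t_start = 60, t_end = 120)
  ev2 <- extract_saccades(labels, cyc, blink)
  expect_equal(ev2$kind, c("fixation", "saccade", "blink"))
  expect_equal(ev2$t_end[2], 60)  # saccade run truncated by the blink
})

test_that("the full chain labels a session exhaustively and disjointly", {
  ses <- simulate_session(stimulus_protocol("horizontal",
                                            amplitudes_deg = c(-10, 10, 18),
                                            reps_per_amplitude = 2),
                          simulation_params(), seed = 11)
  det <- detect_events(ses$recording)
  ev <- det$events
  expect_true(all(diff(ev$t_start) > 0))
  expect_equal(ev$t_start[-1], ev$t_end[-nrow(ev)])  # contiguous tiling
  expect_equal(ev$t_start[1], ses$recording$samples$t[1])
  expect_equal(ev$t_end[nrow(ev)],
               max(ses$recording$samples$t) + 4)
  expect_true(all(ev$t_end > ev$t_start))
  expect_true(all(ev$kind %in% c("fixation", "saccade", "blink", "gap")))
})

test_that("noise-free sessions recover the exact simulated saccade count", {
  protocol <- stimulus_protocol("horizontal", amplitudes_deg = c(-10, 10, 18),
                                reps_per_amplitude = 2)
  for (s in 1:3) {
    ses <- simulate_session(protocol, quiet_params(noise_sd_deg = 0),
                            seed = s)
    det <- detect_events(ses$recording)
    expect_equal(sum(det$events$kind == "saccade"),
                 nrow(ses$truth$saccades))
  }
})

test_that("saccade onsets and offsets land within 8 ms of ground truth", {
  protocol <- stimulus_protocol("horizontal", amplitudes_deg = c(-10, 10, 18),
                                reps_per_amplitude = 3)
  hits <- 0; total <- 0
  for (s in 1:4) {
    ses <- simulate_session(protocol, quiet_params(noise_sd_deg = 0.15),
                            seed = 100 + s)
    det <- detect_events(ses$recording)
    sac <- det$events[det$events$kind == "saccade", ]
    tr <- ses$truth$saccades
    for (i in seq_len(nrow(tr))) {
      j <- which.min(abs(sac$t_start - tr$onset_ms[i]))
      total <- total + 1
      if (abs(sac$t_start[j] - tr$onset_ms[i]) <= 8 &&
          abs(sac$t_end[j] - tr$offset_ms[i]) <= 8) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("fixational noise below 0.1 degrees keeps median velocity subthreshold", {
  p <- ivt_params()
  ok <- 0
  for (s in 1:20) {
    rec <- withr::with_seed(s, {
      t <- seq(0, 1996, by = 4)
      noise <- degrees_to_pixels(0.1, geom)
      make_recording(t, 960 + rnorm(length(t), 0, noise),
                     540 + rnorm(length(t), 0, noise))
    })
    vel <- compute_velocity(average_eyes(rec), geom, p)
    if (stats::median(vel$velocity, na.rm = TRUE) <
        p$velocity_threshold_deg_s) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})
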