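# Simulation settings used for recovery tests: deterministic response path
# (no blinks, no anticipatory saccades, no tracking loss), noise as given.
quiet_params <- function(noise_sd_deg = 0.15, ...) {
  simulation_params(noise_sd_deg = noise_sd_deg, blink_rate_per_min = 0,
                    p_anticipatory = 0, data_loss_rate = 0, ...)
}

# Independent permutation enumerator (list-of-vectors, insertion recursion);
# deliberately separate from the package's permutation machinery.
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumerate_perms(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = k)
  }
  out
}

# Brute-force two-sided Spearman permutation p-value.
spearman_p_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perm_rho <- vapply(enumerate_perms(length(y)),
                     function(idx) stats::cor(rx, ry[idx]), numeric(1))
  mean(abs(perm_rho) >= abs(rho) - 1e-9)
}

# Closed-form Pearson r from raw sums.
pearson_closed_form <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Binocular recording with both eyes at the same (x, y) path.
make_recording <- function(t, x, y, lval = 0, rval = 0,
                           geometry = screen_geometry(),
                           nominal_rate_hz = 250) {
  n <- length(t)
  lval <- rep_len(lval, n); rval <- rep_len(rval, n)
  lx <- ifelse(lval == 0, x, NA_real_)
  rx <- ifelse(rval == 0, x, NA_real_)
  ly <- ifelse(lval == 0, y, NA_real_)
  ry <- ifelse(rval == 0, y, NA_real_)
  gaze_recording(data.frame(t = t, lx = lx, ly = ly, lval = lval,
                            rx = rx, ry = ry, rval = rval),
                 nominal_rate_hz = nominal_rate_hz, geometry = geometry)
}

# One-row event constructor for hand-built event streams.
make_event <- function(kind, t_start, t_end, x_start = NA, y_start = NA,
                       x_end = NA, y_end = NA, centroid_x = NA,
                       centroid_y = NA, n_samples = NA) {
  data.frame(kind = kind, t_start = t_start, t_end = t_end,
             x_start = as.numeric(x_start), y_start = as.numeric(y_start),
             x_end = as.numeric(x_end), y_end = as.numeric(y_end),
             centroid_x = as.numeric(centroid_x),
             centroid_y = as.numeric(centroid_y),
             n_samples = as.integer(n_samples), stringsAsFactors = FALSE)
}

make_events <- function(...) do.call(rbind, list(...))

# Minimal detection object for trial-validation scenarios.
fake_detection <- function(events, samples, velocity = NULL) {
  if (is.null(velocity)) {
    velocity <- data.frame(t = samples$t,
                           velocity = rep(0, nrow(samples)))
  }
  structure(list(events = events, samples = samples, velocity = velocity,
                 blinks = events[events$kind == "blink", , drop = FALSE],
                 geometry = screen_geometry()),
            class = "vgs_events")
}

# Shared simulated recovery runs (computed once per noise setting per test
# run; several acceptance checks consume the same study conditions).
.recovery_cache <- new.env(parent = emptyenv())
recovery_runs <- function(noise_sd_deg, n_seeds = 20) {
  key <- sprintf("noise%.3f_n%d", noise_sd_deg, n_seeds)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  protocol <- stimulus_protocol("horizontal")
  runs <- lapply(seq_len(n_seeds), function(s) {
    ses <- simulate_session(protocol, quiet_params(noise_sd_deg), seed = s)
    det <- detect_events(ses$recording)
    trials <- analyze_trials(det, ses$schedule, subject_id = "sim")
    list(session = ses, detection = det, trials = trials)
  })
  .recovery_cache[[key]] <- runs
  runs
}
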