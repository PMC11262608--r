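#' Synthetic clinical cohort specification
#'
#' Describes a cohort of Parkinson's disease subjects for the covariate
#' simulator: demographics (age, sex, Hoehn & Yahr stage, disease
#' duration), neuropsychological scores (MMSE, CANTAB PRM/SWM) with
#' controllable missingness, and effect coefficients linking covariates to
#' per-subject oculomotor means.  All effect coefficients default to zero,
#' in which case covariates and metrics are exchangeable (the null
#' cohort).  The demographic defaults mirror a reference clinical PD
#' cohort of 62 patients (37 male / 25 female, age 60.35 +/- 8.98 years,
#' HY stages 1-4 with mode 2, 42 MMSE and 22 CANTAB evaluations).
#'
#' @param n_subjects Number of subjects.
#' @param age_mean,age_sd,age_range Age distribution (years; truncated
#'   normal).
#' @param n_male Number of male subjects (the rest are female).
#' @param hy_stage_levels,hy_stage_probs Hoehn & Yahr stages and their
#'   probabilities.
#' @param disease_duration_mean,disease_duration_sd Disease duration
#'   (years; truncated at 0.5).
#' @param mmse_mean,mmse_sd MMSE distribution (score 0-30).
#' @param n_mmse,n_cantab Number of subjects with MMSE / CANTAB scores
#'   (the rest are missing).
#' @param cantab_nested If `TRUE` the CANTAB subjects are a subset of the
#'   MMSE subjects.
#' @param cantab_means,cantab_sds Named CANTAB score distributions
#'   (`prmcd`, `prmmcld`, `prmpci`, `prmmcli`, `swm_te`).
#' @param baseline_latency_ms,baseline_gain,baseline_blink_rate Baseline
#'   oculomotor means.
#' @param latency_age_slope Latency change per year of age (ms/yr).
#' @param gain_age_slope Gain change per year of age (1/yr).
#' @param blink_swm_slope Blink-rate change per SWM total error
#'   (min^-1 per error).
#' @param latency_resid_sd,gain_resid_sd,blink_resid_sd Residual
#'   between-subject SDs.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 62,
                        age_mean = 60.35, age_sd = 8.98,
                        age_range = c(35, 85),
                        n_male = 37,
                        hy_stage_levels = c(1, 1.5, 2, 2.5, 3, 4),
                        hy_stage_probs = c(3, 12, 29, 6, 6, 6) / 62,
                        disease_duration_mean = 6,
                        disease_duration_sd = 3,
                        mmse_mean = 28.0, mmse_sd = 2.61,
                        n_mmse = 42, n_cantab = 22, cantab_nested = TRUE,
                        cantab_means = c(prmcd = 0.77, prmmcld = 2631.86,
                                         prmpci = 8.36, prmmcli = 2529.89,
                                         swm_te = 23.23),
                        cantab_sds = c(prmcd = 0.12, prmmcld = 560.96,
                                       prmpci = 24.33, prmmcli = 652.80,
                                       swm_te = 8.33),
                        baseline_latency_ms = 230,
                        baseline_gain = 0.9,
                        baseline_blink_rate = 12,
                        latency_age_slope = 0,
                        gain_age_slope = 0,
                        blink_swm_slope = 0,
                        latency_resid_sd = 20,
                        gain_resid_sd = 0.05,
                        blink_resid_sd = 3) {
  sds <- c(age_sd, disease_duration_sd, mmse_sd, cantab_sds,
           latency_resid_sd, gain_resid_sd, blink_resid_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all SDs must be non-negative")
  }
  stopifnot(n_subjects >= 1, n_male >= 0, n_male <= n_subjects,
            n_mmse <= n_subjects, n_cantab <= n_subjects,
            length(hy_stage_levels) == length(hy_stage_probs),
            all(hy_stage_probs >= 0))
  structure(list(n_subjects = n_subjects, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range, n_male = n_male,
                 hy_stage_levels = hy_stage_levels,
                 hy_stage_probs = hy_stage_probs,
                 disease_duration_mean = disease_duration_mean,
                 disease_duration_sd = disease_duration_sd,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 n_mmse = n_mmse, n_cantab = n_cantab,
                 cantab_nested = cantab_nested,
                 cantab_means = cantab_means, cantab_sds = cantab_sds,
                 baseline_latency_ms = baseline_latency_ms,
                 baseline_gain = baseline_gain,
                 baseline_blink_rate = baseline_blink_rate,
                 latency_age_slope = latency_age_slope,
                 gain_age_slope = gain_age_slope,
                 blink_swm_slope = blink_swm_slope,
                 latency_resid_sd = latency_resid_sd,
                 gain_resid_sd = gain_resid_sd,
                 blink_resid_sd = blink_resid_sd),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a clinical cohort with linked oculomotor metrics
#'
#' Draws per-subject covariates from the cohort specification and
#' per-subject oculomotor means from the linear covariate model
#' (`baseline + slope x centred covariate + residual`).  By default the
#' subject-level aggregated metrics are generated directly from that model
#' (`full_sessions = FALSE`), which is what the statistical-calibration
#' machinery consumes; with `full_sessions = TRUE` a gap-paradigm session
#' is additionally simulated for each subject with its simulation
#' parameters shifted to match the subject's means, for end-to-end runs
#' through the event-detection pipeline.
#'
#' Class structure of the metric table: latency carries fixed
#' eccentricity-class offsets (far +25 ms, up +15 ms, down +10 ms relative
#' to near), amplitude is `gain x eccentricity`, peak velocity follows the
#' main sequence, duration the raised-cosine identity `2A/Vp`, and each
#' cell adds independent trial-averaging noise.
#'
#' @param spec A [cohort_spec()].
#' @param params [simulation_params()] (kinematic model for derived
#'   metrics and for full sessions).
#' @param seed Integer seed.
#' @param full_sessions Simulate full gaze sessions per subject (slow;
#'   intended for small cohorts).
#' @param protocol Protocol used when `full_sessions = TRUE`.
#' @param geometry [screen_geometry()].
#' @return A list with `clinical` (the covariate table), `records` (the
#'   covariate table joined with wide subject-level metrics, input for
#'   [correlation_grid()]), and (if requested) `sessions`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            params = simulation_params(),
                            seed = 1, full_sessions = FALSE,
                            protocol = stimulus_protocol("horizontal"),
                            geometry = screen_geometry()) {
  with_seed(seed, {
    n <- spec$n_subjects
    id <- sprintf("S%03d", seq_len(n))
    sex <- sample(c(rep("male", spec$n_male),
                    rep("female", n - spec$n_male)))
    age <- rnorm_trunc(n, spec$age_mean, spec$age_sd,
                       spec$age_range[1], spec$age_range[2])
    hy <- sample(spec$hy_stage_levels, n, replace = TRUE,
                 prob = spec$hy_stage_probs)
    duration <- rnorm_trunc(n, spec$disease_duration_mean,
                            spec$disease_duration_sd, 0.5, Inf)
    mmse_lat <- round(rnorm_trunc(n, spec$mmse_mean, spec$mmse_sd, 0, 30))
    cm <- spec$cantab_means; cs <- spec$cantab_sds
    swm_lat <- round(rnorm_trunc(n, cm[["swm_te"]], cs[["swm_te"]], 0, Inf))
    prmcd_lat <- rnorm_trunc(n, cm[["prmcd"]], cs[["prmcd"]], 0, 1)
    prmmcld_lat <- rnorm_trunc(n, cm[["prmmcld"]], cs[["prmmcld"]], 200, Inf)
    prmpci_lat <- stats::rnorm(n, cm[["prmpci"]], cs[["prmpci"]])
    prmmcli_lat <- rnorm_trunc(n, cm[["prmmcli"]], cs[["prmmcli"]], 200, Inf)

    has_mmse <- seq_len(n) %in% sample(n, spec$n_mmse)
    has_cantab <- if (spec$cantab_nested && spec$n_cantab <= spec$n_mmse) {
      seq_len(n) %in% sample(which(has_mmse), spec$n_cantab)
    } else {
      seq_len(n) %in% sample(n, spec$n_cantab)
    }
    mask <- function(x, keep) ifelse(keep, x, NA)

    clinical <- data.frame(
      subject_id = id, age = age, sex = sex, hy_stage = hy,
      disease_duration_yr = duration,
      mmse = mask(mmse_lat, has_mmse),
      cantab_prmcd = mask(prmcd_lat, has_cantab),
      cantab_prmmcld = mask(prmmcld_lat, has_cantab),
      cantab_prmpci = mask(prmpci_lat, has_cantab),
      cantab_prmmcli = mask(prmmcli_lat, has_cantab),
      cantab_swm_te = mask(swm_lat, has_cantab),
      stringsAsFactors = FALSE)

    # per-subject oculomotor means from the covariate model (latent scores
    # drive the metrics even where the observed score is masked)
    lat_subj <- spec$baseline_latency_ms +
      spec$latency_age_slope * (age - spec$age_mean) +
      stats::rnorm(n, 0, spec$latency_resid_sd)
    gain_subj <- pmin(pmax(
      spec$baseline_gain + spec$gain_age_slope * (age - spec$age_mean) +
        stats::rnorm(n, 0, spec$gain_resid_sd), 0.2), 1.4)
    blink_subj <- pmax(
      spec$baseline_blink_rate +
        spec$blink_swm_slope * (swm_lat - cm[["swm_te"]]) +
        stats::rnorm(n, 0, spec$blink_resid_sd), 0)

    classes <- data.frame(
      class = c("near", "far", "up", "down"),
      ecc = c(10, 18, 8, 8),
      lat_offset = c(0, 25, 15, 10))
    metrics <- data.frame(subject_id = id, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(classes))) {
      cl <- classes$class[k]
      lat <- lat_subj + classes$lat_offset[k] + stats::rnorm(n, 0, 5)
      g <- pmin(pmax(gain_subj + stats::rnorm(n, 0, 0.02), 0.15), 1.45)
      amp <- g * classes$ecc[k]
      vp <- main_sequence(amp, params) * (1 + stats::rnorm(n, 0, 0.03))
      dur <- 2 * amp / vp * 1000
      metrics[[paste0("latency_", cl)]] <- lat
      metrics[[paste0("amplitude_", cl)]] <- amp
      metrics[[paste0("gain_", cl)]] <- g
      metrics[[paste0("peak_velocity_", cl)]] <- vp
      metrics[[paste0("mean_velocity_", cl)]] <- vp / 2
      metrics[[paste0("duration_", cl)]] <- dur
    }
    metrics$blink_rate_horizontal <- blink_subj + stats::rnorm(n, 0, 1)
    metrics$blink_rate_vertical <- blink_subj + stats::rnorm(n, 0, 1)
    metrics$percent_valid_horizontal <-
      100 * pmin(pmax(stats::rnorm(n, 0.85, 0.08), 0.3), 1)
    metrics$percent_valid_vertical <-
      100 * pmin(pmax(stats::rnorm(n, 0.8, 0.1), 0.3), 1)

    records <- merge(clinical, metrics, by = "subject_id", sort = TRUE)

    sessions <- NULL
    if (full_sessions) {
      sessions <- lapply(seq_len(n), function(i) {
        p <- params
        # match the subject's means: gamma mean = shift + shape * scale
        p$latency_shift <- max(lat_subj[i] -
                                 p$latency_shape * p$latency_scale, 0)
        p$gain_mean <- gain_subj[i]
        p$blink_rate_per_min <- blink_subj[i]
        simulate_session(protocol, p, geometry, subject_id = id[i],
                         seed = substream_seed(seed, i))
      })
      names(sessions) <- id
    }
    list(clinical = clinical, records = records, sessions = sessions)
  })
}

#' Reference Parkinson's disease cohort demographics
#'
#' The demographic composition of a reference clinical PD cohort of 62
#' patients used in the package's worked examples: 37 male and 25 female
#' subjects with Hoehn & Yahr stages distributed as male 1.5:7, 2:20,
#' 2.5:4, 3:4, 4:2 and female 1:3, 1.5:5, 2:9, 2.5:2, 3:2, 4:4.  Only sex
#' and stage are tabulated; per-subject ages are not part of the
#' composition and are `NA`.
#'
#' @return A data frame with columns `subject_id`, `sex`, `hy_stage`,
#'   `age`.
#' @export
reference_cohort <- function() {
  male_hy <- rep(c(1.5, 2, 2.5, 3, 4), times = c(7, 20, 4, 4, 2))
  female_hy <- rep(c(1, 1.5, 2, 2.5, 3, 4), times = c(3, 5, 9, 2, 2, 4))
  data.frame(
    subject_id = sprintf("P%02d", seq_len(length(male_hy) + length(female_hy))),
    sex = c(rep("male", length(male_hy)), rep("female", length(female_hy))),
    hy_stage = c(male_hy, female_hy),
    age = NA_real_,
    stringsAsFactors = FALSE)
}
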