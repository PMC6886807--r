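#' Configuration for the synthetic CGM generator
#'
#' The generator emulates the statistical structure the forecasting
#' pipeline assumes — 5-minute sampling, the 40–400 mg/dl sensor range,
#' trace gaps of varying duration, and the heavy normoglycemic imbalance
#' of real T1D data — without attempting physiological fidelity.
#' Glucose follows a discrete mean-reverting (Ornstein–Uhlenbeck style)
#' process plus gamma-shaped meal excursions at Poisson event times;
#' some meal responses are followed by an insulin overcorrection dip
#' into hypoglycemia. Defaults were calibrated once against the range
#' occupancy of the public eight-week six-patient CGM benchmark (about
#' 3.4% hypoglycemic and 34% hyperglycemic readings) and then frozen.
#'
#' @param days days of data per patient (default 56, about eight weeks).
#' @param interval_mins sampling interval in minutes (default 5).
#' @param baseline_mean mean-reversion level in mg/dl, in (70, 180).
#' @param reversion_rate mean-reversion rate per minute.
#' @param noise_sd Gaussian noise scale in mg/dl per sqrt(minute).
#' @param meal_rate meal events per day (Poisson).
#' @param meal_amplitude range of meal excursion peaks in mg/dl.
#' @param meal_peak_mins time to excursion peak in minutes.
#' @param meal_shape gamma-kernel shape of the excursion.
#' @param overcorrection_prob probability that a meal response is
#'   followed by an undershoot below the hypoglycemic threshold.
#' @param overcorrection_depth range of dip depths in mg/dl.
#' @param overcorrection_delay_mins delay from meal to dip center.
#' @param overcorrection_sd_mins Gaussian width of the dip.
#' @param gap_rate sensor gaps per day (Poisson); gap durations are
#'   log-uniform over `gap_duration_mins` and the readings under a gap
#'   are deleted, never imputed.
#' @param gap_duration_mins gap duration range in minutes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(days = 56, interval_mins = 5, baseline_mean = 160,
                       reversion_rate = 0.01, noise_sd = 1.0,
                       meal_rate = 4, meal_amplitude = c(55, 175),
                       meal_peak_mins = 60, meal_shape = 2,
                       overcorrection_prob = 0.40,
                       overcorrection_depth = c(105, 140),
                       overcorrection_delay_mins = 240,
                       overcorrection_sd_mins = 35,
                       gap_rate = 1, gap_duration_mins = c(15, 480)) {
  stopifnot(
    days >= 1, interval_mins > 0,
    baseline_mean > 70, baseline_mean < 180,
    reversion_rate >= 0, noise_sd >= 0, meal_rate >= 0,
    length(meal_amplitude) == 2, meal_amplitude[1] <= meal_amplitude[2],
    overcorrection_prob >= 0, overcorrection_prob <= 1,
    gap_rate >= 0, length(gap_duration_mins) == 2,
    gap_duration_mins[1] > 0,
    gap_duration_mins[1] <= gap_duration_mins[2]
  )
  structure(
    list(
      days = days, interval_mins = interval_mins,
      baseline_mean = baseline_mean, reversion_rate = reversion_rate,
      noise_sd = noise_sd, meal_rate = meal_rate,
      meal_amplitude = meal_amplitude, meal_peak_mins = meal_peak_mins,
      meal_shape = meal_shape,
      overcorrection_prob = overcorrection_prob,
      overcorrection_depth = overcorrection_depth,
      overcorrection_delay_mins = overcorrection_delay_mins,
      overcorrection_sd_mins = overcorrection_sd_mins,
      gap_rate = gap_rate, gap_duration_mins = gap_duration_mins
    ),
    class = "sim_config"
  )
}

#' Simulate one patient's CGM record with a chronological split
#'
#' Generates a gap-punctuated CGM trace under `config` (see
#' [sim_config()]), clips it to the sensor range, rounds readings to
#' 0.1 mg/dl, and splits it 75/25 chronologically into training and test
#' traces.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical patients.
#' @param patient_id identifier for the generated traces.
#' @param test_fraction fraction of readings held out for testing.
#' @return A [patient_dataset()].
#' @export
simulate_patient <- function(config = sim_config(), seed = 1,
                             patient_id = "sim-01",
                             test_fraction = 0.25) {
  stopifnot(inherits(config, "sim_config"))
  trace <- simulate_trace(config, seed, patient_id)
  split_chronological(trace, test_fraction)
}

simulate_trace <- function(config, seed, patient_id) {
  cf <- config
  dt <- cf$interval_mins
  n <- as.integer(cf$days * 24 * 60 / dt)
  total_mins <- n * dt
  withr::with_seed(seed, {
    tt <- (seq_len(n) - 1) * dt
    # mean-reverting base process, started at its fixed point
    g <- numeric(n)
    g[1] <- cf$baseline_mean
    noise <- stats::rnorm(n) * cf$noise_sd * sqrt(dt)
    for (i in seq_len(n - 1)) {
      g[i + 1] <- g[i] + cf$reversion_rate * (cf$baseline_mean - g[i]) * dt +
        noise[i + 1]
    }
    # meal excursions: gamma-shaped kernels at Poisson event times
    n_meals <- stats::rpois(1, cf$meal_rate * cf$days)
    if (n_meals > 0) {
      meal_t <- sort(stats::runif(n_meals, 0, total_mins))
      amp <- stats::runif(n_meals, cf$meal_amplitude[1],
                          cf$meal_amplitude[2])
      overc <- stats::runif(n_meals) < cf$overcorrection_prob
      depth <- stats::runif(n_meals, cf$overcorrection_depth[1],
                            cf$overcorrection_depth[2])
      for (j in seq_len(n_meals)) {
        tau <- tt - meal_t[j]
        idx <- tau > 0 & tau < 12 * cf$meal_peak_mins
        if (any(idx)) {
          kern <- (tau[idx] / cf$meal_peak_mins)^cf$meal_shape *
            exp(cf$meal_shape * (1 - tau[idx] / cf$meal_peak_mins))
          g[idx] <- g[idx] + amp[j] * kern
        }
        if (overc[j]) {
          z <- (tt - meal_t[j] - cf$overcorrection_delay_mins) /
            cf$overcorrection_sd_mins
          dip <- exp(-0.5 * z^2)
          keep <- dip > 1e-4
          g[keep] <- g[keep] - depth[j] * dip[keep]
        }
      }
    }
    g <- round(pmin(400, pmax(40, g)), 1)
    # sensor gaps: delete readings under log-uniformly long outages
    keep <- rep(TRUE, n)
    n_gaps <- stats::rpois(1, cf$gap_rate * cf$days)
    if (n_gaps > 0) {
      gs <- stats::runif(n_gaps, 0, total_mins)
      gd <- exp(stats::runif(n_gaps, log(cf$gap_duration_mins[1]),
                             log(cf$gap_duration_mins[2])))
      for (j in seq_len(n_gaps)) {
        keep[tt >= gs[j] & tt < gs[j] + gd[j]] <- FALSE
      }
    }
    ts <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") + tt * 60
    cgm_trace(ts[keep], g[keep], patient_id = patient_id)
  })
}

#' Simulate a cohort of independent patients
#'
#' @param n number of patients (default 6, the size of the benchmark
#'   cohort the generator stands in for).
#' @param config a [sim_config()] shared by all patients.
#' @param seed master seed; per-patient sub-seeds are drawn from it, so
#'   patients are mutually independent and the whole cohort is
#'   reproducible.
#' @return A list of class `sim_cohort` with `patients` (a list of
#'   [patient_dataset()]s) and `config`.
#' @export
simulate_cohort <- function(n = 6, config = sim_config(), seed = 1) {
  stopifnot(n >= 1)
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, n))
  patients <- lapply(seq_len(n), function(i) {
    simulate_patient(config, seeds[i], sprintf("sim-%02d", i))
  })
  structure(list(patients = patients, config = config),
            class = "sim_cohort")
}

#' Fraction of readings in each glycemic range
#'
#' @param trace a non-empty [cgm_trace()].
#' @param thresholds a [glycemic_thresholds()].
#' @return Named numeric vector `c(hypo=, norm=, hyper=)` summing to 1.
#' @export
range_occupancy <- function(trace, thresholds = glycemic_thresholds()) {
  stopifnot(inherits(trace, "cgm_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  g <- trace$glucose_mgdl
  c(
    hypo = mean(g < thresholds$hypo),
    norm = mean(g >= thresholds$hypo & g <= thresholds$hyper),
    hyper = mean(g > thresholds$hyper)
  )
}
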