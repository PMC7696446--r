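#' Parameters of the synthetic CGM patient model
#'
#' Defines one simulated inpatient for [simulate_trace()]. The generated
#' series is the sum of a basal level, a circadian sinusoid, double-
#' exponential meal excursions, an AR(1) physiological noise process and
#' white sensor noise, clipped to the sensor's recording range, with
#' geometric-length dropout runs removed to mimic signal loss.
#'
#' @param patient_id Patient identifier.
#' @param basal_level Baseline glucose in mg/dL (> 0).
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL.
#' @param meal_times Clock times of daily meals, in hours (e.g. `c(8, 12, 18)`).
#' @param meal_magnitude_mean Mean peak height of a meal excursion, mg/dL.
#' @param meal_magnitude_sd SD of per-meal peak heights, mg/dL.
#' @param meal_jitter_min Half-width of the uniform jitter applied to each
#'   meal time, minutes.
#' @param meal_rise_tau,meal_decay_tau Rise and decay time constants of the
#'   meal response, minutes (`0 < rise < decay`).
#' @param ar_coefficient AR(1) coefficient of the process noise, in `[0, 1)`.
#' @param process_noise_sd SD of AR(1) innovations, mg/dL.
#' @param sensor_noise_sd SD of white sensor noise, mg/dL.
#' @param dropout_rate Expected number of missing runs per day.
#' @param dropout_mean_len Mean length of a missing run, in grid steps.
#' @param sensor_floor,sensor_ceiling Recording range of the sensor, mg/dL.
#'   The permissive default is `c(40, 400)`; a stricter floor of 60 matches
#'   devices that do not record below 60.
#' @param seed Integer seed; identical parameters (including the seed) yield
#'   a bit-identical trace.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(patient_id = "S001",
                           basal_level = 170,
                           circadian_amplitude = 20,
                           meal_times = c(8, 12, 18),
                           meal_magnitude_mean = 60,
                           meal_magnitude_sd = 12,
                           meal_jitter_min = 30,
                           meal_rise_tau = 20,
                           meal_decay_tau = 60,
                           ar_coefficient = 0.8,
                           process_noise_sd = 5,
                           sensor_noise_sd = 2,
                           dropout_rate = 0.5,
                           dropout_mean_len = 4,
                           sensor_floor = 40,
                           sensor_ceiling = 400,
                           seed = 1L) {
  p <- list(patient_id = as.character(patient_id),
            basal_level = basal_level,
            circadian_amplitude = circadian_amplitude,
            meal_times = as.numeric(meal_times),
            meal_magnitude_mean = meal_magnitude_mean,
            meal_magnitude_sd = meal_magnitude_sd,
            meal_jitter_min = meal_jitter_min,
            meal_rise_tau = meal_rise_tau,
            meal_decay_tau = meal_decay_tau,
            ar_coefficient = ar_coefficient,
            process_noise_sd = process_noise_sd,
            sensor_noise_sd = sensor_noise_sd,
            dropout_rate = dropout_rate,
            dropout_mean_len = dropout_mean_len,
            sensor_floor = sensor_floor,
            sensor_ceiling = sensor_ceiling,
            seed = as.integer(seed))
  validate_patient_params(p)
  structure(p, class = "patient_params")
}

validate_patient_params <- function(p) {
  if (p$basal_level <= 0) stop("`basal_level` must be > 0", call. = FALSE)
  if (p$meal_rise_tau <= 0 || p$meal_decay_tau <= 0) {
    stop("meal time constants must be > 0", call. = FALSE)
  }
  if (p$meal_rise_tau >= p$meal_decay_tau) {
    stop("`meal_rise_tau` must be smaller than `meal_decay_tau`", call. = FALSE)
  }
  if (p$ar_coefficient < 0 || p$ar_coefficient >= 1) {
    stop("`ar_coefficient` must lie in [0, 1)", call. = FALSE)
  }
  if (p$sensor_floor >= p$sensor_ceiling) {
    stop("`sensor_floor` must be below `sensor_ceiling`", call. = FALSE)
  }
  if (any(c(p$circadian_amplitude, p$meal_magnitude_mean, p$meal_magnitude_sd,
            p$meal_jitter_min, p$process_noise_sd, p$sensor_noise_sd,
            p$dropout_rate) < 0) || p$dropout_mean_len < 1) {
    stop("noise/meal/dropout parameters must be non-negative (dropout_mean_len >= 1)",
         call. = FALSE)
  }
  invisible(p)
}

# normalized double-exponential meal response, peak height exactly 1:
# r(s) = (exp(-s/decay) - exp(-s/rise)) / peak for s >= 0, else 0
meal_response <- function(s, rise_tau, decay_tau) {
  s_star <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  peak <- exp(-s_star / decay_tau) - exp(-s_star / rise_tau)
  out <- numeric(length(s))
  pos <- s >= 0
  out[pos] <- (exp(-s[pos] / decay_tau) - exp(-s[pos] / rise_tau)) / peak
  out
}

#' Simulate one patient's CGM trace
#'
#' Generates `round(days * 1440 / interval)` scheduled readings as
#' basal + circadian sinusoid + meal responses + AR(1) process noise +
#' white sensor noise, clips to the sensor range, and removes dropout runs.
#' The realized meal schedule (times in minutes from start, peak heights)
#' is attached as attribute `"meal_schedule"` for auditing.
#'
#' @param params A [patient_params()] object.
#' @param days Trace length in days (> 0).
#' @param interval Sampling interval in minutes (default 5).
#' @param start_time `POSIXct` time of the first scheduled reading.
#' @return A [glucose_trace()]; deterministic given `params` (incl. its seed).
#' @export
simulate_trace <- function(params, days, interval = 5,
                           start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  if (!inherits(params, "patient_params")) {
    stop("`params` must be a `patient_params` object", call. = FALSE)
  }
  validate_patient_params(params)
  if (!is.numeric(days) || length(days) != 1L || days <= 0) {
    stop("`days` must be a single positive number", call. = FALSE)
  }
  n <- round(days * 1440 / interval)
  if (n < 1) stop("`days` too short for one reading", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(params$seed)

  t_min <- (seq_len(n) - 1L) * interval          # minutes from start
  tod <- (t_min / 60) %% 24                      # clock hours

  # circadian component, acrophase at 16:00
  circ <- params$circadian_amplitude * cos(2 * pi * (tod - 16) / 24)

  # meal schedule: every scheduled day, jittered times and random heights
  n_days <- ceiling(days)
  sched_t <- rep((seq_len(n_days) - 1L) * 1440, each = length(params$meal_times)) +
    rep(params$meal_times * 60, times = n_days)
  n_meals <- length(sched_t)
  meal_comp <- numeric(n)
  meal_t <- numeric(0)
  meal_mag <- numeric(0)
  if (n_meals) {
    jit <- if (params$meal_jitter_min > 0) {
      stats::runif(n_meals, -params$meal_jitter_min, params$meal_jitter_min)
    } else rep(0, n_meals)
    mag <- pmax(stats::rnorm(n_meals, params$meal_magnitude_mean,
                             params$meal_magnitude_sd), 0)
    meal_t <- sched_t + jit
    keep <- meal_t < max(t_min)
    meal_t <- meal_t[keep]
    meal_mag <- mag[keep]
    for (k in seq_along(meal_t)) {
      meal_comp <- meal_comp + meal_mag[k] *
        meal_response(t_min - meal_t[k], params$meal_rise_tau, params$meal_decay_tau)
    }
  }

  innov <- stats::rnorm(n, 0, params$process_noise_sd)
  ar <- if (params$ar_coefficient > 0) {
    as.numeric(stats::filter(innov, params$ar_coefficient, method = "recursive"))
  } else innov
  sensor <- stats::rnorm(n, 0, params$sensor_noise_sd)

  g <- params$basal_level + circ + meal_comp + ar + sensor
  g <- pmin(pmax(g, params$sensor_floor), params$sensor_ceiling)

  # dropout: Poisson number of runs, geometric run lengths (mean dropout_mean_len)
  present <- rep(TRUE, n)
  if (params$dropout_rate > 0) {
    n_runs <- stats::rpois(1, params$dropout_rate * days)
    if (n_runs > 0) {
      starts <- sample.int(n, n_runs, replace = TRUE)
      lens <- stats::rgeom(n_runs, 1 / params$dropout_mean_len) + 1L
      for (k in seq_len(n_runs)) {
        present[starts[k]:min(n, starts[k] + lens[k] - 1L)] <- FALSE
      }
      if (!any(present)) present[1] <- TRUE   # never emit a fully-empty trace
    }
  }

  trace <- glucose_trace(params$patient_id, g[present],
                         index = which(present) - 1L,
                         interval = interval, start_time = start_time)
  attr(trace, "meal_schedule") <- tibble::tibble(time_min = meal_t,
                                                 magnitude = meal_mag)
  trace
}

#' Default cohort parameter distributions
#'
#' Sampling distributions used by [simulate_cohort()] for each patient-level
#' parameter. Each entry is either a constant or a function of `n` returning
#' `n` draws. The defaults emulate a heterogeneous type-2 inpatient cohort:
#' 2.6-7.4 day stays, per-patient mean levels spread roughly 130-280 mg/dL
#' around a pooled mean near 193 mg/dL, three jittered meals a day, and
#' patient-specific volatility and sensor-dropout behaviour.
#'
#' @return Named list of constants and sampling functions.
#' @export
cohort_param_defaults <- function() {
  list(
    days = function(n) stats::runif(n, 2.6, 7.4),
    basal_level = function(n) pmin(pmax(stats::rnorm(n, 178, 30), 110), 270),
    circadian_amplitude = function(n) stats::runif(n, 10, 30),
    meal_times = list(c(8, 12, 18)),
    meal_magnitude_mean = function(n) stats::runif(n, 40, 90),
    meal_magnitude_sd = function(n) stats::runif(n, 8, 18),
    meal_jitter_min = 30,
    meal_rise_tau = function(n) stats::runif(n, 15, 25),
    meal_decay_tau = function(n) stats::runif(n, 50, 80),
    ar_coefficient = function(n) stats::runif(n, 0.6, 0.95),
    process_noise_sd = function(n) stats::runif(n, 2, 8),
    sensor_noise_sd = function(n) stats::runif(n, 1, 4),
    dropout_rate = function(n) stats::runif(n, 0.2, 1),
    dropout_mean_len = function(n) stats::runif(n, 2, 6),
    sensor_floor = 40,
    sensor_ceiling = 400
  )
}

#' Simulate a cohort of CGM traces
#'
#' Draws independent [patient_params()] for `n_patients` patients from the
#' given distributions and simulates one trace per patient. Reproducible
#' from `seed`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param param_distributions Named list overriding entries of
#'   [cohort_param_defaults()]; unknown names are rejected. Each entry is a
#'   constant (recycled) or a `function(n)` returning `n` draws; `meal_times`
#'   may be a list of per-patient numeric vectors.
#' @param seed Integer seed for the cohort draw.
#' @return List of [glucose_trace()] objects, with the drawn parameter sets
#'   attached as attribute `"params"`.
#' @export
simulate_cohort <- function(n_patients = 20, param_distributions = list(),
                            seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be >= 1", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  defaults <- cohort_param_defaults()
  unknown <- setdiff(names(param_distributions), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter distribution key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dists <- utils::modifyList(defaults, param_distributions)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  draw <- function(d) {
    if (is.function(d)) d(n_patients)
    else if (is.list(d)) rep(d, length.out = n_patients)
    else rep(d, length.out = n_patients)
  }
  drawn <- lapply(dists, draw)
  patient_seeds <- sample.int(.Machine$integer.max, n_patients)

  pick <- function(x, i) if (is.list(x)) x[[i]] else x[[i]]
  traces <- vector("list", n_patients)
  all_params <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    p <- patient_params(
      patient_id = sprintf("S%03d", i),
      basal_level = pick(drawn$basal_level, i),
      circadian_amplitude = pick(drawn$circadian_amplitude, i),
      meal_times = pick(drawn$meal_times, i),
      meal_magnitude_mean = pick(drawn$meal_magnitude_mean, i),
      meal_magnitude_sd = pick(drawn$meal_magnitude_sd, i),
      meal_jitter_min = pick(drawn$meal_jitter_min, i),
      meal_rise_tau = pick(drawn$meal_rise_tau, i),
      meal_decay_tau = pick(drawn$meal_decay_tau, i),
      ar_coefficient = pick(drawn$ar_coefficient, i),
      process_noise_sd = pick(drawn$process_noise_sd, i),
      sensor_noise_sd = pick(drawn$sensor_noise_sd, i),
      dropout_rate = pick(drawn$dropout_rate, i),
      dropout_mean_len = pick(drawn$dropout_mean_len, i),
      sensor_floor = pick(drawn$sensor_floor, i),
      sensor_ceiling = pick(drawn$sensor_ceiling, i),
      seed = patient_seeds[i]
    )
    all_params[[i]] <- p
    traces[[i]] <- simulate_trace(p, days = pick(drawn$days, i))
  }
  attr(traces, "params") <- all_params
  traces
}
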