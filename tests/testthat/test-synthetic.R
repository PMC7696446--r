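test_that("degenerate generator settings produce an exactly constant trace", {
  p <- patient_params(basal_level = 150, circadian_amplitude = 0,
                      meal_times = numeric(0), process_noise_sd = 0,
                      sensor_noise_sd = 0, dropout_rate = 0, seed = 1)
  tr <- simulate_trace(p, days = 1)
  expect_length(tr$glucose, 288)
  expect_true(all(tr$glucose == 150))
  expect_identical(tr$index, 0:287)
})

test_that("scheduled point counts follow the 5-minute cadence", {
  p <- patient_params(dropout_rate = 0, seed = 2)
  expect_length(simulate_trace(p, days = 7)$glucose, 2016)
  expect_length(simulate_trace(p, days = 1)$glucose, 288)
  expect_length(simulate_trace(p, days = 2.5)$glucose, 720)
})

test_that("single-meal peak matches dense evaluation of the response curve", {
  p <- patient_params(basal_level = 100, circadian_amplitude = 0,
                      meal_times = 6, meal_magnitude_mean = 80,
                      meal_magnitude_sd = 0, meal_jitter_min = 0,
                      meal_rise_tau = 20, meal_decay_tau = 60,
                      process_noise_sd = 0, sensor_noise_sd = 0,
                      dropout_rate = 0, seed = 3)
  tr <- simulate_trace(p, days = 1)
  sched <- attr(tr, "meal_schedule")
  expect_equal(nrow(sched), 1L)
  # oracle: evaluate the double-exponential response on the same grid
  t_min <- tr$index * tr$interval
  s <- t_min - sched$time_min[1]
  s_star <- log(60 / 20) * 20 * 60 / (60 - 20)
  peak <- exp(-s_star / 60) - exp(-s_star / 20)
  resp <- ifelse(s >= 0, (exp(-s / 60) - exp(-s / 20)) / peak, 0)
  oracle <- 100 + sched$magnitude[1] * resp
  expect_equal(tr$glucose, oracle, tolerance = 1e-12)
  # peak excursion stays below the nominal magnitude only by grid resolution
  expect_lt(abs(max(tr$glucose) - 100 - sched$magnitude[1] * max(resp)), 1e-9)
})

test_that("generation is a pure function of parameters and seed", {
  p <- patient_params(seed = 11)
  t1 <- simulate_trace(p, days = 3)
  t2 <- simulate_trace(p, days = 3)
  expect_identical(t1$index, t2$index)
  expect_identical(t1$glucose, t2$glucose)
  p2 <- patient_params(seed = 12)
  t3 <- simulate_trace(p2, days = 3)
  expect_false(identical(t1$glucose, t3$glucose))
})

test_that("all generated values respect the sensor recording range", {
  for (s in 1:5) {
    p <- patient_params(process_noise_sd = 40, sensor_noise_sd = 20,
                        sensor_floor = 60, sensor_ceiling = 400, seed = s)
    tr <- simulate_trace(p, days = 2)
    expect_true(all(tr$glucose >= 60 & tr$glucose <= 400))
  }
})

test_that("turning on a noise source increases trace variance in expectation", {
  base <- function(s, psd, ssd) {
    p <- patient_params(circadian_amplitude = 10, process_noise_sd = psd,
                        sensor_noise_sd = ssd, dropout_rate = 0, seed = s)
    var(simulate_trace(p, days = 2)$glucose)
  }
  seeds <- 1:20
  quiet <- vapply(seeds, base, numeric(1), psd = 0, ssd = 0)
  proc <- vapply(seeds, base, numeric(1), psd = 6, ssd = 0)
  sens <- vapply(seeds, base, numeric(1), psd = 0, ssd = 6)
  expect_gt(mean(proc), mean(quiet))
  expect_gt(mean(sens), mean(quiet))
})

test_that("invalid parameters and days are rejected", {
  expect_error(patient_params(basal_level = -5), "basal_level")
  expect_error(patient_params(ar_coefficient = 1), "ar_coefficient")
  expect_error(patient_params(sensor_floor = 400, sensor_ceiling = 400),
               "sensor_floor")
  expect_error(patient_params(meal_rise_tau = 80, meal_decay_tau = 60),
               "meal_rise_tau")
  expect_error(simulate_trace(patient_params(), days = 0), "days")
})

test_that("cohorts are reproducible and match the target glucose level", {
  co <- simulate_cohort(20, seed = 101)
  expect_length(co, 20)
  pooled <- mean(unlist(lapply(co, function(tr) tr$glucose)))
  expect_lt(abs(pooled - 193.1), 15)
  days <- vapply(co, trace_days, numeric(1))
  expect_true(all(days >= 2.5 & days <= 7.5))

  co2 <- simulate_cohort(20, seed = 101)
  expect_identical(lapply(co, `[[`, "glucose"), lapply(co2, `[[`, "glucose"))

  expect_length(simulate_cohort(1, seed = 1), 1)
  expect_error(simulate_cohort(3, list(nonsense = 1)), "nonsense")
})

test_that("trace summaries match a naive re-summation oracle", {
  tr <- simulate_trace(patient_params(seed = 9), days = 3)
  s <- summarize_trace(tr)
  acc <- 0
  for (v in tr$glucose) acc <- acc + v
  expect_equal(s$mean, acc / length(tr$glucose))
  expect_equal(s$max, max(tr$glucose))
  expect_equal(s$min, min(tr$glucose))
  expect_equal(s$days, round(diff(range(tr$index)) * 5 / 1440, 1))

  const <- constant_trace(288, 150)
  sc <- summarize_trace(const)
  expect_equal(unlist(sc[c("days", "max", "min", "mean")]),
               c(days = 1.0, max = 150, min = 150, mean = 150))
  expect_error(summarize_trace(glucose_trace("E", numeric(0), integer(0))),
               "empty")
})
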