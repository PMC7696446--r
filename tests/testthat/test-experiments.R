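# small fast cohort for structural checks (short stays, low dropout)
tiny_cohort <- function(n = 2, seed = 71) {
  simulate_cohort(n, list(days = function(k) runif(k, 2.6, 3.0)), seed = seed)
}

test_that("the full per-patient pipeline holds its leakage guarantee", {
  tr <- simulate_trace(patient_params(seed = 41), days = 3)
  fit <- forecast_patient(tr, config = train_config(epochs = 2, seed = 41))
  # scaler statistics come only from readings before the test segment
  expect_lt(fit$scaler_fit_last_index, fit$cut_index)
  expect_true(min(fit$report$pairs$reference_mg_dl) > 0)
  expect_identical(fit$report$n_pairs, fit$n_test)
  expect_true(is.finite(fit$report$rmse))
})

test_that("algorithm comparison covers the three cell types", {
  co <- tiny_cohort()
  ex <- run_algorithm_comparison(co, seed = 7)
  expect_identical(ex$conditions, c("simple_rnn", "gru", "lstm"))
  expect_identical(sort(unique(ex$records$condition)), sort(ex$conditions))
  # every (patient, condition) pair appears exactly once
  expect_identical(nrow(ex$records), length(co) * 3L)
  expect_identical(anyDuplicated(ex$records[c("patient_id", "condition")]), 0L)
  expect_true(all(is.finite(ex$records$rmse)))
  # summary mean is recomputable from the records
  for (cond in ex$conditions) {
    expect_equal(ex$summary$mean_rmse[ex$summary$condition == cond],
                 mean(ex$records$rmse[ex$records$condition == cond]))
  }
})

test_that("a constant-glucose patient is fitted almost perfectly by all cells", {
  co <- list(constant_trace(600, 150, "FLAT"))
  ex <- run_algorithm_comparison(co, seed = 1)
  expect_identical(nrow(ex$records), 3L)
  expect_true(all(ex$records$rmse < 1))
})

test_that("architecture comparison orders parameter counts as expected", {
  co <- tiny_cohort(2, seed = 72)
  ex <- run_architecture_comparison(co, seed = 3)
  expect_identical(ex$conditions, c("one_layer", "bidirectional", "two_layers"))
  expect_true(all(is.finite(ex$records$rmse)))
  p1 <- build_model(model_spec("gru"), 7)$n_params
  pb <- build_model(model_spec("gru", bidirectional = TRUE), 7)$n_params
  p2 <- build_model(model_spec("gru", recurrent_layers = 2), 7)$n_params
  expect_lt(p1, pb)
  expect_lt(p1, p2)
})

test_that("split comparison spans the five ratios with shrinking train sets", {
  co <- tiny_cohort(1, seed = 73)
  ex <- run_split_comparison(co, seed = 5)
  expect_identical(ex$conditions, c("7:3", "6:4", "5:5", "4:6", "3:7"))
  expect_true(all(is.finite(ex$records$rmse)))
  n_train <- ex$records$n_train[match(ex$conditions, ex$records$condition)]
  expect_true(all(diff(n_train) < 0))
})

test_that("improvement grid covers the five hyper-parameter settings", {
  co <- tiny_cohort(1, seed = 74)
  ex <- run_improvement_grid(co, seed = 11)
  expect_identical(ex$conditions,
                   c("batch50", "batch50_shuffle", "batch50_shuffle_adamax",
                     "batch50_shuffle_rmsprop_10ep", "batch50_shuffle_rmsprop_30ep"))
  expect_true(all(is.finite(ex$records$rmse)))
})

test_that("experiments re-run bit-identically from their seed", {
  co <- tiny_cohort(2, seed = 75)
  a <- run_algorithm_comparison(co, seed = 9)
  b <- run_algorithm_comparison(co, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
})

test_that("patients with insufficient data are skipped with a message", {
  co <- list(glucose_trace("TINY", 100 + 1:20),
             constant_trace(600, 150, "FLAT"))
  expect_message(ex <- run_algorithm_comparison(co, seed = 2), "skipping")
  expect_identical(unique(ex$records$patient_id), "FLAT")
  expect_identical(ex$skipped, "TINY")
})

test_that("cohort summary has one row per patient plus a recomputable total", {
  co <- tiny_cohort(3, seed = 76)
  tab <- summarize_cohort(co)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$patient_id[4], "Total")
  expect_equal(tab$days[4], round(sum(tab$days[1:3]), 1))
  expect_equal(tab$max[4], max(tab$max[1:3]))
  expect_equal(tab$min[4], min(tab$min[1:3]))
  all_vals <- unlist(lapply(co, `[[`, "glucose"))
  expect_equal(tab$mean[4], mean(all_vals))
})

test_that("experiment artefacts round-trip through disk", {
  co <- tiny_cohort(1, seed = 77)
  ex <- run_algorithm_comparison(co, seed = 4)
  out <- tempfile("exp")
  paths <- write_experiment(ex, out)
  expect_true(all(file.exists(paths)))
  records <- utils::read.csv(paths["records"])
  expect_identical(nrow(records), nrow(ex$records))
  manifest <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  expect_identical(manifest$seed, 4L)
  expect_identical(manifest$conditions, ex$conditions)
  unlink(out, recursive = TRUE)
})
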