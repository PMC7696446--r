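test_that("analytic gradients match central finite differences", {
  # one representative per cell type, plus stacked and bidirectional variants
  cases <- list(
    list(cell = "simple_rnn", layers = 1L, bidir = FALSE, act = "tanh", dact = "relu"),
    list(cell = "gru", layers = 1L, bidir = FALSE, act = "linear", dact = "linear"),
    list(cell = "gru", layers = 2L, bidir = TRUE, act = "tanh", dact = "relu"),
    list(cell = "lstm", layers = 1L, bidir = TRUE, act = "tanh", dact = "linear"),
    list(cell = "lstm", layers = 2L, bidir = FALSE, act = "linear", dact = "relu")
  )
  set.seed(55)
  for (cs in cases) {
    spec <- model_spec(cs$cell, cs$layers, cs$bidir, recurrent_units = 3,
                       recurrent_activation = cs$act, dense_hidden_units = 2,
                       dense_hidden_activation = cs$dact)
    pred <- build_model(spec, lookback = 5, seed = 99)
    X <- matrix(rnorm(4 * 5), 4, 5)
    y <- rnorm(4)
    args <- engine_args(spec)
    analytic <- do.call(cgmforecast:::rnn_loss_grad_cpp,
                        c(list(pred$weights, X, y), args))$grads
    numeric <- numerical_gradient(pred$weights, X, y, args)
    err <- max(mapply(function(a, b) max(abs(a - b)), analytic, numeric))
    expect_lt(err, 1e-5)
  }
})

test_that("parameter counts scale with depth and bidirectionality", {
  one <- build_model(model_spec("gru"), lookback = 7)
  two <- build_model(model_spec("gru", recurrent_layers = 2), lookback = 7)
  bi <- build_model(model_spec("gru", bidirectional = TRUE), lookback = 7)
  expect_gt(two$n_params, one$n_params)
  expect_identical(count_params(bi, "recurrent"),
                   2L * count_params(one, "recurrent"))
  # closed-form GRU count: 3 * units * (input + units + 1)
  u <- 32L
  expect_identical(count_params(one, "recurrent"), 3L * u * (1L + u + 1L))
  lstm <- build_model(model_spec("lstm"), lookback = 7)
  expect_identical(count_params(lstm, "recurrent"), 4L * u * (1L + u + 1L))
  rnn <- build_model(model_spec("simple_rnn"), lookback = 7)
  expect_identical(count_params(rnn, "recurrent"), 1L * u * (1L + u + 1L))
})

test_that("untrained predictors give finite outputs of the right shape", {
  ss <- suppressWarnings(frame_samples(constant_trace(60), framing_spec()))
  for (cell in c("simple_rnn", "gru", "lstm")) {
    pred <- build_model(model_spec(cell), lookback = 7, seed = 2)
    out <- predict(pred, ss)
    expect_length(out, n_samples(ss))
    expect_true(all(is.finite(out)))
  }
  empty <- suppressWarnings(frame_samples(glucose_trace("E", 100 + 1:5),
                                          framing_spec()))
  expect_identical(predict(build_model(model_spec(), 7), empty), numeric(0))
  wrong <- build_model(model_spec(), lookback = 9)
  expect_error(predict(wrong, ss), "lookback")
})

test_that("zero-epoch training returns the predictor unchanged", {
  ss <- suppressWarnings(frame_samples(constant_trace(60), framing_spec()))
  pred <- build_model(model_spec(), 7, seed = 5)
  out <- train_model(pred, ss, train_config(epochs = 0))
  expect_identical(out$predictor$weights, pred$weights)
  expect_length(out$history, 0)
})

test_that("training is reproducible under a fixed seed, with and without shuffle", {
  tr <- simulate_trace(smooth_patient_params(), days = 2)
  ss <- suppressWarnings(frame_samples(tr, framing_spec()))
  sc <- fit_scaler(ss$targets, "zscore")
  sss <- scale_samples(ss, sc)
  for (shuffle in c(FALSE, TRUE)) {
    cfg <- train_config(epochs = 3, shuffle = shuffle, seed = 17)
    a <- train_model(build_model(model_spec(), 7, seed = 17), sss, cfg)
    b <- train_model(build_model(model_spec(), 7, seed = 17), sss, cfg)
    expect_identical(a$history, b$history)
    expect_identical(a$predictor$weights, b$predictor$weights)
  }
})

test_that("training reduces the loss on a learnable noiseless task", {
  tr <- simulate_trace(smooth_patient_params(), days = 4)
  ss <- suppressWarnings(frame_samples(tr, framing_spec()))
  sc <- fit_scaler(ss$targets, "zscore")
  sss <- scale_samples(ss, sc)
  fit <- train_model(build_model(model_spec(), 7, seed = 1), sss,
                     train_config(epochs = 20, seed = 1))
  expect_length(fit$history, 20)
  expect_lt(fit$history[20], fit$history[1])
  # final training RMSE well under the series spread
  expect_lt(sqrt(fit$history[20]), 0.5)
})

test_that("persistence baseline repeats the window's last value", {
  tr <- glucose_trace("P", c(rep(100, 12), 150))
  ss <- suppressWarnings(frame_samples(tr, framing_spec()))
  expect_identical(persistence_baseline(ss), 100)

  const <- suppressWarnings(frame_samples(constant_trace(60), framing_spec()))
  expect_equal(rmse(const$targets, persistence_baseline(const)), 0)
})

test_that("persistence error on a sinusoid matches the closed form", {
  # RMSE of lag-h persistence on A*sin(2*pi*t/P) is A*sqrt(2)*|sin(pi*h/P)|
  period_steps <- 288   # 24 h at 5-min cadence
  amp <- 40
  t <- 0:(20 * period_steps)
  tr <- glucose_trace("SIN", 200 + amp * sin(2 * pi * t / period_steps))
  fs <- framing_spec()   # horizon h = delay = 6 steps
  ss <- suppressWarnings(frame_samples(tr, fs))
  emp <- rmse(ss$targets, persistence_baseline(ss))
  closed <- amp * sqrt(2) * abs(sin(pi * fs$delay / period_steps))
  expect_equal(emp, closed, tolerance = 0.01)
})

test_that("optimizers differ but both learn", {
  tr <- simulate_trace(smooth_patient_params(), days = 3)
  ss <- suppressWarnings(frame_samples(tr, framing_spec()))
  sss <- scale_samples(ss, fit_scaler(ss$targets, "zscore"))
  h_rms <- train_model(build_model(model_spec(), 7, seed = 2), sss,
                       train_config("rmsprop", epochs = 5, seed = 2))$history
  h_ada <- train_model(build_model(model_spec(), 7, seed = 2), sss,
                       train_config("adamax", epochs = 5, seed = 2))$history
  expect_false(identical(h_rms, h_ada))
  expect_lt(h_rms[5], h_rms[1])
  expect_lt(h_ada[5], h_ada[1])
})
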