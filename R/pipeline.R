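#' End-to-end personalized forecast for one patient
#'
#' Runs the full per-patient pipeline: range cleaning, chronological
#' train/test split, scaler fitting on the training segment only, model
#' training, prediction on the held-out segment and clinical evaluation in
#' mg/dL. One model is fitted per patient; no cross-patient information is
#' used.
#'
#' @param trace A [glucose_trace()].
#' @param model A [model_spec()].
#' @param framing A [framing_spec()].
#' @param config A [train_config()]; its seed drives weight initialization
#'   and any shuffling.
#' @param train_fraction Fraction of the trace used for training (0.7
#'   reproduces a 7:3 split).
#' @param scaler_method Scaling applied before training; see [fit_scaler()].
#' @param valid_range Passed to [clean_trace()].
#' @return A `cgm_forecast_fit`: `report` (model [evaluate_forecast()]
#'   output), `persistence_report` (same metrics for the persistence
#'   baseline), `predictor`, `history`, `scaler`, `n_removed`, `cut_index`
#'   and `scaler_fit_last_index` (the largest grid index whose value entered
#'   the scaler fit -- always before the test segment, so test-period
#'   statistics never leak into training).
#' @export
forecast_patient <- function(trace,
                             model = model_spec(),
                             framing = framing_spec(),
                             config = train_config(),
                             train_fraction = 0.7,
                             scaler_method = "zscore",
                             valid_range = c(40, 400)) {
  stopifnot(inherits(trace, "glucose_trace"))
  cleaned <- clean_trace(trace, valid_range)
  n_removed <- attr(cleaned, "n_removed")
  split <- chronological_split(cleaned, train_fraction, framing)

  train_values <- cleaned$glucose[cleaned$index < split$cut_index]
  if (scaler_method != "none" && max(train_values) == min(train_values)) {
    # degenerate (constant) training segment: spread-based scaling is
    # undefined; centre on the training mean with unit scale instead
    message("forecast_patient: constant training segment for patient ",
            trace$patient_id, "; centring without rescaling")
    scaler <- structure(list(method = "zscore",
                             stats = list(mean = mean(train_values), sd = 1)),
                        class = "glucose_scaler")
  } else {
    scaler <- fit_scaler(train_values, scaler_method)
  }
  scaler_fit_last_index <- max(cleaned$index[cleaned$index < split$cut_index])

  train_scaled <- scale_samples(split$train, scaler)
  test_scaled <- scale_samples(split$test, scaler)

  predictor <- build_model(model, framing$lookback, seed = config$seed)
  fit <- train_model(predictor, train_scaled, config)

  pred <- predict(fit$predictor, test_scaled, scaler = scaler)
  reference <- split$test$targets          # unscaled mg/dL

  report <- evaluate_forecast(reference, pred, trace$patient_id)
  persistence <- evaluate_forecast(reference, persistence_baseline(split$test),
                                   trace$patient_id)
  structure(
    list(report = report,
         persistence_report = persistence,
         predictor = fit$predictor,
         history = fit$history,
         scaler = scaler,
         n_removed = n_removed,
         cut_index = split$cut_index,
         scaler_fit_last_index = scaler_fit_last_index,
         n_train = n_samples(split$train),
         n_test = n_samples(split$test),
         train_fraction = train_fraction,
         model = model, framing = framing, config = config),
    class = "cgm_forecast_fit"
  )
}

#' @export
print.cgm_forecast_fit <- function(x, ...) {
  cat(sprintf(
    "<cgm_forecast_fit> patient %s: %d train / %d test samples (%.0f:%.0f split)\n",
    x$report$patient_id, x$n_train, x$n_test,
    10 * x$train_fraction, 10 * (1 - x$train_fraction)))
  cat(sprintf("  model RMSE %.2f mg/dL (MAPE %.2f%%), persistence RMSE %.2f mg/dL\n",
              x$report$rmse, x$report$mape, x$persistence_report$rmse))
  invisible(x)
}
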