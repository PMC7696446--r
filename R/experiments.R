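#' @title Cohort experiment runners
#' @description
#' The four experiment families compare, across a cohort of per-patient
#' models: recurrent cell types, architectures, chronological split ratios
#' and training hyper-parameters. Every runner trains one personalized model
#' per (patient, condition), evaluates it on the patient's held-out segment
#' and reports per-patient RMSE/MAPE plus the unweighted cohort mean per
#' condition. Patients whose traces cannot support a split are skipped with
#' a message. Results carry a config/seed manifest sufficient to re-run
#' bit-identically.
#' @name cgm_experiments
NULL

new_experiment <- function(name, records, conditions, config_snapshot, seed,
                           skipped) {
  summary <- dplyr::summarise(
    dplyr::group_by(records, .data$condition),
    mean_rmse = mean(.data$rmse),
    mean_mape = mean(.data$mape),
    n_patients = dplyr::n(),
    .groups = "drop"
  )
  summary <- summary[match(conditions, summary$condition), ]
  structure(
    list(name = name, records = records, summary = summary,
         conditions = conditions, config = config_snapshot, seed = seed,
         skipped = skipped),
    class = "cgm_experiment"
  )
}

#' @export
print.cgm_experiment <- function(x, ...) {
  cat(sprintf("<cgm_experiment> %s: %d condition(s) x %d patient record(s)\n",
              x$name, length(x$conditions), nrow(x$records)))
  print(as.data.frame(x$summary), row.names = FALSE)
  if (length(x$skipped)) {
    cat("  skipped patients:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# shared loop: one row per (patient, condition)
run_conditions <- function(name, cohort, conditions, seed, config_snapshot) {
  stopifnot(length(cohort) >= 1)
  rows <- list()
  skipped <- character(0)
  for (i in seq_along(cohort)) {
    trace <- cohort[[i]]
    for (cond in names(conditions)) {
      cnd <- conditions[[cond]]
      res <- tryCatch(
        forecast_patient(trace,
                         model = cnd$model,
                         framing = cnd$framing,
                         config = cnd$config_fn(seed + i),
                         train_fraction = cnd$train_fraction),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        message("experiment ", name, ": skipping patient ", trace$patient_id,
                " under condition '", cond, "': ", conditionMessage(res))
        skipped <- unique(c(skipped, trace$patient_id))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = trace$patient_id,
        condition = cond,
        rmse = res$report$rmse,
        mape = res$report$mape,
        persistence_rmse = res$persistence_report$rmse,
        n_train = res$n_train,
        n_test = res$n_test
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  if (!nrow(records)) stop("no patient produced a result in experiment ", name,
                           call. = FALSE)
  new_experiment(name, records, names(conditions), config_snapshot, seed, skipped)
}

baseline_condition <- function(model, framing, train_fraction = 0.7,
                               batch_size = 20L, epochs = 20L,
                               shuffle = FALSE, optimizer = "rmsprop") {
  list(model = model, framing = framing, train_fraction = train_fraction,
       config_fn = function(s) train_config(optimizer = optimizer,
                                            batch_size = batch_size,
                                            epochs = epochs, shuffle = shuffle,
                                            seed = s))
}

#' Compare recurrent cell types
#'
#' Trains the baseline architecture (one recurrent layer plus two dense
#' layers) with each of simple RNN, GRU and LSTM cells per patient at a 7:3
#' chronological split, batch size 20, RMSprop.
#'
#' @param cohort List of [glucose_trace()] objects.
#' @param framing A [framing_spec()].
#' @param seed Base integer seed (per-patient seeds are derived from it).
#' @return A `cgm_experiment` with conditions `simple_rnn`, `gru`, `lstm`.
#' @export
run_algorithm_comparison <- function(cohort, framing = framing_spec(), seed = 1L) {
  cells <- c("simple_rnn", "gru", "lstm")
  conditions <- stats::setNames(lapply(cells, function(cl) {
    baseline_condition(model_spec(cell = cl), framing)
  }), cells)
  run_conditions("algorithm_comparison", cohort, conditions, seed,
                 list(framing = unclass(framing), split = "7:3",
                      batch_size = 20L, epochs = 20L, optimizer = "rmsprop"))
}

#' Compare GRU architectures
#'
#' One unidirectional layer (baseline) versus a bidirectional layer versus
#' two stacked layers, all GRU, at the baseline training protocol.
#'
#' @inheritParams run_algorithm_comparison
#' @return A `cgm_experiment` with conditions `one_layer`, `bidirectional`,
#'   `two_layers`.
#' @export
run_architecture_comparison <- function(cohort, framing = framing_spec(),
                                        seed = 1L) {
  conditions <- list(
    one_layer = baseline_condition(model_spec(cell = "gru"), framing),
    bidirectional = baseline_condition(
      model_spec(cell = "gru", bidirectional = TRUE), framing),
    two_layers = baseline_condition(
      model_spec(cell = "gru", recurrent_layers = 2L), framing)
  )
  run_conditions("architecture_comparison", cohort, conditions, seed,
                 list(framing = unclass(framing), split = "7:3",
                      batch_size = 20L, epochs = 20L, optimizer = "rmsprop"))
}

#' Compare chronological split ratios
#'
#' Trains the GRU baseline per patient at each train:test ratio. Patients
#' whose segments yield no samples at a ratio are skipped for that ratio.
#'
#' @inheritParams run_algorithm_comparison
#' @param ratios Training fractions to test; the defaults span 7:3 to 3:7.
#' @return A `cgm_experiment` with one condition per ratio (labelled
#'   `"7:3"`, `"6:4"`, ...).
#' @export
run_split_comparison <- function(cohort, ratios = c(0.7, 0.6, 0.5, 0.4, 0.3),
                                 framing = framing_spec(), seed = 1L) {
  labels <- sprintf("%d:%d", round(10 * ratios), round(10 * (1 - ratios)))
  conditions <- stats::setNames(lapply(ratios, function(r) {
    baseline_condition(model_spec(cell = "gru"), framing, train_fraction = r)
  }), labels)
  run_conditions("split_comparison", cohort, conditions, seed,
                 list(framing = unclass(framing), ratios = ratios,
                      batch_size = 20L, epochs = 20L, optimizer = "rmsprop"))
}

#' Hyper-parameter improvement grid
#'
#' Evaluates the GRU baseline under the improvement settings: batch size 50
#' without and with epoch shuffling, shuffling with the Adamax optimizer,
#' and shuffling with RMSprop at 10 and 30 epochs.
#'
#' @inheritParams run_algorithm_comparison
#' @return A `cgm_experiment` with conditions `batch50`, `batch50_shuffle`,
#'   `batch50_shuffle_adamax`, `batch50_shuffle_rmsprop_10ep`,
#'   `batch50_shuffle_rmsprop_30ep`.
#' @export
run_improvement_grid <- function(cohort, framing = framing_spec(), seed = 1L) {
  gru <- model_spec(cell = "gru")
  conditions <- list(
    batch50 = baseline_condition(gru, framing, batch_size = 50L),
    batch50_shuffle = baseline_condition(gru, framing, batch_size = 50L,
                                         shuffle = TRUE),
    batch50_shuffle_adamax = baseline_condition(gru, framing, batch_size = 50L,
                                                shuffle = TRUE,
                                                optimizer = "adamax"),
    batch50_shuffle_rmsprop_10ep = baseline_condition(gru, framing,
                                                      batch_size = 50L,
                                                      shuffle = TRUE,
                                                      epochs = 10L),
    batch50_shuffle_rmsprop_30ep = baseline_condition(gru, framing,
                                                      batch_size = 50L,
                                                      shuffle = TRUE,
                                                      epochs = 30L)
  )
  run_conditions("improvement_grid", cohort, conditions, seed,
                 list(framing = unclass(framing), split = "7:3",
                      batch_size = 50L, base_epochs = 20L))
}

#' Cohort overview table
#'
#' One row per patient (experiment days to one decimal, max, min, mean over
#' present readings) plus a `Total` row with summed days, global extrema and
#' the pooled mean over all readings.
#'
#' @param cohort Non-empty list of [glucose_trace()] objects.
#' @return A [tibble::tibble()] with `length(cohort) + 1` rows.
#' @export
summarize_cohort <- function(cohort) {
  if (!length(cohort)) stop("`cohort` must be non-empty", call. = FALSE)
  rows <- dplyr::bind_rows(lapply(cohort, summarize_trace))
  all_values <- unlist(lapply(cohort, function(tr) tr$glucose))
  total <- tibble::tibble(
    patient_id = "Total",
    days = round(sum(rows$days), 1),
    max = max(all_values),
    min = min(all_values),
    mean = mean(all_values)
  )
  dplyr::bind_rows(rows, total)
}

#' Write an experiment result to disk
#'
#' Emits `<name>_records.csv`, `<name>_summary.csv` and `<name>_manifest.json`
#' (config snapshot + seed, sufficient to re-run the experiment
#' bit-identically).
#'
#' @param experiment A `cgm_experiment`.
#' @param out_dir Output directory (created if absent).
#' @return Paths of the written files, invisibly.
#' @export
write_experiment <- function(experiment, out_dir) {
  stopifnot(inherits(experiment, "cgm_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, experiment$name)
  paths <- c(records = paste0(base, "_records.csv"),
             summary = paste0(base, "_summary.csv"),
             manifest = paste0(base, "_manifest.json"))
  utils::write.csv(experiment$records, paths["records"], row.names = FALSE)
  utils::write.csv(experiment$summary, paths["summary"], row.names = FALSE)
  jsonlite::write_json(
    list(name = experiment$name, conditions = experiment$conditions,
         seed = experiment$seed, config = experiment$config,
         skipped = experiment$skipped,
         package_version = as.character(utils::packageVersion("cgmforecast"))),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
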