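#' Write traces to the CGM CSV dialect
#'
#' Comma-separated, UTF-8, header `patient_id,timestamp,glucose_mg_dl`;
#' timestamps are ISO-8601 local clock time (`YYYY-MM-DDTHH:MM:SS`, no
#' timezone arithmetic); missing readings are simply absent rows.
#'
#' @param traces A [glucose_trace()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "glucose_trace")) traces <- list(traces)
  rows <- dplyr::bind_rows(lapply(traces, function(tr) {
    df <- as.data.frame(tr)
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read traces from the CGM CSV dialect
#'
#' Parses the CSV dialect written by [write_traces()], splits rows by
#' patient, and snaps each patient's observations onto the regular grid via
#' [regularize_trace()].
#'
#' @param path CSV file with header `patient_id,timestamp,glucose_mg_dl`.
#' @param interval Grid spacing in minutes.
#' @param strict If `TRUE` (default), malformed rows (unparseable timestamp
#'   or non-numeric/non-positive glucose) abort with an error listing the
#'   offending line numbers; if `FALSE` they are dropped with a warning.
#' @return List of [glucose_trace()] objects (empty list, with a warning,
#'   for a file with no data rows).
#' @export
read_traces <- function(path, interval = 5, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  required <- c("patient_id", "timestamp", "glucose_mg_dl")
  if (!all(required %in% names(df))) {
    stop("missing required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) {
    warning("no data rows in ", path, call. = FALSE)
    return(list())
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ts2 <- as.POSIXct(df$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  ts[is.na(ts)] <- ts2[is.na(ts)]
  glu <- suppressWarnings(as.numeric(df$glucose_mg_dl))
  bad <- is.na(ts) | is.na(glu) | glu <= 0
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (strict) {
      stop("malformed row(s) at line(s): ", paste(lines, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(lines, collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]; glu <- glu[!bad]
  }
  split_idx <- split(seq_along(ts), df$patient_id)
  # preserve first-appearance order of patients
  split_idx <- split_idx[unique(df$patient_id)]
  lapply(split_idx, function(ix) {
    o <- ix[order(ts[ix])]
    regularize_trace(
      data.frame(patient_id = df$patient_id[o], timestamp = ts[o],
                 glucose_mg_dl = glu[o]),
      interval = interval
    )
  })
}

config_defaults <- function() {
  list(
    # framing (lookback 7 x 5 min history, delay 6 x 5 min = 30 min horizon)
    lookback = 7L, delay = 6L, step = 1L, interval = 5,
    # model
    cell = "gru", recurrent_layers = 1L, bidirectional = FALSE,
    recurrent_units = 32L, recurrent_activation = "linear",
    dense_hidden_units = 16L, dense_hidden_activation = "linear",
    # training
    optimizer = "rmsprop", batch_size = 20L, epochs = 20L, shuffle = FALSE,
    learning_rate = NULL,
    # pipeline
    train_fraction = 0.7, scaler = "zscore", valid_range = c(40, 400),
    # cohort
    n_patients = 20L, seed = 1L
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) key-value file, rejects unknown keys, fills in the
#' documented defaults, and returns a frozen configuration object from which
#' [framing_spec()], [model_spec()] and [train_config()] can be constructed.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return A `cgm_config` (named list).
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  # normalize numeric types so dump/load round-trips are idempotent
  for (k in c("lookback", "delay", "step", "recurrent_layers",
              "recurrent_units", "dense_hidden_units", "batch_size",
              "epochs", "n_patients", "seed")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("interval", "train_fraction", "valid_range")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  if (!is.null(cfg$learning_rate)) cfg$learning_rate <- as.numeric(cfg$learning_rate)
  cfg$bidirectional <- isTRUE(cfg$bidirectional)
  cfg$shuffle <- isTRUE(cfg$shuffle)
  # validate through the constructors
  fs <- framing_spec(cfg$lookback, cfg$delay, cfg$step, cfg$interval)
  model_spec(cfg$cell, cfg$recurrent_layers, cfg$bidirectional,
             cfg$recurrent_units, cfg$recurrent_activation,
             cfg$dense_hidden_units, cfg$dense_hidden_activation)
  train_config(cfg$optimizer, cfg$batch_size, cfg$epochs, cfg$shuffle,
               cfg$learning_rate, cfg$seed)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("config key `train_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  cfg$horizon_minutes <- fs$horizon_minutes
  cfg$history_minutes <- fs$history_minutes
  structure(cfg, class = "cgm_config")
}

#' @rdname load_config
#' @param config A `cgm_config`.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "cgm_config"))
  out <- unclass(config)
  out$horizon_minutes <- NULL
  out$history_minutes <- NULL
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Helpers turning a config into pipeline objects
#' @param config A `cgm_config` from [load_config()].
#' @return The corresponding spec object.
#' @export
config_framing <- function(config) {
  framing_spec(config$lookback, config$delay, config$step, config$interval)
}

#' @rdname config_framing
#' @export
config_model <- function(config) {
  model_spec(config$cell, config$recurrent_layers, config$bidirectional,
             config$recurrent_units, config$recurrent_activation,
             config$dense_hidden_units, config$dense_hidden_activation)
}

#' @rdname config_framing
#' @export
config_train <- function(config) {
  train_config(config$optimizer, config$batch_size, config$epochs,
               config$shuffle, config$learning_rate, config$seed)
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run deterministically: the
#' frozen config, seed, package version, stage file paths and bookkeeping
#' counts (patients, samples, removed readings).
#'
#' @param config A `cgm_config`.
#' @param path Output JSON path.
#' @param files Named list/character vector of per-stage input/output paths.
#' @param counts Named list of counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, files = list(), counts = list()) {
  stopifnot(inherits(config, "cgm_config"))
  jsonlite::write_json(
    list(config = unclass(config),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("cgmforecast")),
         files = files,
         counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
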