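#' Construct a glucose trace
#'
#' A `glucose_trace` stores one patient's CGM series on a regular sampling
#' grid. Observations live at integer grid indices (index 0 at `start_time`,
#' one step every `interval` minutes); missing readings are represented by
#' absent indices, never by sentinel values.
#'
#' @param patient_id Single string identifying the patient.
#' @param glucose Numeric vector of glucose readings in mg/dL (all > 0).
#' @param index Integer vector of grid indices, strictly increasing, same
#'   length as `glucose`.
#' @param interval Grid spacing in minutes (default 5, the nominal CGM
#'   cadence).
#' @param start_time `POSIXct` time of grid index 0.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(patient_id, glucose, index = seq_along(glucose) - 1L,
                          interval = 5,
                          start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  index <- as.integer(index)
  glucose <- as.numeric(glucose)
  if (length(index) != length(glucose)) {
    stop("`index` and `glucose` must have the same length", call. = FALSE)
  }
  if (length(index) && any(diff(index) <= 0L)) {
    stop("grid indices must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    stop("all glucose values must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("`interval` must be a single positive number of minutes", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         start_time = start_time,
         interval = as.numeric(interval),
         index = index,
         glucose = glucose),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- length(x$index)
  cat(sprintf("<glucose_trace> patient %s: %d readings", x$patient_id, n))
  if (n) {
    cat(sprintf(", %.1f days, %d-min grid, %.0f-%.0f mg/dL (mean %.1f)",
                trace_days(x), as.integer(x$interval),
                min(x$glucose), max(x$glucose), mean(x$glucose)))
  }
  cat("\n")
  invisible(x)
}

#' Observation times of a trace
#'
#' @param trace A `glucose_trace`.
#' @return `POSIXct` vector, one element per present reading.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  trace$start_time + trace$index * trace$interval * 60
}

#' Trace duration in days
#'
#' Span between the first and last present reading, `(last index - first
#' index) * interval / 1440`.
#'
#' @param trace A `glucose_trace`.
#' @return Duration in days (numeric).
#' @export
trace_days <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!length(trace$index)) return(0)
  diff(range(trace$index)) * trace$interval / 1440
}

#' Summary statistics for one trace
#'
#' Reports the per-patient statistics used in cohort overview tables:
#' experiment days (to one decimal), maximum, minimum and mean glucose,
#' computed over present (non-missing) readings only.
#'
#' @param trace A non-empty `glucose_trace`.
#' @return A one-row [tibble::tibble()] with columns `patient_id`, `days`,
#'   `max`, `min`, `mean`.
#' @export
summarize_trace <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!length(trace$index)) stop("cannot summarize an empty trace", call. = FALSE)
  tibble::tibble(
    patient_id = trace$patient_id,
    days = round(trace_days(trace), 1),
    max = max(trace$glucose),
    min = min(trace$glucose),
    mean = mean(trace$glucose)
  )
}

#' Convert a trace to a data frame of observations
#'
#' @param x A `glucose_trace`.
#' @param ... Unused.
#' @return Tibble with columns `patient_id`, `timestamp`, `glucose_mg_dl`.
#' @export
as.data.frame.glucose_trace <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id,
    timestamp = trace_times(x),
    glucose_mg_dl = x$glucose
  )
}

# internal: subset a trace to indices satisfying `keep` (logical over
# present readings); grid and start time are unchanged
trace_subset <- function(trace, keep) {
  trace$index <- trace$index[keep]
  trace$glucose <- trace$glucose[keep]
  trace
}

`%||%` <- function(a, b) if (is.null(a)) b else a
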