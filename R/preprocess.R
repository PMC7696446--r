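#' Remove out-of-range readings
#'
#' Readings outside `valid_range` become missing (their grid slots are
#' dropped); the grid itself is unchanged. The number of removed readings is
#' attached as attribute `"n_removed"`.
#'
#' @param trace A [glucose_trace()].
#' @param valid_range Length-2 numeric, `c(low, high)` in mg/dL with
#'   `low < high`. The permissive default `c(40, 400)` covers the full sensor
#'   range; use `c(60, 400)` for devices that do not record below 60.
#' @return The filtered `glucose_trace`; idempotent.
#' @export
clean_trace <- function(trace, valid_range = c(40, 400)) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    stop("`valid_range` must be c(low, high) with low < high", call. = FALSE)
  }
  keep <- trace$glucose >= valid_range[1] & trace$glucose <= valid_range[2]
  out <- trace_subset(trace, keep)
  attr(out, "n_removed") <- sum(!keep)
  if (!length(out$index) && length(trace$index)) {
    message("clean_trace: all ", length(trace$index),
            " readings of patient ", trace$patient_id, " were out of range")
  }
  out
}

#' Snap irregular observations onto a regular grid
#'
#' Aligns raw timestamped observations to the nearest slot of a regular
#' `interval`-minute grid anchored at the first observation. Each
#' observation is snapped to its nearest slot (within `interval / 2` by
#' construction); when two observations map to one slot, the one nearer in
#' time to the slot centre is kept (ties keep the earlier). Slots receiving
#' no observation are missing.
#'
#' @param x Either a data frame with columns `timestamp` (`POSIXct`) and
#'   `glucose_mg_dl` (plus optional `patient_id`), or an existing
#'   [glucose_trace()] (re-gridded via its observation times).
#' @param interval Target grid spacing in minutes.
#' @param patient_id Identifier used when `x` has no `patient_id` column.
#' @return A [glucose_trace()] on the regular grid.
#' @export
regularize_trace <- function(x, interval = 5, patient_id = NULL) {
  if (inherits(x, "glucose_trace")) {
    x <- as.data.frame(x)
  }
  if (!all(c("timestamp", "glucose_mg_dl") %in% names(x))) {
    stop("`x` must have columns `timestamp` and `glucose_mg_dl`", call. = FALSE)
  }
  if (interval <= 0) stop("`interval` must be > 0", call. = FALSE)
  pid <- patient_id %||% (if ("patient_id" %in% names(x)) x$patient_id[1] else "patient")
  if (!nrow(x)) {
    return(glucose_trace(pid, numeric(0), integer(0), interval = interval))
  }
  ts <- as.numeric(x$timestamp)
  if (any(diff(ts) < 0)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  t0 <- ts[1]
  offset_min <- (ts - t0) / 60
  slot <- as.integer(round(offset_min / interval))
  miss <- abs(offset_min - slot * interval)   # distance to slot centre, min

  ord <- order(slot, miss, seq_along(slot))   # per slot: nearest, then earlier
  slot <- slot[ord]
  g <- x$glucose_mg_dl[ord]
  keep <- !duplicated(slot)
  slot <- slot[keep]
  g <- g[keep]
  o <- order(slot)
  glucose_trace(pid, g[o], index = slot[o], interval = interval,
                start_time = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"))
}

#' Fit a reversible value scaler
#'
#' Scalers are fitted on training-period values only and inverted exactly
#' when reporting predictions in mg/dL.
#'
#' @param values Numeric vector to fit on (>= 2 values with nonzero spread
#'   for `zscore`/`minmax`).
#' @param method `"zscore"` (population-SD standardization, the default used
#'   by the pipeline), `"minmax"` (maps the fitting range to `[0, 1]`) or
#'   `"none"` (identity).
#' @return An object of class `glucose_scaler`.
#' @export
fit_scaler <- function(values, method = c("zscore", "minmax", "none")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (method != "none") {
    if (length(values) < 2L) {
      stop("need at least 2 values to fit a ", method, " scaler", call. = FALSE)
    }
    if (max(values) == min(values)) {
      stop("cannot fit a ", method, " scaler on values with zero spread",
           call. = FALSE)
    }
  }
  stats <- switch(method,
    zscore = {
      m <- mean(values)
      # population (n) convention, not sample (n - 1)
      s <- sqrt(mean((values - m)^2))
      list(mean = m, sd = s)
    },
    minmax = list(min = min(values), max = max(values)),
    none = list()
  )
  structure(list(method = method, stats = stats), class = "glucose_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `glucose_scaler`.
#' @export
apply_scaler <- function(scaler, values) {
  stopifnot(inherits(scaler, "glucose_scaler"))
  switch(scaler$method,
    zscore = (values - scaler$stats$mean) / scaler$stats$sd,
    minmax = (values - scaler$stats$min) / (scaler$stats$max - scaler$stats$min),
    none = values
  )
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, values) {
  stopifnot(inherits(scaler, "glucose_scaler"))
  switch(scaler$method,
    zscore = values * scaler$stats$sd + scaler$stats$mean,
    minmax = values * (scaler$stats$max - scaler$stats$min) + scaler$stats$min,
    none = values
  )
}
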