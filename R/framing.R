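#' Window framing parameters
#'
#' Describes how a trace is converted into supervised samples: each sample
#' is a window of `lookback` consecutive readings plus a scalar target
#' `delay` steps after the window's last reading; window starts advance by
#' `step` grid slots. With the defaults (lookback 7, delay 6, step 1 on a
#' 5-minute grid) a sample uses 35 minutes of history to predict the value
#' 30 minutes ahead.
#'
#' @param lookback Number of readings per input window (>= 1).
#' @param delay Prediction horizon in grid steps (>= 1), measured from the
#'   window's last reading.
#' @param step Stride between consecutive window starts, in grid slots (>= 1).
#' @param interval Minutes per grid step (> 0).
#' @return An object of class `framing_spec` with derived fields
#'   `horizon_minutes = delay * interval` and
#'   `history_minutes = lookback * interval`.
#' @export
framing_spec <- function(lookback = 7L, delay = 6L, step = 1L, interval = 5) {
  lookback <- as.integer(lookback); delay <- as.integer(delay); step <- as.integer(step)
  if (lookback < 1L || delay < 1L || step < 1L || interval <= 0) {
    stop("need lookback >= 1, delay >= 1, step >= 1, interval > 0", call. = FALSE)
  }
  structure(
    list(lookback = lookback, delay = delay, step = step, interval = interval,
         horizon_minutes = delay * interval,
         history_minutes = lookback * interval),
    class = "framing_spec"
  )
}

#' @export
print.framing_spec <- function(x, ...) {
  cat(sprintf(
    "<framing_spec> lookback %d, delay %d, step %d on a %g-min grid (%g min history -> +%g min horizon)\n",
    x$lookback, x$delay, x$step, x$interval, x$history_minutes, x$horizon_minutes))
  invisible(x)
}

new_sample_set <- function(inputs, targets, target_index, patient_id, spec,
                           scaled = FALSE) {
  structure(
    list(inputs = inputs, targets = targets, target_index = target_index,
         patient_id = patient_id, spec = spec, scaled = scaled),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> patient %s: %d samples (lookback %d, delay %d%s)\n",
              x$patient_id, length(x$targets), x$spec$lookback, x$spec$delay,
              if (x$scaled) ", scaled" else ""))
  invisible(x)
}

#' Number of samples in a sample set
#' @param samples A `sample_set`.
#' @return Integer count.
#' @export
n_samples <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  length(samples$targets)
}

#' Frame a trace into supervised samples
#'
#' Slides a window over the trace's grid: every start slot `s` (stride
#' `spec$step` from the first present reading) for which the `lookback`
#' window slots and the target slot `s + lookback - 1 + delay` are all
#' present yields one sample. Windows touching any missing slot are skipped
#' entirely; nothing is interpolated. For a gap-free trace of `N` readings
#' with step 1 the sample count is `N - lookback - delay + 1`.
#'
#' @param trace A [glucose_trace()] on the grid implied by `spec$interval`.
#' @param spec A [framing_spec()].
#' @return A `sample_set` with fields `inputs` (n x lookback matrix),
#'   `targets` (n), `target_index` (absolute grid indices, strictly
#'   increasing), `patient_id` and `spec`. Traces too short for a single
#'   sample give an empty set with a warning.
#' @export
frame_samples <- function(trace, spec = framing_spec()) {
  stopifnot(inherits(trace, "glucose_trace"), inherits(spec, "framing_spec"))
  if (trace$interval != spec$interval) {
    stop("trace grid interval (", trace$interval,
         " min) does not match spec$interval (", spec$interval, " min)",
         call. = FALSE)
  }
  L <- spec$lookback; D <- spec$delay
  empty <- function() {
    warning("trace of patient ", trace$patient_id,
            " is too short to frame a single sample", call. = FALSE)
    new_sample_set(matrix(numeric(0), 0, L), numeric(0), integer(0),
                   trace$patient_id, spec)
  }
  if (!length(trace$index)) return(empty())
  first <- trace$index[1]
  span <- trace$index[length(trace$index)] - first   # slots: 0..span
  need <- L - 1L + D                                 # offset of target from start
  if (span < need) return(empty())

  vals <- rep(NA_real_, span + 1L)
  vals[trace$index - first + 1L] <- trace$glucose
  present <- !is.na(vals)
  cpres <- cumsum(present)

  starts <- seq(0L, span - need, by = spec$step)     # offsets from `first`
  win_end <- starts + L                              # 1-based position of window end
  full_window <- (cpres[win_end] - c(0L, cpres)[starts + 1L]) == L
  has_target <- present[starts + need + 1L]
  ok <- starts[full_window & has_target]
  if (!length(ok)) return(empty())

  idx <- outer(ok, 0:(L - 1L), "+") + 1L
  inputs <- matrix(vals[idx], nrow = length(ok), ncol = L)
  targets <- vals[ok + need + 1L]
  new_sample_set(inputs, targets, as.integer(first + ok + need),
                 trace$patient_id, spec)
}

#' Chronological train/test split
#'
#' Cuts the trace at the grid slot nearest `train_fraction` of its scheduled
#' span and frames the two segments independently, so no input window or
#' target crosses the boundary and every training target precedes every test
#' target.
#'
#' @param trace A [glucose_trace()].
#' @param train_fraction Fraction of the scheduled grid slots assigned to
#'   training, strictly between 0 and 1 (0.7 reproduces a 7:3 split).
#' @param spec A [framing_spec()].
#' @return List with elements `train` and `test` (both `sample_set`s) and
#'   `cut_index`, the first grid index of the test segment.
#' @export
chronological_split <- function(trace, train_fraction = 0.7,
                                spec = framing_spec()) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!length(trace$index)) stop("cannot split an empty trace", call. = FALSE)
  first <- trace$index[1]
  n_slots <- trace$index[length(trace$index)] - first + 1L
  cut_index <- first + as.integer(round(train_fraction * n_slots))

  train_trace <- trace_subset(trace, trace$index < cut_index)
  test_trace <- trace_subset(trace, trace$index >= cut_index)
  train <- suppressWarnings(frame_samples(train_trace, spec))
  test <- suppressWarnings(frame_samples(test_trace, spec))
  if (!n_samples(train)) {
    stop("training segment of patient ", trace$patient_id,
         " yields zero samples at train_fraction ", train_fraction, call. = FALSE)
  }
  if (!n_samples(test)) {
    stop("test segment of patient ", trace$patient_id,
         " yields zero samples at train_fraction ", train_fraction, call. = FALSE)
  }
  list(train = train, test = test, cut_index = cut_index)
}

#' Apply a fitted scaler to a sample set
#'
#' @param samples A `sample_set` in mg/dL.
#' @param scaler A fitted [fit_scaler()] object.
#' @return The sample set with inputs and targets transformed.
#' @export
scale_samples <- function(samples, scaler) {
  stopifnot(inherits(samples, "sample_set"))
  samples$inputs <- matrix(apply_scaler(scaler, samples$inputs),
                           nrow = nrow(samples$inputs))
  samples$targets <- apply_scaler(scaler, samples$targets)
  samples$scaled <- !identical(scaler$method, "none")
  samples
}

#' Export a sample set for audit
#'
#' One row per sample: the lookback input values, the target and the
#' target's timestamp.
#'
#' @param samples A `sample_set`.
#' @param trace The source [glucose_trace()] (for timestamp reconstruction).
#' @return A [tibble::tibble()].
#' @export
samples_as_table <- function(samples, trace) {
  stopifnot(inherits(samples, "sample_set"), inherits(trace, "glucose_trace"))
  inp <- as.data.frame(samples$inputs)
  names(inp) <- paste0("x", seq_len(ncol(inp)))
  tibble::as_tibble(cbind(
    inp,
    data.frame(target = samples$targets,
               target_time = trace$start_time +
                 samples$target_index * trace$interval * 60)
  ))
}
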