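#' Root mean squared error
#'
#' @param reference,predicted Equal-length, non-empty numeric vectors in
#'   mg/dL.
#' @return RMSE in mg/dL.
#' @export
rmse <- function(reference, predicted) {
  check_pairs(reference, predicted)
  sqrt(mean((reference - predicted)^2))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|reference - predicted| / reference)`; all reference values
#' must be positive (glucose always is).
#'
#' @inheritParams rmse
#' @return MAPE in percent.
#' @export
mape <- function(reference, predicted) {
  check_pairs(reference, predicted)
  if (any(reference <= 0)) {
    stop("all reference values must be > 0 for MAPE", call. = FALSE)
  }
  100 * mean(abs(reference - predicted) / reference)
}

check_pairs <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must have equal length", call. = FALSE)
  }
  if (!length(reference)) stop("need at least one pair", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(predicted))) {
    stop("values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Clarke error-grid zone of (reference, predicted) pairs
#'
#' Assigns each pair to exactly one clinical-accuracy zone A-E by the
#' standard ordered rule chain (values in mg/dL):
#' \enumerate{
#'   \item A if the prediction is within 20\% of the reference, or both are
#'     below 70 (clinically accurate);
#'   \item E if `ref >= 180 & pred <= 70` or `ref <= 70 & pred >= 180`
#'     (erroneous treatment);
#'   \item C if `70 <= ref <= 290 & pred >= ref + 110` or
#'     `130 <= ref <= 180 & pred <= (7/5) ref - 182` (overcorrection);
#'   \item D if `ref >= 240 & 70 <= pred <= 180`, or `ref <= 175/3 &
#'     70 <= pred <= 180`, or `175/3 <= ref <= 70 & pred >= (6/5) ref`
#'     (failure to detect);
#'   \item B otherwise (benign deviation).
#' }
#' Boundary ties resolve by rule order, so a pair that is both within 20\%
#' and on an E-region boundary is zone A.
#'
#' @param reference,predicted Positive glucose values in mg/dL (vectorized).
#' @return Character vector of zones, `"A"` to `"E"`.
#' @export
clarke_zone <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must have equal length", call. = FALSE)
  }
  if (any(reference <= 0) || any(predicted <= 0)) {
    stop("glucose values must be > 0", call. = FALSE)
  }
  r <- reference; p <- predicted
  zone <- rep("B", length(r))
  d_rule <- (r >= 240 & p >= 70 & p <= 180) |
    (r <= 175 / 3 & p >= 70 & p <= 180) |
    (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r)
  zone[d_rule] <- "D"
  c_rule <- (r >= 70 & r <= 290 & p >= r + 110) |
    (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182)
  zone[c_rule] <- "C"
  e_rule <- (r >= 180 & p <= 70) | (r <= 70 & p >= 180)
  zone[e_rule] <- "E"
  a_rule <- abs(p - r) <= 0.2 * r | (r < 70 & p < 70)
  zone[a_rule] <- "A"
  zone
}

#' Clarke error-grid zone distribution
#'
#' @inheritParams rmse
#' @return List with `zone_counts` and `zone_percentages`, both named
#'   vectors over zones A-E (percentages sum to 100).
#' @export
clarke_grid <- function(reference, predicted) {
  check_pairs(reference, predicted)
  z <- clarke_zone(reference, predicted)
  counts <- table(factor(z, levels = c("A", "B", "C", "D", "E")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(zone_counts = counts,
       zone_percentages = 100 * counts / length(z))
}

#' Full forecast evaluation for one patient/model pair
#'
#' @inheritParams rmse
#' @param patient_id Identifier recorded in the report.
#' @return An `eval_report`: `patient_id`, `n_pairs`, `rmse` (mg/dL), `mape`
#'   (percent), `zone_counts`, `zone_percentages`, and `pairs`, a tibble of
#'   `(reference_mg_dl, predicted_mg_dl, zone)` for error-grid plotting.
#' @export
evaluate_forecast <- function(reference, predicted, patient_id = "patient") {
  check_pairs(reference, predicted)
  grid <- clarke_grid(reference, predicted)
  structure(
    list(patient_id = as.character(patient_id),
         n_pairs = length(reference),
         rmse = rmse(reference, predicted),
         mape = mape(reference, predicted),
         zone_counts = grid$zone_counts,
         zone_percentages = grid$zone_percentages,
         pairs = tibble::tibble(reference_mg_dl = reference,
                                predicted_mg_dl = predicted,
                                zone = clarke_zone(reference, predicted))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> patient %s: %d pairs, RMSE %.2f mg/dL, MAPE %.2f%%\n",
              x$patient_id, x$n_pairs, x$rmse, x$mape))
  cat("  Clarke zones (%):",
      paste(sprintf("%s %.2f", names(x$zone_percentages), x$zone_percentages),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `eval_report`.
#' @param path File path; `.json` writes the full report, `.csv` writes the
#'   pair table.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(patient_id = report$patient_id, n_pairs = report$n_pairs,
           rmse = report$rmse, mape = report$mape,
           zone_counts = as.list(report$zone_counts),
           zone_percentages = as.list(report$zone_percentages)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report$pairs, path, row.names = FALSE)
  }
  invisible(path)
}
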