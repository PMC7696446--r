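# Independent oracles used across the suite. These deliberately use naive
# loop-based logic, kept separate from the package's vectorized paths.

# brute-force framing enumeration: try every start offset, check presence
oracle_frame_count <- function(index, lookback, delay, step = 1L) {
  if (!length(index)) return(0L)
  first <- index[1]
  last <- index[length(index)]
  present <- rep(FALSE, last - first + 1L)
  present[index - first + 1L] <- TRUE
  count <- 0L
  s <- 0L
  while (s + lookback - 1L + delay <= last - first) {
    slots <- c(s:(s + lookback - 1L), s + lookback - 1L + delay)
    if (all(present[slots + 1L])) count <- count + 1L
    s <- s + step
  }
  count
}

# naive loop RMSE
oracle_rmse <- function(ref, pred) {
  acc <- 0
  for (i in seq_along(ref)) acc <- acc + (ref[i] - pred[i])^2
  sqrt(acc / length(ref))
}

# scalar Clarke zone by the ordered rule chain, written independently
oracle_clarke_zone <- function(r, p) {
  if (abs(p - r) <= 0.2 * r || (r < 70 && p < 70)) return("A")
  if ((r >= 180 && p <= 70) || (r <= 70 && p >= 180)) return("E")
  if ((r >= 70 && r <= 290 && p >= r + 110) ||
      (r >= 130 && r <= 180 && p <= (7 / 5) * r - 182)) return("C")
  if ((r >= 240 && p >= 70 && p <= 180) ||
      (r <= 175 / 3 && p >= 70 && p <= 180) ||
      (r >= 175 / 3 && r <= 70 && p >= (6 / 5) * r)) return("D")
  "B"
}

# a trace with randomly punched-out gaps, for framing property tests
random_gappy_trace <- function(n, gap_fraction = 0.15) {
  keep <- sort(sample.int(n, max(2L, round(n * (1 - gap_fraction)))))
  glucose_trace("GAP", 100 + stats::runif(length(keep), -20, 20),
                index = keep - 1L)
}

# fully deterministic smooth patient: circadian + slow identical daily meals,
# all stochastic terms off -- the learnability fixture
smooth_patient_params <- function(seed = 7) {
  patient_params(patient_id = "SMOOTH",
                 basal_level = 160, circadian_amplitude = 30,
                 meal_magnitude_mean = 50, meal_magnitude_sd = 0,
                 meal_jitter_min = 0,
                 meal_rise_tau = 60, meal_decay_tau = 150,
                 ar_coefficient = 0, process_noise_sd = 0,
                 sensor_noise_sd = 0, dropout_rate = 0, seed = seed)
}

# gap-free constant-level trace
constant_trace <- function(n, level = 150, patient_id = "CONST") {
  glucose_trace(patient_id, rep(level, n))
}

# small low-noise cohort used by learnability checks
low_noise_cohort <- function(n_patients, seed) {
  simulate_cohort(
    n_patients,
    param_distributions = list(
      process_noise_sd = function(n) stats::runif(n, 0.5, 2),
      sensor_noise_sd = function(n) stats::runif(n, 0.2, 1)
    ),
    seed = seed
  )
}

# numerical gradient of the training loss by central differences
numerical_gradient <- function(weights, X, y, args, eps = 1e-6) {
  lg <- function(w) do.call(cgmforecast:::rnn_loss_grad_cpp,
                            c(list(w, X, y), args))$loss
  lapply(seq_along(weights), function(i) {
    g <- weights[[i]]
    for (j in seq_along(g)) {
      wp <- weights; wp[[i]][j] <- wp[[i]][j] + eps
      wm <- weights; wm[[i]][j] <- wm[[i]][j] - eps
      g[j] <- (lg(wp) - lg(wm)) / (2 * eps)
    }
    g
  })
}

engine_args <- function(spec) {
  list(cell = cgmforecast:::cell_code(spec$cell),
       nlayers = spec$recurrent_layers,
       bidir = spec$bidirectional,
       units = spec$recurrent_units,
       act = cgmforecast:::act_code(spec$recurrent_activation),
       dense_act = cgmforecast:::dense_act_code(spec$dense_hidden_activation))
}
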