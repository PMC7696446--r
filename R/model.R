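#' Forecaster architecture description
#'
#' All forecasters share one shape: a sequence-processing block (simple RNN,
#' GRU or LSTM; one or two layers; optionally bidirectional) followed by a
#' dense hidden layer and a single linear output unit (scalar regression).
#' In a two-layer stack the lower layer returns its full state sequence to
#' the upper layer. The `recurrent_activation` applies to the state (simple
#' RNN), the candidate state (GRU) or the cell input/output transforms
#' (LSTM); gate activations are always logistic. The baseline configuration
#' uses a linear recurrent activation, with `tanh` selectable.
#'
#' @param cell `"gru"` (default), `"simple_rnn"` or `"lstm"`.
#' @param recurrent_layers 1 or 2 stacked recurrent layers.
#' @param bidirectional Process the window in both time directions and
#'   concatenate the two final states.
#' @param recurrent_units Hidden state width of each recurrent layer.
#' @param recurrent_activation `"linear"` (baseline) or `"tanh"`.
#' @param dense_hidden_units Width of the dense hidden layer.
#' @param dense_hidden_activation `"linear"` (baseline) or `"relu"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(cell = c("gru", "simple_rnn", "lstm"),
                       recurrent_layers = 1L,
                       bidirectional = FALSE,
                       recurrent_units = 32L,
                       recurrent_activation = c("linear", "tanh"),
                       dense_hidden_units = 16L,
                       dense_hidden_activation = c("linear", "relu")) {
  cell <- match.arg(cell)
  recurrent_activation <- match.arg(recurrent_activation)
  dense_hidden_activation <- match.arg(dense_hidden_activation)
  recurrent_layers <- as.integer(recurrent_layers)
  if (!recurrent_layers %in% 1:2) {
    stop("`recurrent_layers` must be 1 or 2", call. = FALSE)
  }
  if (recurrent_units < 1L || dense_hidden_units < 1L) {
    stop("unit counts must be >= 1", call. = FALSE)
  }
  structure(
    list(cell = cell,
         recurrent_layers = recurrent_layers,
         bidirectional = isTRUE(bidirectional),
         recurrent_units = as.integer(recurrent_units),
         recurrent_activation = recurrent_activation,
         dense_hidden_units = as.integer(dense_hidden_units),
         dense_hidden_activation = dense_hidden_activation),
    class = "model_spec"
  )
}

#' Training protocol
#'
#' @param optimizer `"rmsprop"` (default) or `"adamax"`.
#' @param batch_size Samples per weight update (default 20; 50 in the
#'   improvement setting).
#' @param epochs Full passes over the training samples (default 20).
#' @param shuffle Reorder the samples each epoch (off for the baseline, on
#'   for the improved setting).
#' @param learning_rate Step size; `NULL` uses the optimizer default (0.001).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @return An object of class `train_config`. The loss is always mean
#'   squared error.
#' @export
train_config <- function(optimizer = c("rmsprop", "adamax"),
                         batch_size = 20L, epochs = 20L, shuffle = FALSE,
                         learning_rate = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1L || epochs < 0L) {
    stop("need batch_size >= 1 and epochs >= 0", call. = FALSE)
  }
  if (!is.null(learning_rate) && learning_rate <= 0) {
    stop("`learning_rate` must be > 0", call. = FALSE)
  }
  structure(
    list(optimizer = optimizer, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), shuffle = isTRUE(shuffle),
         learning_rate = learning_rate, loss = "mse", seed = as.integer(seed)),
    class = "train_config"
  )
}

cell_code <- function(cell) c(simple_rnn = 0L, gru = 1L, lstm = 2L)[[cell]]
n_gates <- function(cell) c(simple_rnn = 1L, gru = 3L, lstm = 4L)[[cell]]
act_code <- function(a) c(linear = 0L, tanh = 1L)[[a]]
dense_act_code <- function(a) c(linear = 0L, relu = 1L)[[a]]

# Glorot-uniform initialization; biases zero except the LSTM forget gate (1)
init_weights <- function(spec, lookback) {
  U <- spec$recurrent_units
  G <- n_gates(spec$cell)
  ndir <- if (spec$bidirectional) 2L else 1L
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  w <- list()
  input_dim <- 1L
  for (l in seq_len(spec$recurrent_layers)) {
    for (d in seq_len(ndir)) {
      b <- matrix(0, 1, G * U)
      if (spec$cell == "lstm") b[1, (U + 1):(2 * U)] <- 1  # forget-gate bias
      w[[sprintf("l%d_d%d_W", l, d)]] <- glorot(input_dim, G * U)
      w[[sprintf("l%d_d%d_U", l, d)]] <- glorot(U, G * U)
      w[[sprintf("l%d_d%d_b", l, d)]] <- b
    }
    input_dim <- U * ndir
  }
  feat <- U * ndir
  dh <- spec$dense_hidden_units
  w[["dense1_W"]] <- glorot(feat, dh)
  w[["dense1_b"]] <- matrix(0, 1, dh)
  w[["dense2_W"]] <- glorot(dh, 1L)
  w[["dense2_b"]] <- matrix(0, 1, 1)
  w
}

#' Build an untrained forecaster
#'
#' Initializes the weights (Glorot-uniform kernels under `seed`, zero biases
#' with the LSTM forget-gate bias at 1) for the given architecture and input
#' window length.
#'
#' @param spec A [model_spec()].
#' @param lookback Input window length the model will accept.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cgm_predictor` with element `n_params`, the
#'   total trainable parameter count (a deterministic function of `spec`).
#' @export
build_model <- function(spec, lookback, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  lookback <- as.integer(lookback)
  if (lookback < 1L) stop("`lookback` must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  w <- init_weights(spec, lookback)
  structure(
    list(spec = spec, lookback = lookback, weights = w,
         n_params = sum(vapply(w, length, integer(1))),
         init_seed = as.integer(seed), trained = FALSE),
    class = "cgm_predictor"
  )
}

#' Parameter count of a recurrent layer stack
#'
#' @param predictor A `cgm_predictor`.
#' @param layers Which weight groups to count: `"all"`, `"recurrent"` or
#'   `"dense"`.
#' @return Integer parameter count.
#' @export
count_params <- function(predictor, layers = c("all", "recurrent", "dense")) {
  stopifnot(inherits(predictor, "cgm_predictor"))
  layers <- match.arg(layers)
  nm <- names(predictor$weights)
  pick <- switch(layers,
    all = rep(TRUE, length(nm)),
    recurrent = startsWith(nm, "l"),
    dense = startsWith(nm, "dense"))
  sum(vapply(predictor$weights[pick], length, integer(1)))
}

#' @export
print.cgm_predictor <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<cgm_predictor> %s%s x%d (%d units, %s act) -> dense %d (%s) -> 1 linear; %d params%s\n",
    if (s$bidirectional) "bidirectional " else "", s$cell, s$recurrent_layers,
    s$recurrent_units, s$recurrent_activation, s$dense_hidden_units,
    s$dense_hidden_activation, x$n_params,
    if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Train a forecaster
#'
#' Runs `config$epochs` full passes of minibatch gradient descent on the
#' mean-squared-error loss. When `config$shuffle` is on, sample order is
#' re-drawn each epoch under `config$seed`; otherwise batches are taken in
#' chronological order. Inputs are expected in scaled space (see
#' [scale_samples()]); training on raw mg/dL works but typically needs a
#' smaller learning rate.
#'
#' @param predictor A `cgm_predictor` from [build_model()].
#' @param samples A non-empty `sample_set` framed with the predictor's
#'   lookback.
#' @param config A [train_config()].
#' @return List with `predictor` (fitted) and `history` (per-epoch training
#'   MSE; empty when `epochs = 0`, in which case the predictor is returned
#'   unchanged).
#' @export
train_model <- function(predictor, samples, config = train_config()) {
  stopifnot(inherits(predictor, "cgm_predictor"),
            inherits(samples, "sample_set"),
            inherits(config, "train_config"))
  n <- n_samples(samples)
  if (!n) stop("cannot train on an empty sample set", call. = FALSE)
  if (ncol(samples$inputs) != predictor$lookback) {
    stop("sample lookback (", ncol(samples$inputs),
         ") does not match model lookback (", predictor$lookback, ")",
         call. = FALSE)
  }
  if (config$epochs == 0L) {
    return(list(predictor = predictor, history = numeric(0)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  order_mat <- t(vapply(seq_len(config$epochs), function(e) {
    if (config$shuffle) sample.int(n) else seq_len(n)
  }, integer(n)))

  s <- predictor$spec
  fit <- rnn_fit_cpp(
    predictor$weights, samples$inputs, samples$targets,
    cell = cell_code(s$cell), nlayers = s$recurrent_layers,
    bidir = s$bidirectional, units = s$recurrent_units,
    act = act_code(s$recurrent_activation),
    dense_act = dense_act_code(s$dense_hidden_activation),
    optimizer = if (config$optimizer == "rmsprop") 0L else 1L,
    lr = config$learning_rate %||% 0.001,
    batch_size = config$batch_size, epochs = config$epochs,
    order = order_mat
  )
  predictor$weights <- fit$weights
  predictor$trained <- TRUE
  list(predictor = predictor, history = as.numeric(fit$history))
}

#' Predict glucose for framed samples
#'
#' @param object A `cgm_predictor`.
#' @param samples A `sample_set` framed with the same lookback (and, when a
#'   scaler is supplied, scaled the same way as the training samples).
#' @param scaler Optional [fit_scaler()] object; predictions are
#'   inverse-transformed back to mg/dL.
#' @param ... Unused.
#' @return Numeric vector, one prediction per sample.
#' @export
predict.cgm_predictor <- function(object, samples, scaler = NULL, ...) {
  stopifnot(inherits(samples, "sample_set"))
  if (!n_samples(samples)) return(numeric(0))
  if (ncol(samples$inputs) != object$lookback) {
    stop("sample lookback (", ncol(samples$inputs),
         ") does not match model lookback (", object$lookback, ")",
         call. = FALSE)
  }
  s <- object$spec
  pred <- rnn_predict_cpp(
    object$weights, samples$inputs,
    cell = cell_code(s$cell), nlayers = s$recurrent_layers,
    bidir = s$bidirectional, units = s$recurrent_units,
    act = act_code(s$recurrent_activation),
    dense_act = dense_act_code(s$dense_hidden_activation)
  )
  if (!is.null(scaler)) pred <- invert_scaler(scaler, pred)
  as.numeric(pred)
}

#' Persistence baseline forecaster
#'
#' Predicts, for every sample, the last value of its input window -- the
#' naive reference any learned forecaster should beat.
#'
#' @param samples A non-empty `sample_set` (in the units of its inputs).
#' @return Numeric vector of predictions.
#' @export
persistence_baseline <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  if (!n_samples(samples)) stop("empty sample set", call. = FALSE)
  samples$inputs[, ncol(samples$inputs)]
}
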