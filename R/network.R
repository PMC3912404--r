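#' Network architecture configuration
#'
#' Describes the sizes of the two-stream horizontal-product network: a
#' "dorsal" (where/movement) and a "ventral" (what/feature) recurrent hidden
#' layer share the input layer, and their linear output contributions are
#' multiplied element-wise to form the network output.  Each stream receives
#' one group of parametric-bias (PB) units, cross-wired: PB group 2 feeds
#' the dorsal layer and PB group 1 feeds the ventral layer.
#'
#' @param n_in Number of input units (two colour layers x 2-D position = 4).
#' @param n_d Dorsal hidden layer size.
#' @param n_v Ventral hidden layer size.
#' @param n_pb1 Size of PB group 1 (feeds the ventral layer).
#' @param n_pb2 Size of PB group 2 (feeds the dorsal layer).
#' @return An object of class `rnnpb_config`.
#' @export
network_config <- function(n_in = 4L, n_d = 50L, n_v = 50L,
                           n_pb1 = 1L, n_pb2 = 1L) {
  sizes <- c(n_in = n_in, n_d = n_d, n_v = n_v, n_pb1 = n_pb1, n_pb2 = n_pb2)
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != round(sizes)))
    stop("all layer sizes must be integers >= 1")
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_in),
                 n_d = as.integer(n_d), n_v = as.integer(n_v),
                 n_pb1 = as.integer(n_pb1), n_pb2 = as.integer(n_pb2)),
            class = "rnnpb_config")
}

#' @export
print.rnnpb_config <- function(x, ...) {
  cat("Two-stream RNNPB configuration\n")
  cat(sprintf("  input/output units: %d\n", x$n_in))
  cat(sprintf("  dorsal hidden: %d   ventral hidden: %d\n", x$n_d, x$n_v))
  cat(sprintf("  PB group 1 (-> ventral): %d   PB group 2 (-> dorsal): %d\n",
              x$n_pb1, x$n_pb2))
  invisible(x)
}

#' Scaled hyperbolic-tangent transfer function
#'
#' `transfer()` computes `1.7159 * tanh(2/3 * y)`, the scaled sigmoid used by
#' all hidden and PB units; it is odd, strictly increasing and bounded by
#' +/-1.7159.  `transfer_deriv()` returns its derivative expressed through
#' the activation `s = transfer(y)`, which is how the backward pass uses it.
#'
#' @param y Numeric vector/matrix of pre-activations (must be finite).
#' @param s Activations, i.e. values previously returned by `transfer()`.
#' @return Element-wise transformed object of the same shape.
#' @examples
#' transfer(0)            # 0
#' transfer(1.5)          # 1.7159 * tanh(1)
#' @export
transfer <- function(y) {
  if (any(!is.finite(y))) stop("non-finite pre-activation")
  TRANSFER_AMPLITUDE * tanh(TRANSFER_SLOPE * y)
}

#' @rdname transfer
#' @export
transfer_deriv <- function(s) {
  TRANSFER_SLOPE * (TRANSFER_AMPLITUDE - s^2 / TRANSFER_AMPLITUDE)
}

#' Model weights
#'
#' Bundles the eight weight matrices of the two-stream network together with
#' the input-normalization bounds.  Matrices: `w_d`, `w_v` input->hidden;
#' `v_d`, `v_v` recurrent; `wbar_d` (PB group 2 -> dorsal), `wbar_v`
#' (PB group 1 -> ventral); `u_d`, `u_v` hidden->output (linear).  There are
#' no bias terms other than the PB units.
#'
#' @param config An [network_config()] object.
#' @param init `"uniform"` for i.i.d. uniform entries on
#'   `[-init_range, init_range]` (drawn from R's RNG stream; seed it with
#'   `set.seed()` for reproducibility), or `"zero"`.
#' @param init_range Half-width of the uniform initialization interval.
#' @param norm_bounds 2x2 matrix of per-coordinate normalization bounds
#'   (rows `lo`/`hi`, columns horizontal/vertical), carried with the model
#'   so that recognition and prediction can (de)normalize consistently.
#' @return An object of class `rnnpb_weights`.
#' @export
random_weights <- function(config = network_config(), init = "uniform",
                           init_range = 0.1, norm_bounds = default_norm_bounds()) {
  init <- match.arg(init, c("uniform", "zero"))
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(runif(nr * nc, -init_range, init_range), nr, nc)
  }
  w <- list(w_d = mk(config$n_d, config$n_in),
            w_v = mk(config$n_v, config$n_in),
            v_d = mk(config$n_d, config$n_d),
            v_v = mk(config$n_v, config$n_v),
            wbar_d = mk(config$n_d, config$n_pb2),
            wbar_v = mk(config$n_v, config$n_pb1),
            u_d = mk(config$n_out, config$n_d),
            u_v = mk(config$n_out, config$n_v))
  structure(c(w, list(config = config, norm_bounds = norm_bounds)),
            class = "rnnpb_weights")
}

WEIGHT_NAMES <- c("w_d", "w_v", "v_d", "v_v", "wbar_d", "wbar_v", "u_d", "u_v")

check_weights <- function(weights) {
  cfg <- weights$config
  shapes <- list(w_d = c(cfg$n_d, cfg$n_in), w_v = c(cfg$n_v, cfg$n_in),
                 v_d = c(cfg$n_d, cfg$n_d), v_v = c(cfg$n_v, cfg$n_v),
                 wbar_d = c(cfg$n_d, cfg$n_pb2), wbar_v = c(cfg$n_v, cfg$n_pb1),
                 u_d = c(cfg$n_out, cfg$n_d), u_v = c(cfg$n_out, cfg$n_v))
  for (nm in WEIGHT_NAMES) {
    if (!identical(dim(weights[[nm]]), as.integer(shapes[[nm]])))
      stop(sprintf("weight matrix '%s' has shape %s, expected %s", nm,
                   paste(dim(weights[[nm]]), collapse = "x"),
                   paste(shapes[[nm]], collapse = "x")))
    if (any(!is.finite(weights[[nm]])))
      stop(sprintf("weight matrix '%s' contains non-finite entries", nm))
  }
  invisible(weights)
}

#' Parametric-bias vector
#'
#' Holds the internal values `rho` of the two PB groups and their squashed
#' activations `act = transfer(rho)`.  The activations are constant in time:
#' they are recomputed from `rho` only when `rho` is updated (once per
#' epoch/sequence presentation), never within a forward pass.  Group 1 feeds
#' the ventral layer, group 2 the dorsal layer.
#'
#' @param rho1,rho2 Numeric vectors of internal PB values.
#' @return An object of class `rnnpb_pb` with fields `rho1`, `rho2`,
#'   `act1`, `act2`.
#' @export
pb_vector <- function(rho1 = 0, rho2 = 0) {
  if (any(!is.finite(c(rho1, rho2)))) stop("non-finite PB internal values")
  structure(list(rho1 = as.numeric(rho1), rho2 = as.numeric(rho2),
                 act1 = transfer(as.numeric(rho1)),
                 act2 = transfer(as.numeric(rho2))),
            class = "rnnpb_pb")
}

#' Zero hidden state
#'
#' The recurrent state before the first time step: both hidden layers start
#' at the zero vector (standard Elman convention).
#'
#' @param config An [network_config()] object.
#' @return List with zero vectors `s_d` and `s_v`.
#' @export
zero_state <- function(config) {
  list(s_d = numeric(config$n_d), s_v = numeric(config$n_v))
}

#' One-step forward dynamics
#'
#' Advances the network one time step.  Dorsal pre-activation = input term +
#' recurrent term + PB-group-2 term; ventral pre-activation = input term +
#' recurrent term + PB-group-1 term; hidden activations through [transfer()];
#' the two linear output contributions `x_d`, `x_v` are multiplied
#' element-wise (horizontal product) to give the output `s_o`.
#'
#' @param weights An [random_weights()] object.
#' @param state Hidden state from the previous step (see [zero_state()]).
#' @param input Normalized input vector of length `n_in`.
#' @param pb A [pb_vector()].
#' @return List with `state` (new hidden state, including pre-activations
#'   `y_d`, `y_v`) and `output` (list `x_d`, `x_v`, `s_o`).
#' @export
network_step <- function(weights, state, input, pb) {
  cfg <- weights$config
  input <- as.numeric(input)
  if (length(input) != cfg$n_in)
    stop(sprintf("input has length %d, expected %d", length(input), cfg$n_in))
  if (length(state$s_d) != cfg$n_d || length(state$s_v) != cfg$n_v)
    stop("hidden state size does not match the configuration")
  if (length(pb$act1) != cfg$n_pb1 || length(pb$act2) != cfg$n_pb2)
    stop("PB vector size does not match the configuration")
  y_d <- drop(weights$w_d %*% input + weights$v_d %*% state$s_d +
                weights$wbar_d %*% pb$act2)
  y_v <- drop(weights$w_v %*% input + weights$v_v %*% state$s_v +
                weights$wbar_v %*% pb$act1)
  s_d <- transfer(y_d)
  s_v <- transfer(y_v)
  x_d <- drop(weights$u_d %*% s_d)
  x_v <- drop(weights$u_v %*% s_v)
  list(state = list(s_d = s_d, s_v = s_v, y_d = y_d, y_v = y_v),
       output = list(x_d = x_d, x_v = x_v, s_o = x_d * x_v))
}

#' Teacher-forced forward pass over a whole sequence
#'
#' Runs the network open-loop over an observed sequence: the hidden state is
#' zeroed at t = 0 and the observed value at each step is fed as input
#' (teacher forcing), so each output is a one-step-ahead prediction.  A
#' sequence of T steps yields T - 1 outputs.
#'
#' @param weights An [random_weights()] object.
#' @param pb A [pb_vector()].
#' @param sequence A [make_sequence()] object, or a T x n_in numeric matrix
#'   of normalized values.
#' @return A (T-1) x n_out matrix of predictions; row t predicts the
#'   observation at step t + 1.
#' @export
run_sequence <- function(weights, pb, sequence) {
  x <- sequence_values(sequence)
  if (nrow(x) < 2) stop("sequence must have at least 2 time steps")
  check_weights(weights)
  state <- zero_state(weights$config)
  out <- matrix(NA_real_, nrow(x) - 1, weights$config$n_out)
  for (t in seq_len(nrow(x) - 1)) {
    st <- network_step(weights, state, x[t, ], pb)
    state <- st$state
    out[t, ] <- st$output$s_o
  }
  out
}

#' Prediction cost of a sequence
#'
#' The summed squared one-step prediction error
#' `C = 1/2 * sum_t sum_k (target[t, k] - output[t, k])^2`, where the target
#' at step t is the observation at step t + 1.
#'
#' @param outputs (T-1) x N matrix of one-step predictions.
#' @param targets (T-1) x N matrix of observed next-step values.
#' @return Non-negative scalar; zero iff the prediction is perfect.
#' @export
sequence_cost <- function(outputs, targets) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!identical(dim(outputs), dim(targets)))
    stop("outputs and targets have mismatched dimensions")
  0.5 * sum((targets - outputs)^2)
}

# Extract the T x n_in value matrix from a sequence object or plain matrix.
sequence_values <- function(sequence) {
  if (inherits(sequence, "sensorimotor_sequence")) sequence$values
  else as.matrix(sequence)
}
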