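#' Recognition-mode configuration
#'
#' @param window_a Sliding-window length `a` in time steps (must not exceed
#'   the sequence length T; `a = T` uses the whole series).  `NULL` defaults
#'   to the full series at recognition time.
#' @param gamma_recog PB update rate in recognition mode; fixed (not
#'   adaptive) and larger than the learning-mode adaptive rates.  Default
#'   `10 * m_gamma` with the standard `m_gamma = 1e-2`.
#' @param recog_epochs Maximum number of recognition iterations.
#' @param tol Early-stop threshold on `max |delta rho|` between iterations.
#' @return An object of class `rnnpb_recog_config`.
#' @export
recognition_config <- function(window_a = NULL, gamma_recog = 0.1,
                               recog_epochs = 200L, tol = 1e-6) {
  if (gamma_recog < 0) stop("gamma_recog must be non-negative")
  if (recog_epochs < 1) stop("recog_epochs must be >= 1")
  structure(list(window_a = window_a, gamma_recog = gamma_recog,
                 recog_epochs = as.integer(recog_epochs), tol = tol),
            class = "rnnpb_recog_config")
}

#' Recognition mode: infer PB values for an observed sequence
#'
#' With the synaptic weights frozen, the one-step prediction error of the
#' observed sequence is repeatedly back-propagated to the PB units only.
#' Starting from `rho = 0`, each iteration runs a teacher-forced forward
#' pass and moves each PB internal value by `gamma * sum(delta)` over the
#' last `window_a` steps of the series.  Iteration stops after
#' `recog_epochs` rounds or when `max |delta rho| < tol`.
#'
#' @param model A trained `rnnpb_model`, or an `rnnpb_weights` object.
#' @param observed A `sensorimotor_sequence` or T x n_in matrix, normalized
#'   with the model's bounds.
#' @param cfg A [recognition_config()].
#' @return List with `pb` (final [pb_vector()]), `trace` (iterations x
#'   (n_pb1+n_pb2) matrix of `rho` values after each iteration), `epochs`
#'   and `final_cost`.
#' @export
recognize_sequence <- function(model, observed, cfg = recognition_config()) {
  weights <- if (inherits(model, "rnnpb_model")) model$weights else model
  check_weights(weights)
  x <- sequence_values(observed)
  T_len <- nrow(x)
  if (T_len < 2) stop("observed sequence must have at least 2 time steps")
  a <- if (is.null(cfg$window_a)) T_len else cfg$window_a
  if (a < 1 || a > T_len)
    stop(sprintf("window_a = %d outside [1, T = %d]", a, T_len))
  cfg_net <- weights$config
  pb <- pb_vector(numeric(cfg_net$n_pb1), numeric(cfg_net$n_pb2))
  # T-1 per-step deltas; the window covers the last steps of the series
  # (a = T takes all of them).
  idx <- max(1L, T_len - a) : (T_len - 1L)
  n_pb <- cfg_net$n_pb1 + cfg_net$n_pb2
  trace <- matrix(NA_real_, cfg$recog_epochs, n_pb)
  epochs <- 0L
  final_cost <- NA_real_
  for (e in seq_len(cfg$recog_epochs)) {
    res <- bptt_gradients(weights, pb, x)
    final_cost <- res$cost
    d1 <- cfg$gamma_recog * rowSums(res$delta_pb1[, idx, drop = FALSE])
    d2 <- cfg$gamma_recog * rowSums(res$delta_pb2[, idx, drop = FALSE])
    pb <- pb_vector(pb$rho1 + d1, pb$rho2 + d2)
    trace[e, ] <- c(pb$rho1, pb$rho2)
    epochs <- e
    if (max(abs(c(d1, d2))) < cfg$tol) break
  }
  trace <- trace[seq_len(epochs), , drop = FALSE]
  colnames(trace) <- c(sprintf("pb1_%d", seq_len(cfg_net$n_pb1)),
                       sprintf("pb2_%d", seq_len(cfg_net$n_pb2)))
  list(pb = pb, trace = trace, epochs = epochs, final_cost = final_cost)
}

#' Prediction mode: closed-loop sequence generation
#'
#' With PB values fixed (set manually or obtained from recognition), the
#' network generates a sequence by feeding its own one-step prediction back
#' as the next input.  The hidden state is zeroed; the true (normalized)
#' value is consumed only at the first step.
#'
#' @param model A trained `rnnpb_model` or an `rnnpb_weights` object.
#' @param pb A [pb_vector()].
#' @param initial_input Normalized input vector for the first step.
#' @param horizon Number of generated steps (>= 1).
#' @return `horizon` x n_out matrix of generated values (normalized); the
#'   denormalized series is attached as attribute `"denormalized"`.
#' @export
predict_closed_loop <- function(model, pb, initial_input, horizon) {
  weights <- if (inherits(model, "rnnpb_model")) model$weights else model
  check_weights(weights)
  if (horizon < 1) stop("horizon must be >= 1")
  state <- zero_state(weights$config)
  input <- as.numeric(initial_input)
  out <- matrix(NA_real_, horizon, weights$config$n_out)
  for (t in seq_len(horizon)) {
    st <- network_step(weights, state, input, pb)
    if (any(!is.finite(st$output$s_o)))
      stop(sprintf("closed-loop generation diverged at step %d", t))
    state <- st$state
    out[t, ] <- st$output$s_o
    input <- st$output$s_o
  }
  attr(out, "denormalized") <- denormalize_values(out, weights$norm_bounds)
  out
}

#' Per-unit prediction error
#'
#' Mean squared deviation between a generated and a true series, per output
#' unit, in normalized units.
#'
#' @param generated,truth Equal-dimension numeric matrices (steps x units).
#' @return Named numeric vector of per-unit mean squared errors.
#' @export
evaluate_prediction <- function(generated, truth) {
  generated <- as.matrix(generated); truth <- as.matrix(truth)
  if (!identical(dim(generated), dim(truth)))
    stop("generated and truth have mismatched dimensions")
  err <- colMeans((generated - truth)^2)
  names(err) <- sprintf("unit%d", seq_along(err))
  err
}
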