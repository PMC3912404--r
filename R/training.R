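#' Training hyper-parameters
#'
#' Collects every tunable of the learning mode.  The per-weight learning
#' rates start at `eta_dorsal` for the four dorsal-side matrices and
#' `eta_ventral` for the four ventral-side matrices and are then adapted by
#' the sign rule (see [adapt_learning_rates()]) within `[eta_min, eta_max]`.
#' `m_gamma` is the proportionality constant of the adaptive PB update rate.
#'
#' @param eta_dorsal,eta_ventral Initial per-weight learning rates of the
#'   dorsal-side / ventral-side matrices.
#' @param eta_max,eta_min Bounds on every adapted learning rate.
#' @param xi_plus,xi_minus Multiplicative increase/decrease factors of the
#'   sign-based adaptation (`xi_plus > 1 > xi_minus`).
#' @param m_gamma Proportionality constant of the PB update rate.
#' @param max_epochs Epoch cap.
#' @param cost_threshold Stop when the epoch-summed cost falls below this.
#' @param init_range Half-width of the uniform weight initialization.
#' @return An object of class `rnnpb_training_params`.
#' @export
training_params <- function(eta_dorsal = 1e-3, eta_ventral = 1e-5,
                            eta_max = 1e-1, eta_min = 1e-7,
                            xi_plus = 1.000001, xi_minus = 0.999999,
                            m_gamma = 1e-2,
                            max_epochs = 5000L, cost_threshold = 1e-4,
                            init_range = 0.1) {
  if (xi_plus <= 1 || xi_minus >= 1 || xi_minus <= 0)
    stop("need xi_plus > 1 and 0 < xi_minus < 1")
  if (eta_min <= 0 || eta_max <= eta_min)
    stop("need 0 < eta_min < eta_max")
  structure(list(eta_dorsal = eta_dorsal, eta_ventral = eta_ventral,
                 eta_max = eta_max, eta_min = eta_min,
                 xi_plus = xi_plus, xi_minus = xi_minus, m_gamma = m_gamma,
                 max_epochs = as.integer(max_epochs),
                 cost_threshold = cost_threshold, init_range = init_range),
            class = "rnnpb_training_params")
}

DORSAL_SIDE <- c("w_d", "v_d", "wbar_d", "u_d")
VENTRAL_SIDE <- c("w_v", "v_v", "wbar_v", "u_v")

#' Per-weight adaptive learning-rate state
#'
#' One learning rate per weight, initialized per stream, plus the previous
#' epoch's gradient used by the sign rule.
#'
#' @param weights An [random_weights()] object (for the matrix shapes).
#' @param params A [training_params()].
#' @return An object of class `rnnpb_rate_state` with fields `eta` (list of
#'   matrices), `prev_grad` (NULL until the first adaptation call) and the
#'   adaptation constants.
#' @export
rate_state <- function(weights, params = training_params()) {
  eta <- lapply(WEIGHT_NAMES, function(nm) {
    init <- if (nm %in% DORSAL_SIDE) params$eta_dorsal else params$eta_ventral
    matrix(init, nrow(weights[[nm]]), ncol(weights[[nm]]))
  })
  names(eta) <- WEIGHT_NAMES
  structure(list(eta = eta, prev_grad = NULL,
                 eta_max = params$eta_max, eta_min = params$eta_min,
                 xi_plus = params$xi_plus, xi_minus = params$xi_minus),
            class = "rnnpb_rate_state")
}

#' Sign-based learning-rate adaptation
#'
#' For each weight, the product `sigma` of the previous and current epoch's
#' cost gradients decides the step: same sign (`sigma > 0`) multiplies the
#' rate by `xi_plus` (capped at `eta_max`), opposite sign (`sigma < 0`)
#' multiplies by `xi_minus` (floored at `eta_min`), and `sigma == 0` leaves
#' it unchanged.  On the first call (`prev_grad` empty) the rates are left
#' unchanged and the gradient is only recorded.
#'
#' @param state An [rate_state()].
#' @param grad Named list of epoch-accumulated gradient matrices.
#' @return The updated `rnnpb_rate_state` (with `prev_grad <- grad`).
#' @export
adapt_learning_rates <- function(state, grad) {
  if (!is.null(state$prev_grad)) {
    for (nm in WEIGHT_NAMES) {
      sigma <- state$prev_grad[[nm]] * grad[[nm]]
      eta <- state$eta[[nm]]
      up <- sigma > 0
      dn <- sigma < 0
      eta[up] <- pmin(eta[up] * state$xi_plus, state$eta_max)
      eta[dn] <- pmax(eta[dn] * state$xi_minus, state$eta_min)
      state$eta[[nm]] <- eta
    }
  }
  state$prev_grad <- grad
  state
}

#' BPTT gradients and PB deltas for one sequence
#'
#' Unrolls the full teacher-forced sequence and back-propagates the one-step
#' prediction error through all time steps (errors flow through the
#' recurrent connections), returning the cost gradient for each of the eight
#' weight matrices and the per-step errors back-propagated to the PB units.
#' The PB deltas follow the cross-wiring: group 2 routes through the dorsal
#' layer, group 1 through the ventral layer.  Deltas carry the sign of the
#' NEGATIVE cost gradient, so that adding `gamma * sum(delta)` to `rho`
#' decreases the cost.
#'
#' @param weights An [random_weights()] object.
#' @param pb A [pb_vector()].
#' @param sequence A `sensorimotor_sequence` or T x n_in matrix.
#' @return List with `cost`, `outputs` ((T-1) x n_out), `grads` (named list
#'   over the eight matrices), `delta_pb1` and `delta_pb2` (n_pb x (T-1)
#'   per-step delta matrices).
#' @export
bptt_gradients <- function(weights, pb, sequence) {
  check_weights(weights)
  x <- sequence_values(sequence)
  if (nrow(x) < 2) stop("sequence must have at least 2 time steps")
  res <- .cpp_seq_grad(weights$w_d, weights$w_v, weights$v_d, weights$v_v,
                       weights$wbar_d, weights$wbar_v, weights$u_d,
                       weights$u_v, pb$rho1, pb$rho2, x, TRUE)
  bad <- vapply(res$grads, function(g) any(!is.finite(g)), logical(1))
  if (any(bad) || any(!is.finite(res$delta_pb1)) ||
      any(!is.finite(res$delta_pb2)))
    stop("non-finite gradient: training diverged")
  res
}

# Compiled teacher-forced forward pass (cost + outputs only); must agree
# exactly with run_sequence()/sequence_cost().
forward_pass <- function(weights, pb, sequence) {
  x <- sequence_values(sequence)
  .cpp_seq_grad(weights$w_d, weights$w_v, weights$v_d, weights$v_v,
                weights$wbar_d, weights$wbar_v, weights$u_d, weights$u_v,
                pb$rho1, pb$rho2, x, FALSE)
}

#' Adaptive PB update in learning mode
#'
#' For PB node i with per-step deltas `delta_i(t)` over a series of length
#' T, the update rate is `gamma_i = m_gamma * |mean_t delta_i(t)|` and the
#' internal value moves by `gamma_i * sum_t delta_i(t)`; activations are
#' recomputed from the new `rho`.  The rate is proportional to the absolute
#' mean back-propagated error, so nodes receiving consistently signed error
#' move fastest while nodes with cancelling error barely move.
#'
#' @param pb A [pb_vector()].
#' @param delta_pb1,delta_pb2 Per-step delta matrices (n_pb x steps), as
#'   returned by [bptt_gradients()].
#' @param m_gamma Proportionality constant of the update rate.
#' @return The updated [pb_vector()].
#' @export
update_pb_learning <- function(pb, delta_pb1, delta_pb2, m_gamma) {
  upd <- function(rho, delta) {
    delta <- matrix(delta, nrow = length(rho))
    s <- rowSums(delta)
    gamma <- m_gamma * abs(s) / ncol(delta)
    rho + gamma * s
  }
  pb_vector(upd(pb$rho1, delta_pb1), upd(pb$rho2, delta_pb2))
}

#' Train the two-stream network on a set of sequences
#'
#' Learning mode.  Weights start from a seeded uniform distribution on
#' `[-init_range, init_range]`; every sequence gets its own PB vector,
#' initialized at `rho = 0`.  Each epoch presents all sequences one after
#' another: for each sequence, full-BPTT gradients are computed with that
#' sequence's PB vector, the weights move by `-eta_ij * dC/dw_ij` (one rate
#' per weight), and the sequence's PB vector is updated adaptively.  Once
#' per epoch, the learning rates adapt on the epoch-accumulated (summed
#' over sequences) gradients.  Training stops at `max_epochs` or when the
#' epoch-summed cost drops below `cost_threshold`.
#'
#' @param dataset Non-empty list of sequences (see [make_dataset()]), all
#'   with the same number of channels.
#' @param config An [network_config()].
#' @param params A [training_params()].
#' @param seed Integer seed for the weight initialization.
#' @param norm_bounds Normalization bounds stored with the model.
#' @param trace_every Record the PB table every this many epochs (the final
#'   epoch is always recorded).
#' @return An object of class `rnnpb_model`: list with `weights`,
#'   `pb_table` (one [pb_vector()] per sequence, named by sequence id),
#'   `report` (class `rnnpb_training_report`: `cost_per_epoch`, `pb_trace`,
#'   `epochs_run`, `stop_reason`), `config`, `params`, `seed`.
#' @export
train_network <- function(dataset, config = network_config(),
                          params = training_params(), seed = 1L,
                          norm_bounds = default_norm_bounds(),
                          trace_every = 10L) {
  if (!length(dataset)) stop("dataset is empty")
  n_ch <- unique(vapply(dataset, function(s) ncol(sequence_values(s)),
                        integer(1)))
  if (length(n_ch) != 1 || n_ch != config$n_in)
    stop("all sequences must share the configured channel count")
  ids <- vapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    if (inherits(s, "sensorimotor_sequence")) s$sequence_id
    else sprintf("seq%03d", i)
  }, character(1))

  set.seed(seed)
  weights <- random_weights(config, init_range = params$init_range,
                            norm_bounds = norm_bounds)
  pb_table <- replicate(length(dataset),
                        pb_vector(numeric(config$n_pb1),
                                  numeric(config$n_pb2)),
                        simplify = FALSE)
  names(pb_table) <- ids
  state <- rate_state(weights, params)

  cost_per_epoch <- numeric(params$max_epochs)
  pb_trace <- list()
  stop_reason <- "max-epochs"
  epochs_run <- 0L

  for (e in seq_len(params$max_epochs)) {
    epoch_grad <- NULL
    epoch_cost <- 0
    for (i in seq_along(dataset)) {
      res <- bptt_gradients(weights, pb_table[[i]], dataset[[i]])
      epoch_cost <- epoch_cost + res$cost
      for (nm in WEIGHT_NAMES)
        weights[[nm]] <- weights[[nm]] - state$eta[[nm]] * res$grads[[nm]]
      epoch_grad <- if (is.null(epoch_grad)) res$grads
                    else mapply(`+`, epoch_grad, res$grads, SIMPLIFY = FALSE)
      pb_table[[i]] <- update_pb_learning(pb_table[[i]], res$delta_pb1,
                                          res$delta_pb2, params$m_gamma)
    }
    if (!is.finite(epoch_cost))
      stop(sprintf("training diverged (non-finite cost) at epoch %d", e))
    state <- adapt_learning_rates(state, epoch_grad)
    cost_per_epoch[e] <- epoch_cost
    epochs_run <- e
    if (e %% trace_every == 0L || e == params$max_epochs)
      pb_trace[[as.character(e)]] <- pb_table_matrix(pb_table)
    if (epoch_cost < params$cost_threshold) {
      stop_reason <- "cost-threshold"
      break
    }
  }
  pb_trace[[as.character(epochs_run)]] <- pb_table_matrix(pb_table)

  report <- structure(list(cost_per_epoch = cost_per_epoch[seq_len(epochs_run)],
                           pb_trace = pb_trace, epochs_run = epochs_run,
                           stop_reason = stop_reason),
                      class = "rnnpb_training_report")
  structure(list(weights = weights, pb_table = pb_table, report = report,
                 config = config, params = params, seed = as.integer(seed)),
            class = "rnnpb_model")
}

#' Flatten a PB table into a matrix
#'
#' @param pb_table Named list of [pb_vector()]s.
#' @return Matrix with one row per sequence; columns `pb1_*` then `pb2_*`
#'   hold the internal values `rho`.
#' @export
pb_table_matrix <- function(pb_table) {
  m <- t(vapply(pb_table, function(p) c(p$rho1, p$rho2),
                numeric(length(pb_table[[1]]$rho1) +
                          length(pb_table[[1]]$rho2))))
  colnames(m) <- c(sprintf("pb1_%d", seq_along(pb_table[[1]]$rho1)),
                   sprintf("pb2_%d", seq_along(pb_table[[1]]$rho2)))
  m
}

#' @export
print.rnnpb_model <- function(x, ...) {
  cat("Trained two-stream RNNPB model\n")
  print(x$config)
  cat(sprintf("  sequences: %d   epochs run: %d (%s)\n",
              length(x$pb_table), x$report$epochs_run, x$report$stop_reason))
  cat(sprintf("  final epoch cost: %.6g\n",
              x$report$cost_per_epoch[x$report$epochs_run]))
  invisible(x)
}
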