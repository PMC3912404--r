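# Shared fixtures: tiny random networks, a finite-difference gradient
# oracle that goes through the pure-R forward path only, and memoized
# trained models reused across test files.

tiny_config <- function(n_in = 2L, n_d = 3L, n_v = 2L, n_pb1 = 1L,
                        n_pb2 = 2L) {
  network_config(n_in = n_in, n_d = n_d, n_v = n_v, n_pb1 = n_pb1,
                 n_pb2 = n_pb2)
}

rand_instance <- function(seed, T_len = 4L, cfg = NULL) {
  set.seed(seed)
  if (is.null(cfg))
    cfg <- network_config(n_in = sample(1:3, 1), n_d = sample(1:3, 1),
                          n_v = sample(1:3, 1), n_pb1 = sample(1:2, 1),
                          n_pb2 = sample(1:2, 1))
  list(cfg = cfg,
       weights = random_weights(cfg, init_range = 0.5),
       pb = pb_vector(rnorm(cfg$n_pb1, sd = 0.5), rnorm(cfg$n_pb2, sd = 0.5)),
       x = matrix(runif(T_len * cfg$n_in), T_len, cfg$n_in))
}

# Central finite differences of the sequence cost, through run_sequence()
# (pure R), for every weight matrix and both PB groups.
fd_gradients <- function(weights, pb, x, h = 1e-6) {
  targets <- x[-1, , drop = FALSE]
  cost_at <- function(w, p) sequence_cost(run_sequence(w, p, x), targets)
  grads <- list()
  for (nm in rnnpb:::WEIGHT_NAMES) {
    g <- weights[[nm]]
    for (i in seq_along(g)) {
      wp <- weights; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- weights; wm[[nm]][i] <- wm[[nm]][i] - h
      g[i] <- (cost_at(wp, pb) - cost_at(wm, pb)) / (2 * h)
    }
    grads[[nm]] <- g
  }
  drho <- function(which) {
    r <- if (which == 1) pb$rho1 else pb$rho2
    vapply(seq_along(r), function(i) {
      rp <- r; rp[i] <- rp[i] + h
      rm <- r; rm[i] <- rm[i] - h
      pp <- if (which == 1) pb_vector(rp, pb$rho2) else pb_vector(pb$rho1, rp)
      pm <- if (which == 1) pb_vector(rm, pb$rho2) else pb_vector(pb$rho1, rm)
      (cost_at(weights, pp) - cost_at(weights, pm)) / (2 * h)
    }, numeric(1))
  }
  grads$rho1 <- drho(1)
  grads$rho2 <- drho(2)
  grads
}

# Denominator floored at 1e-4: the central-difference oracle at h = 1e-6
# carries ~1e-10 absolute roundoff, so near-zero gradients are compared
# absolutely (against 1e-9 at the 1e-5 relative threshold) rather than
# dividing by their own noise.
rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a) + abs(b), 1e-4))

# Memoized fixtures (training is the expensive step; share across files).
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# A small but genuinely trained model on a 4-class dataset (reduced hidden
# sizes and epoch budget keep this a few seconds).
small_trained_model <- function() {
  memo("small_model", function() {
    prot <- dataset_protocol(reps_per_class = 1L, base_seed = 42L)
    train_network(make_dataset(prot),
                  network_config(n_d = 12L, n_v = 12L),
                  training_params(max_epochs = 400L),
                  seed = 42L)
  })
}

# Full default-conditions reproduction (standard parameters, 20-sequence
# dataset, 10 seeds); shared by every acceptance block.
acceptance_reproduction <- function() {
  memo("reproduction", function()
    run_reproduction(seed = 1L, n_seeds = 10L, progress = FALSE))
}
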