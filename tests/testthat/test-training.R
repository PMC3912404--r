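test_that("BPTT gradients match central finite differences on random tiny networks", {
  for (seed in 1:20) {
    inst <- rand_instance(seed, T_len = sample(2:5, 1))
    res <- bptt_gradients(inst$weights, inst$pb, inst$x)
    fd <- fd_gradients(inst$weights, inst$pb, inst$x)
    for (nm in rnnpb:::WEIGHT_NAMES)
      expect_lt(rel_err(res$grads[[nm]], fd[[nm]]), 1e-5)
    # summed PB deltas are the negative cost gradient w.r.t. rho
    expect_lt(rel_err(-rowSums(res$delta_pb1), fd$rho1), 1e-5)
    expect_lt(rel_err(-rowSums(res$delta_pb2), fd$rho2), 1e-5)
  }
})

test_that("a perfectly predicted sequence produces zero gradients and deltas", {
  inst <- rand_instance(4, T_len = 2L)
  st <- network_step(inst$weights, zero_state(inst$cfg), inst$x[1, ],
                     inst$pb)
  x <- rbind(inst$x[1, ], st$output$s_o)   # second frame = exact prediction
  res <- bptt_gradients(inst$weights, inst$pb, x)
  expect_equal(res$cost, 0)
  for (nm in rnnpb:::WEIGHT_NAMES)
    expect_true(all(res$grads[[nm]] == 0))
  expect_true(all(res$delta_pb1 == 0) && all(res$delta_pb2 == 0))
})

test_that("single-step PB delta for the dorsal-attached group matches its closed form", {
  # 1 unit per layer, T = 2: delta_pb2 = e * x_v * u_d * f'(s_d) * wbar_d
  # * f'(rho2), with e the (target - output) error and linear outputs
  cfg <- network_config(n_in = 1L, n_d = 1L, n_v = 1L)
  set.seed(8)
  w <- random_weights(cfg, init_range = 0.8)
  pb <- pb_vector(0.3, -0.2)
  x <- matrix(c(0.7, 0.4), 2, 1)
  st <- network_step(w, zero_state(cfg), x[1, ], pb)
  e <- x[2, 1] - st$output$s_o
  closed_form <- e * st$output$x_v * w$u_d[1, 1] *
    transfer_deriv(st$state$s_d) * w$wbar_d[1, 1] *
    transfer_deriv(pb$act2)
  res <- bptt_gradients(w, pb, x)
  expect_equal(res$delta_pb2[1, 1], closed_form, tolerance = 1e-12)
  # and symmetrically through the ventral stream for group 1
  closed_form1 <- e * st$output$x_d * w$u_v[1, 1] *
    transfer_deriv(st$state$s_v) * w$wbar_v[1, 1] *
    transfer_deriv(pb$act1)
  expect_equal(res$delta_pb1[1, 1], closed_form1, tolerance = 1e-12)
})

test_that("sign-based rate adaptation multiplies, caps and floors per weight", {
  cfg <- tiny_config()
  set.seed(1)
  w <- random_weights(cfg)
  p <- training_params()
  st <- rate_state(w, p)
  expect_true(all(st$eta$w_d == p$eta_dorsal))
  expect_true(all(st$eta$w_v == p$eta_ventral))

  g1 <- lapply(w[rnnpb:::WEIGHT_NAMES], function(m) m * 0 + 1)
  # first call only records the gradient
  st <- adapt_learning_rates(st, g1)
  expect_true(all(st$eta$w_d == p$eta_dorsal))

  # same sign -> times xi_plus; opposite -> times xi_minus; zero -> unchanged
  g2 <- g1
  g2$w_d[1, 1] <- -1
  g2$w_d[1, 2] <- 0
  st2 <- adapt_learning_rates(st, g2)
  expect_equal(st2$eta$w_d[1, 1], p$eta_dorsal * p$xi_minus)
  expect_equal(st2$eta$w_d[1, 2], p$eta_dorsal)
  expect_equal(st2$eta$w_d[2, 1], p$eta_dorsal * p$xi_plus)

  # cap at eta_max and floor at eta_min
  st$eta$w_d[] <- p$eta_max
  st$eta$w_v[] <- p$eta_min
  g3 <- g1
  g3$w_v <- -g3$w_v
  st3 <- adapt_learning_rates(st, g3)
  expect_true(all(st3$eta$w_d == p$eta_max))
  expect_true(all(st3$eta$w_v == p$eta_min))

  # rates never leave [eta_min, eta_max] under random gradient streams
  set.seed(2)
  stp <- rate_state(w, p)
  for (i in 1:50) {
    g <- lapply(w[rnnpb:::WEIGHT_NAMES], function(m)
      matrix(rnorm(length(m)), nrow(m)))
    stp <- adapt_learning_rates(stp, g)
    for (nm in rnnpb:::WEIGHT_NAMES)
      expect_true(all(stp$eta[[nm]] >= p$eta_min &
                        stp$eta[[nm]] <= p$eta_max))
  }
})

test_that("PB learning update is the signed quadratic of the accumulated delta", {
  pb <- pb_vector(0.1, -0.2)
  zero <- matrix(0, 1, 10)
  expect_equal(update_pb_learning(pb, zero, zero, 1e-2), pb)

  # constant delta d over T steps: increment = m_gamma * |d| * (T * d)
  d <- -0.3; T_len <- 10
  const <- matrix(d, 1, T_len)
  upd <- update_pb_learning(pb, const, zero, 1e-2)
  expect_equal(upd$rho1, pb$rho1 + 1e-2 * abs(d) * (T_len * d))
  expect_equal(upd$rho2, pb$rho2)
  expect_equal(upd$act1, transfer(upd$rho1))

  # the increment always carries the sign of the delta sum
  set.seed(3)
  for (i in 1:10) {
    dd <- matrix(rnorm(8), 1)
    upd <- update_pb_learning(pb, dd, zero, 1e-2)
    expect_identical(sign(upd$rho1 - pb$rho1), sign(sum(dd)))
  }
})

test_that("training on one constant sequence decreases the cost monotonically", {
  x <- matrix(rep(c(0.3, 0.6, 0.2, 0.5), each = 12), 12, 4)
  m <- train_network(list(x), network_config(n_d = 6L, n_v = 6L),
                     training_params(max_epochs = 50L), seed = 3L)
  expect_identical(m$report$epochs_run, 50L)
  expect_true(all(diff(m$report$cost_per_epoch) <= 1e-12))
})

test_that("training is deterministic and reports its epoch trace", {
  prot <- dataset_protocol(reps_per_class = 1L, base_seed = 5L)
  ds <- make_dataset(prot)
  args <- list(ds, network_config(n_d = 5L, n_v = 5L),
               training_params(max_epochs = 20L))
  m1 <- do.call(train_network, c(args, seed = 9L))
  m2 <- do.call(train_network, c(args, seed = 9L))
  expect_identical(m1$report, m2$report)
  expect_identical(m1$weights, m2$weights)
  expect_length(m1$report$cost_per_epoch, m1$report$epochs_run)
  expect_identical(m1$report$stop_reason, "max-epochs")
  expect_named(m1$pb_table, vapply(ds, `[[`, character(1), "sequence_id"))
  # different seed, different initialization
  m3 <- do.call(train_network, c(args, seed = 10L))
  expect_false(identical(m1$weights$w_d, m3$weights$w_d))
})

test_that("sequences differing only in colour develop different PB vectors", {
  prot0 <- dataset_protocol(noise_sigma = 0)
  sy <- make_sequence("cosine", "yellow", prot0)
  sg <- make_sequence("cosine", "green", prot0)
  m <- train_network(list(sy, sg), network_config(n_d = 8L, n_v = 8L),
                     training_params(max_epochs = 1000L), seed = 1L)
  pm <- pb_table_matrix(m$pb_table)
  expect_false(identical(pm[1, ], pm[2, ]))
  expect_gt(max(abs(pm[1, ] - pm[2, ])), 1e-8)
})

test_that("zero PB update rate reduces training to plain two-stream Elman BPTT", {
  prot <- dataset_protocol(reps_per_class = 1L, curves = "cosine",
                           base_seed = 6L)
  ds <- make_dataset(prot)
  m <- train_network(ds, network_config(n_d = 4L, n_v = 4L),
                     training_params(max_epochs = 15L, m_gamma = 0),
                     seed = 2L)
  pm <- pb_table_matrix(m$pb_table)
  expect_true(all(pm == 0))
  expect_lt(m$report$cost_per_epoch[15], m$report$cost_per_epoch[1])
})

test_that("training rejects empty or inconsistent datasets", {
  expect_error(train_network(list()), "empty")
  x3 <- matrix(runif(9), 3, 3)
  expect_error(train_network(list(x3), network_config()), "channel count")
})
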