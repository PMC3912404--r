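test_that("cosine curve evaluates the generating equations", {
  p <- cosine_curve(c(0, pi / 2, -1, pi))
  expect_true(all(p[, "x"] == 12))
  expect_equal(unname(p[1, "z"]), 4.10)
  expect_equal(unname(p[2, "z"]), -3.90)
  expect_equal(p[, "y"], 8 * (-c(0, pi / 2, -1, pi) / 2) + 0.04,
               ignore_attr = TRUE)
  # quadratic reading available behind the flag
  q <- cosine_curve(1, y_form = "quadratic")
  expect_equal(unname(q[1, "y"]), -8 + 0.04)
  expect_error(cosine_curve(4), "phase")
  expect_error(cosine_curve(-pi), "phase")   # domain is open at -pi
})

test_that("square curve is the continuous closed loop with slopes 16/pi", {
  expect_equal(unname(square_curve(0)[1, "y"]), 8)
  expect_equal(unname(square_curve(pi)[1, "y"]), 0)
  expect_equal(unname(square_curve(-3 * pi / 4 - 1e-9)[1, "y"]), 0,
               tolerance = 1e-6)

  # continuity at every branch boundary, for y and z
  for (tb in c(-3 * pi / 4, -pi / 4, pi / 4, 3 * pi / 4)) {
    lo <- square_curve(tb - 1e-9); hi <- square_curve(tb + 1e-9)
    expect_equal(lo[1, "y"], hi[1, "y"], tolerance = 1e-6)
    expect_equal(lo[1, "z"], hi[1, "z"], tolerance = 1e-6)
  }
  # closure across the phase wrap: the loop ends where it starts
  expect_equal(square_curve(pi)[1, "z"],
               square_curve(-pi + 1e-9)[1, "z"], tolerance = 1e-6)
  # the 20-point loop closes within one segment's step length
  t20 <- -pi + (1:20) * (2 * pi / 20)
  pts <- square_curve(t20)
  gap <- sqrt(sum((pts[20, c("y", "z")] - pts[1, c("y", "z")])^2))
  step_len <- (16 / pi) * (2 * pi / 20)
  expect_lt(gap, step_len + 1e-9)
  # corners of the square are visited
  expect_equal(range(pts[, "y"]), c(0, 8), tolerance = 1e-9)
  expect_equal(range(pts[, "z"]), c(6, 14), tolerance = 0.45)
})

test_that("circle curve traces a radius-4 circle centred at (0.04, 0.10)", {
  t <- seq(-pi + 1e-9, pi, length.out = 33)
  p <- circle_curve(t)
  expect_equal((p[, "y"] - 0.04)^2 + (p[, "z"] - 0.10)^2,
               rep(16, 33), ignore_attr = TRUE)
  expect_equal(circle_curve(0)[1, c("y", "z")], c(y = 0.04, z = 4.10))
  expect_equal(unname(circle_curve(pi / 4)[1, "y"]), 4.04)
})

test_that("sequences encode colour in exclusive channel layers", {
  prot0 <- dataset_protocol(noise_sigma = 0)
  sy <- make_sequence("cosine", "yellow", prot0)
  sg <- make_sequence("cosine", "green", prot0)
  expect_identical(nrow(sy$values), 20L)
  expect_true(all(sy$values[, 3:4] == 0))
  expect_true(all(sg$values[, 1:2] == 0))
  expect_true(all(sy$values[, 1:2] != 0))
  # noiseless values stay inside [0, 1] (actually [0.1, 0.9] by design)
  expect_true(all(sy$values >= 0 & sy$values <= 1))
  expect_true(all(sy$values[, 1:2] >= 0.1 - 1e-12 &
                    sy$values[, 1:2] <= 0.9 + 1e-12))
  # noiseless generation ignores the seed
  expect_identical(make_sequence("square", "green", prot0, seed = 1)$values,
                   make_sequence("square", "green", prot0, seed = 99)$values)
  # noisy generation is reproducible from the seed and perturbs only the
  # active layer
  prot <- dataset_protocol(noise_sigma = 0.01)
  n1 <- make_sequence("square", "yellow", prot, seed = 7)
  n2 <- make_sequence("square", "yellow", prot, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values[, 3:4] == 0))
  expect_false(any(n1$values[, 1:2] ==
                     make_sequence("square", "yellow", prot0)$values[, 1:2]))
  expect_error(make_sequence("helix", "yellow", prot), "should be one of")
  expect_error(make_sequence("cosine", "red", prot), "should be one of")
})

test_that("the default protocol yields the 20-sequence training set, reproducibly", {
  ds <- make_dataset()
  expect_length(ds, 20L)
  ids <- vapply(ds, `[[`, character(1), "sequence_id")
  expect_length(unique(ids), 20L)
  expect_true(all(vapply(ds, function(s) nrow(s$values), integer(1)) == 20L))
  colors <- vapply(ds, `[[`, character(1), "color_label")
  expect_identical(sum(colors == "yellow"), 10L)
  expect_identical(sum(colors == "green"), 10L)
  # byte-for-byte reproducibility from (protocol, base_seed)
  expect_identical(ds, make_dataset())
  expect_false(identical(ds, make_dataset(dataset_protocol(base_seed = 2))))
  expect_length(make_dataset(dataset_protocol(reps_per_class = 1,
                                              colors = "yellow",
                                              curves = "cosine")), 1L)
})

test_that("speed variant multiplies the phase step at fixed sequence length", {
  prot <- dataset_protocol(noise_sigma = 0)
  expect_identical(speed_variant(prot, 1), prot)
  expect_error(speed_variant(prot, 0), "positive")
  expect_error(speed_variant(prot, -2), "positive")

  fast <- speed_variant(prot, 2)
  s1 <- make_sequence("cosine", "yellow", prot)
  s2 <- make_sequence("cosine", "yellow", fast)
  expect_identical(nrow(s2$values), nrow(s1$values))
  # each loop is now sampled at 10 phases, traversed twice
  expect_length(unique(round(s2$phases, 10)), 10L)
  # dominant discrete frequency of the vertical channel doubles (the
  # z-coordinate is 4*cos(2t) + 0.1: 2 cycles/loop at factor 1, 4 at 2)
  dominant <- function(v) {
    sp <- Mod(fft(v - mean(v)))[2:10]
    which.max(sp)
  }
  expect_identical(dominant(s2$values[, 2]), 2L * dominant(s1$values[, 2]))
})

test_that("normalization bounds cover every curve and invert cleanly", {
  b <- default_norm_bounds()
  for (curve in c("cosine", "square", "circle")) {
    t <- seq(-pi + 1e-9, pi, length.out = 101)
    yz <- rnnpb:::curve_points(curve, t)[, c("y", "z")]
    norm <- rnnpb:::normalize_coords(yz, b)
    expect_true(all(norm >= 0.1 - 1e-12 & norm <= 0.9 + 1e-12))
    expect_equal(rnnpb:::denormalize_coords(norm, b), yz,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  s <- make_sequence("circle", "green", dataset_protocol(noise_sigma = 0,
                                                         curves = "circle"))
  den <- denormalize_values(s$values)
  expect_equal((den[, 3] - 0.04)^2 + (den[, 4] - 0.10)^2, rep(16, 20),
               ignore_attr = TRUE, tolerance = 1e-9)
})
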