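class_key <- function(curve, color) paste(curve, color, sep = "_")

sequence_class <- function(s) class_key(s$curve_label, s$color_label)

# Parse "curve_color[_rN]" ids coming from the PB table.
pb_table_classes <- function(pb_table) {
  parts <- strsplit(names(pb_table), "_", fixed = TRUE)
  vapply(parts, function(p) paste(p[1], p[2], sep = "_"), character(1))
}

#' Noise-free class prototype sequences
#'
#' One noiseless sequence per (curve, colour) combination of a protocol,
#' used as reference trajectories when classifying generated series.
#'
#' @param protocol A [dataset_protocol()].
#' @return Named list of `sensorimotor_sequence` objects keyed
#'   `"<curve>_<color>"`.
#' @export
class_prototypes <- function(protocol = dataset_protocol()) {
  proto <- protocol
  proto$noise_sigma <- 0
  out <- list()
  for (curve in protocol$curves)
    for (color in protocol$colors)
      out[[class_key(curve, color)]] <-
        make_sequence(curve, color, proto, seed = 0L,
                      id = class_key(curve, color))
  out
}

#' Per-class PB centroids of a trained model
#'
#' @param model An `rnnpb_model`.
#' @return Matrix, one row per class, columns as in [pb_table_matrix()].
#' @export
pb_centroids <- function(model) {
  pm <- pb_table_matrix(model$pb_table)
  cls <- pb_table_classes(model$pb_table)
  t(vapply(split.data.frame(pm, cls), colMeans, numeric(ncol(pm))))
}

# 1-D threshold separability: the two groups' ranges do not overlap.
threshold_separated <- function(values, group) {
  max(values[group]) < min(values[!group]) ||
    max(values[!group]) < min(values[group])
}

#' PB self-organization summary for a trained model
#'
#' Checks, on the final PB table, whether each 1-D PB axis separates the
#' colour classes and/or the curve classes by a single threshold.  The
#' expected structure is that the dorsal-attached group (pb2) separates
#' colours while the ventral-attached group (pb1) separates curve types;
#' `separated_any_assignment` also accepts the axes-swapped structure.
#'
#' @param model An `rnnpb_model` trained on a colour x curve dataset.
#' @return List of logicals: `pb1_curve`, `pb1_color`, `pb2_curve`,
#'   `pb2_color`, `separated_expected`, `separated_any_assignment`.
#' @export
pb_separation <- function(model) {
  pm <- pb_table_matrix(model$pb_table)
  cls <- pb_table_classes(model$pb_table)
  is_yellow <- grepl("yellow", cls)
  is_cosine <- grepl("cosine", cls)
  pb1 <- rowMeans(pm[, grep("^pb1", colnames(pm)), drop = FALSE])
  pb2 <- rowMeans(pm[, grep("^pb2", colnames(pm)), drop = FALSE])
  out <- list(pb1_curve = threshold_separated(pb1, is_cosine),
              pb1_color = threshold_separated(pb1, is_yellow),
              pb2_curve = threshold_separated(pb2, is_cosine),
              pb2_color = threshold_separated(pb2, is_yellow))
  out$separated_expected <- out$pb1_curve && out$pb2_color
  out$separated_any_assignment <- out$separated_expected ||
    (out$pb1_color && out$pb2_curve)
  out
}

pb_flat <- function(pb) c(pb$rho1, pb$rho2)

#' Recognition class-recovery experiment
#'
#' Generates held-out noisy sequences (new seeds), infers their PB values
#' with frozen weights, and assigns each to the nearest (Euclidean) trained
#' per-class PB centroid.
#'
#' @param model A trained `rnnpb_model`.
#' @param protocol Protocol used to generate the held-out sequences.
#' @param reps Held-out repetitions per class.
#' @param seed Base seed for the held-out noise.
#' @param cfg A [recognition_config()].
#' @return List with `assignments` (data frame: id, true class, assigned
#'   class, recognized rho values), `accuracy` (fraction correct) and `pbs`.
#' @export
recognition_experiment <- function(model, protocol = dataset_protocol(),
                                   reps = 5L, seed = 1000L,
                                   cfg = recognition_config()) {
  centroids <- pb_centroids(model)
  held <- make_dataset(dataset_protocol(
    reps_per_class = reps, colors = protocol$colors,
    curves = protocol$curves, points_per_loop = protocol$points_per_loop,
    noise_sigma = protocol$noise_sigma, base_seed = seed,
    speed_factor = protocol$speed_factor,
    cosine_y_form = protocol$cosine_y_form))
  recs <- lapply(held, recognize_sequence, model = model, cfg = cfg)
  assignments <- do.call(rbind, lapply(seq_along(held), function(i) {
    v <- pb_flat(recs[[i]]$pb)
    d <- apply(centroids, 1, function(ct) sqrt(sum((v - ct)^2)))
    data.frame(sequence_id = held[[i]]$sequence_id,
               true = sequence_class(held[[i]]),
               assigned = rownames(centroids)[which.min(d)],
               epochs = recs[[i]]$epochs, stringsAsFactors = FALSE)
  }))
  list(assignments = assignments,
       accuracy = mean(assignments$true == assignments$assigned),
       pbs = lapply(recs, `[[`, "pb"))
}

#' Closed-loop prediction experiment (per-unit error table)
#'
#' For one held-out noisy sequence per class: recognize its PB with frozen
#' weights, then generate the whole series closed-loop from the first
#' observed frame and compare against the observed series.  Reports the
#' per-unit mean squared error (normalized units) and the per-step error
#' profile used for the early-transient check.
#'
#' @param model A trained `rnnpb_model`.
#' @param protocol Generation protocol for the held-out sequences.
#' @param seed Base seed for the held-out noise.
#' @param cfg A [recognition_config()].
#' @return List with `error_table` (classes x units matrix of MSE),
#'   `per_step` (list of per-step mean squared errors per class) and
#'   `transient_ok` (named logical: mean error of steps 1-3 exceeds the
#'   mean error of the remaining steps).
#' @export
prediction_experiment <- function(model, protocol = dataset_protocol(),
                                  seed = 2000L,
                                  cfg = recognition_config()) {
  held <- make_dataset(dataset_protocol(
    reps_per_class = 1L, colors = protocol$colors, curves = protocol$curves,
    points_per_loop = protocol$points_per_loop,
    noise_sigma = protocol$noise_sigma, base_seed = seed,
    speed_factor = protocol$speed_factor,
    cosine_y_form = protocol$cosine_y_form))
  classes <- vapply(held, sequence_class, character(1))
  err <- matrix(NA_real_, length(held), model$config$n_out,
                dimnames = list(classes,
                                sprintf("unit%d", seq_len(model$config$n_out))))
  per_step <- list()
  transient_ok <- logical(length(held))
  names(transient_ok) <- classes
  for (i in seq_along(held)) {
    x <- held[[i]]$values
    rec <- recognize_sequence(model, held[[i]], cfg)
    gen <- predict_closed_loop(model, rec$pb, x[1, ], nrow(x) - 1L)
    truth <- x[-1, , drop = FALSE]
    err[i, ] <- evaluate_prediction(gen, truth)
    es <- rowMeans((gen - truth)^2)
    per_step[[classes[i]]] <- es
    transient_ok[i] <- mean(es[1:3]) > mean(es[-(1:3)])
  }
  list(error_table = err, per_step = per_step, transient_ok = transient_ok)
}

#' Generalization experiment: recognizing an untrained curve
#'
#' Runs recognition on circle-curve sequences with weights trained on
#' cosine/square only, and reports whether the inferred PB values are
#' finite and how their sign pattern compares to the trained square-class
#' centroids (reported, not asserted: the sign assignment depends on the
#' random initial weights).
#'
#' @param model A trained `rnnpb_model`.
#' @param protocol Generation protocol (colours/noise reused; the curve is
#'   forced to circle).
#' @param seed Base seed for the circle-sequence noise.
#' @param cfg A [recognition_config()].
#' @return List with per-colour recognized PB values, `finite` flag, and
#'   `sign_matches_square` (fraction of PB components whose sign equals the
#'   square-class centroid's sign).
#' @export
generalization_experiment <- function(model, protocol = dataset_protocol(),
                                      seed = 3000L,
                                      cfg = recognition_config()) {
  centroids <- pb_centroids(model)
  res <- list()
  for (color in protocol$colors) {
    s <- make_sequence("circle", color,
                       dataset_protocol(
                         reps_per_class = 1L, colors = color,
                         curves = "circle",
                         points_per_loop = protocol$points_per_loop,
                         noise_sigma = protocol$noise_sigma,
                         base_seed = seed,
                         cosine_y_form = protocol$cosine_y_form),
                       seed = derive_seed(seed, match(color, COLOR_NAMES)))
    rec <- recognize_sequence(model, s, cfg)
    v <- pb_flat(rec$pb)
    sq <- centroids[class_key("square", color), ]
    res[[color]] <- list(pb = v, finite = all(is.finite(v)),
                         epochs = rec$epochs,
                         sign_matches_square = mean(sign(v) == sign(sq)))
  }
  res
}

#' Bifurcation check: the PB vector selects the generated class
#'
#' For each colour, generates closed-loop series from the cosine
#' prototype's first frame using (a) the cosine-class PB centroid and (b)
#' the square-class PB centroid, and vice versa, and classifies each
#' generated series by RMSE against the noiseless class prototypes
#' (steps after the 3-step transient).  Returns `TRUE` when every
#' generated series is assigned to the class of the PB vector driving it.
#'
#' @param model A trained `rnnpb_model`.
#' @param protocol Generation protocol (for the prototypes).
#' @return List with `ok` (logical) and `detail` (data frame of cases).
#' @export
bifurcation_check <- function(model, protocol = dataset_protocol()) {
  protos <- class_prototypes(protocol)
  centroids <- pb_centroids(model)
  n_pb1 <- model$config$n_pb1
  cases <- expand.grid(color = protocol$colors,
                       init_curve = protocol$curves,
                       pb_curve = protocol$curves,
                       stringsAsFactors = FALSE)
  assign_class <- function(gen) {
    skip <- min(3L, nrow(gen) - 1L)
    rmse <- vapply(protos, function(p) {
      truth <- p$values[-1, , drop = FALSE]
      sqrt(mean((gen[-seq_len(skip), ] -
                   truth[-seq_len(skip), , drop = FALSE])^2))
    }, numeric(1))
    names(protos)[which.min(rmse)]
  }
  cases$assigned <- NA_character_
  for (i in seq_len(nrow(cases))) {
    init <- protos[[class_key(cases$init_curve[i], cases$color[i])]]
    ct <- centroids[class_key(cases$pb_curve[i], cases$color[i]), ]
    pb <- pb_vector(ct[seq_len(n_pb1)], ct[-seq_len(n_pb1)])
    gen <- predict_closed_loop(model, pb, init$values[1, ],
                               nrow(init$values) - 1L)
    cases$assigned[i] <- assign_class(gen)
  }
  cases$expected <- class_key(cases$pb_curve, cases$color)
  list(ok = all(cases$assigned == cases$expected), detail = cases)
}

#' Run the full reproduction protocol
#'
#' Drives every experiment of the study protocol: trains `n_seeds`
#' independent models (fresh dataset noise and weight initialization per
#' seed) on the 20-sequence colour x curve dataset, evaluates PB
#' self-organization and the PB bifurcation property per seed, and on the
#' first model runs the recognition-recovery, closed-loop prediction
#' (error-table), circle-curve generalization and speed-variant
#' experiments.
#'
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @param n_seeds Number of independent training replicates.
#' @param protocol Dataset protocol (the study conditions).
#' @param config Network configuration.
#' @param params Training parameters.
#' @param speed Speed factor of the speed-variant experiment.
#' @param progress Print one line per completed stage.
#' @return An `rnnpb_reproduction` list; see [reproduce_report()].
#' @export
run_reproduction <- function(seed = 1L, n_seeds = 10L,
                             protocol = dataset_protocol(),
                             config = network_config(),
                             params = training_params(),
                             speed = 2, progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  replicates <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    s_r <- derive_seed(seed, r)
    prot_r <- protocol
    prot_r$base_seed <- s_r
    model <- train_network(make_dataset(prot_r), config, params,
                           seed = s_r)
    replicates[[r]] <- list(
      seed = s_r, model = if (r == 1L) model else NULL,
      pb_table = pb_table_matrix(model$pb_table),
      final_cost = model$report$cost_per_epoch[model$report$epochs_run],
      separation = pb_separation(model),
      bifurcation = bifurcation_check(model, protocol))
    say("replicate %d/%d done (seed %d, final cost %.4g)", r, n_seeds,
        s_r, replicates[[r]]$final_cost)
  }
  model1 <- replicates[[1]]$model
  recog <- recognition_experiment(model1, protocol,
                                  seed = derive_seed(seed, 1001L))
  say("recognition accuracy: %.0f%%", 100 * recog$accuracy)
  pred <- prediction_experiment(model1, protocol,
                                seed = derive_seed(seed, 2001L))
  gener <- generalization_experiment(model1, protocol,
                                     seed = derive_seed(seed, 3001L))
  prot_speed <- speed_variant(protocol, speed)
  prot_speed$base_seed <- derive_seed(seed, 4001L)
  speed_model <- train_network(make_dataset(prot_speed), config, params,
                               seed = prot_speed$base_seed)
  say("speed-variant training done")
  structure(list(seed = seed, n_seeds = n_seeds, protocol = protocol,
                 replicates = replicates, model = model1,
                 recognition = recog, prediction = pred,
                 generalization = gener,
                 speed_variant = list(
                   factor = speed,
                   pb_table = pb_table_matrix(speed_model$pb_table),
                   separation = pb_separation(speed_model))),
            class = "rnnpb_reproduction")
}

#' Summarize a reproduction run
#'
#' Collates the scatter of trained PB values (per sequence, with labels),
#' the per-seed self-organization and bifurcation outcomes, the
#' recognition-recovery accuracy, the per-class per-unit prediction error
#' table and the early-transient/generalization findings into plain data
#' frames plus a named numeric summary.
#'
#' @param results An `rnnpb_reproduction` from [run_reproduction()].
#' @return List with `pb_points` (data frame of PB scatter data),
#'   `per_seed` (data frame), `error_table` (matrix), `summary` (named
#'   numeric vector).
#' @export
reproduce_report <- function(results) {
  pb_points <- do.call(rbind, lapply(results$replicates, function(r) {
    data.frame(seed = r$seed, sequence_id = rownames(r$pb_table),
               pb1 = rowMeans(r$pb_table[, grep("^pb1",
                 colnames(r$pb_table)), drop = FALSE]),
               pb2 = rowMeans(r$pb_table[, grep("^pb2",
                 colnames(r$pb_table)), drop = FALSE]),
               curve = sub("_.*", "", rownames(r$pb_table)),
               color = sub("_r[0-9]+$", "",
                           sub("^[a-z]+_", "", rownames(r$pb_table))),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  per_seed <- do.call(rbind, lapply(results$replicates, function(r)
    data.frame(seed = r$seed, final_cost = r$final_cost,
               sep_expected = r$separation$separated_expected,
               sep_any = r$separation$separated_any_assignment,
               bifurcation = r$bifurcation$ok)))
  summary <- c(
    n_train_sequences = length(results$model$pb_table),
    sequence_length = results$protocol$points_per_loop,
    seeds_run = results$n_seeds,
    pb_separation_seeds = sum(per_seed$sep_any),
    pb_separation_seeds_expected_axes = sum(per_seed$sep_expected),
    bifurcation_seeds = sum(per_seed$bifurcation),
    recognition_accuracy = results$recognition$accuracy,
    pred_mse_min = min(results$prediction$error_table),
    pred_mse_max = max(results$prediction$error_table),
    transient_classes_ok = sum(results$prediction$transient_ok),
    generalization_finite =
      all(vapply(results$generalization, `[[`, logical(1), "finite")))
  list(pb_points = pb_points, per_seed = per_seed,
       error_table = results$prediction$error_table, summary = summary)
}
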