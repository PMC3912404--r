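#' Presenter-frame trajectory curves
#'
#' Parametric curves traced by the presenter's end-effector in its torso
#' frame (abstract length units; the depth coordinate is fixed at x = 12 so
#' each curve lives in the frontal y-z plane).  The phase `t` loops over
#' (-pi, pi].
#'
#' * `cosine_curve()`: a cosine in z drawn against a linear ramp in y,
#'   `y = 8*(-t/2) + 0.04`, `z = 4*cos(2t) + 0.10`.  Set
#'   `y_form = "quadratic"` for the alternative reading
#'   `y = 8*(-t^2) + 0.04`.
#' * `square_curve()`: a closed piecewise-linear square loop in (y, z) with
#'   slopes +/-16/pi, corners (0, 14), (8, 14), (8, 6), (0, 6).
#' * `circle_curve()`: a circle of radius 4 centred at (0.04, 0.10),
#'   `y = 4*sin(2t) + 0.04`, `z = 4*cos(2t) + 0.10`.
#'
#' @param t Numeric vector of phases in (-pi, pi].
#' @param y_form For the cosine curve only: `"linear"` (default) or
#'   `"quadratic"` sweep along y.
#' @return A `length(t)` x 3 matrix with columns `x`, `y`, `z`.
#' @export
cosine_curve <- function(t, y_form = c("linear", "quadratic")) {
  y_form <- match.arg(y_form)
  check_phase(t)
  y <- if (y_form == "linear") 8 * (-t / 2) + 0.04 else 8 * (-t^2) + 0.04
  cbind(x = rep(12, length(t)), y = y, z = 4 * cos(2 * t) + 0.10)
}

#' @rdname cosine_curve
#' @export
square_curve <- function(t) {
  check_phase(t)
  k <- 16 / pi
  y <- ifelse(t <= -3 * pi / 4, 0,
       ifelse(t <= -pi / 4, k * t + 12,
       ifelse(t <= pi / 4, 8,
       ifelse(t <= 3 * pi / 4, -k * t + 12, 0))))
  # First branch intercept is 26 (not the printed 20): the unique value that
  # joins the constant branch z = 14 at t = -3pi/4 and closes the loop
  # across the t = +/-pi wrap (z -> 10 on both sides).
  z <- ifelse(t <= -3 * pi / 4, k * t + 26,
       ifelse(t <= -pi / 4, 14,
       ifelse(t <= pi / 4, -k * t + 10,
       ifelse(t <= 3 * pi / 4, 6, k * t - 6))))
  cbind(x = rep(12, length(t)), y = y, z = z)
}

#' @rdname cosine_curve
#' @export
circle_curve <- function(t) {
  check_phase(t)
  cbind(x = rep(12, length(t)),
        y = 4 * sin(2 * t) + 0.04,
        z = 4 * cos(2 * t) + 0.10)
}

check_phase <- function(t) {
  if (any(!is.finite(t))) stop("phase values must be finite")
  # the domain is open at -pi (exactly -pi is rejected); a hair of slack on
  # the closed end tolerates wrap-around rounding at +pi
  if (any(t <= -pi) || any(t > pi + 1e-12))
    stop("phase t must lie in (-pi, pi]")
  invisible(t)
}

CURVE_NAMES <- c("cosine", "square", "circle")
COLOR_NAMES <- c("yellow", "green")

curve_points <- function(curve, t, y_form = "linear") {
  switch(curve,
         cosine = cosine_curve(t, y_form),
         square = square_curve(t),
         circle = circle_curve(t),
         stop(sprintf("unknown curve '%s'; valid curves: %s", curve,
                      paste(CURVE_NAMES, collapse = ", "))))
}

#' Fixed input-normalization bounds
#'
#' Per-coordinate affine bounds mapping the curves' (y, z) ranges into the
#' interval used by the network inputs, `[0.1, 0.9]`.  The bounds are
#' computed from the generating equations themselves (extremes over the
#' cosine, square and circle curves) so that every noise-free trajectory
#' normalizes inside the target interval; they are stored with the model so
#' recognition/prediction reuse them.
#'
#' @param y_form Reading of the cosine y-sweep, see [cosine_curve()]; the
#'   quadratic reading widens the horizontal bound.
#' @return 2 x 2 matrix: rows `lo`, `hi`; columns `h` (horizontal, curve y)
#'   and `v` (vertical, curve z).
#' @export
default_norm_bounds <- function(y_form = c("linear", "quadratic")) {
  y_form <- match.arg(y_form)
  y_lo <- if (y_form == "linear") -4 * pi + 0.04 else -8 * pi^2 + 0.04
  y_hi <- if (y_form == "linear") 4 * pi + 0.04 else 0.04
  matrix(c(y_lo, y_hi, -3.9, 14), 2, 2,
         dimnames = list(c("lo", "hi"), c("h", "v")))
}

NORM_TARGET <- c(0.1, 0.9)

normalize_coords <- function(yz, bounds) {
  t(apply(yz, 1, function(p) {
    NORM_TARGET[1] + (p - bounds["lo", ]) / (bounds["hi", ] - bounds["lo", ]) *
      diff(NORM_TARGET)
  }))
}

denormalize_coords <- function(yz, bounds) {
  t(apply(yz, 1, function(p) {
    bounds["lo", ] + (p - NORM_TARGET[1]) / diff(NORM_TARGET) *
      (bounds["hi", ] - bounds["lo", ])
  }))
}

#' Dataset generation protocol
#'
#' Describes how a synthetic training/evaluation set is generated: which
#' colours and curve types, how many repetitions of each combination, how
#' many samples per phase loop, the additive observation-noise level, and
#' the base seed from which per-sequence seeds are derived.
#'
#' @param reps_per_class Repetitions per (colour, curve) combination.
#' @param colors Subset of `c("yellow", "green")`.
#' @param curves Subset of `c("cosine", "square", "circle")`.
#' @param points_per_loop Samples per phase loop; also the sequence length T
#'   (T is kept fixed when the speed factor changes).
#' @param noise_sigma SD of the additive Gaussian observation noise, in
#'   normalized units, applied to the active colour layer only.
#' @param base_seed Integer seed from which each sequence's own seed is
#'   derived deterministically.
#' @param speed_factor Phase-step multiplier, see [speed_variant()].
#' @param cosine_y_form Reading of the cosine y-sweep, see [cosine_curve()].
#' @return An object of class `rnnpb_protocol`.
#' @export
dataset_protocol <- function(reps_per_class = 5L,
                             colors = c("yellow", "green"),
                             curves = c("cosine", "square"),
                             points_per_loop = 20L,
                             noise_sigma = 0.01,
                             base_seed = 1L,
                             speed_factor = 1,
                             cosine_y_form = "linear") {
  colors <- match.arg(colors, COLOR_NAMES, several.ok = TRUE)
  curves <- match.arg(curves, CURVE_NAMES, several.ok = TRUE)
  if (reps_per_class < 1) stop("reps_per_class must be >= 1")
  if (points_per_loop < 2) stop("points_per_loop must be >= 2")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (speed_factor <= 0) stop("speed_factor must be positive")
  structure(list(reps_per_class = as.integer(reps_per_class),
                 colors = colors, curves = curves,
                 points_per_loop = as.integer(points_per_loop),
                 noise_sigma = noise_sigma,
                 base_seed = as.integer(base_seed),
                 speed_factor = speed_factor,
                 cosine_y_form = cosine_y_form),
            class = "rnnpb_protocol")
}

#' Speed-variant protocol
#'
#' Returns a copy of `protocol` whose phase step is multiplied by
#' `speed_factor` while the sequence length T stays fixed: the apparent
#' motion is faster, each loop is sampled at fewer phases, and the phase
#' wraps around (-pi, pi] over multiple loops.
#'
#' @param protocol A [dataset_protocol()].
#' @param speed_factor Positive multiplier of the phase step.
#' @return A new `rnnpb_protocol`.
#' @export
speed_variant <- function(protocol, speed_factor) {
  if (!is.numeric(speed_factor) || length(speed_factor) != 1 ||
      !is.finite(speed_factor) || speed_factor <= 0)
    stop("speed_factor must be a positive number")
  protocol$speed_factor <- protocol$speed_factor * speed_factor
  protocol
}

# Wrap phases into (-pi, pi].
wrap_phase <- function(t) {
  u <- (t + pi) %% (2 * pi)
  ifelse(u == 0, pi, u - pi)
}

sequence_phases <- function(protocol) {
  step <- 2 * pi / protocol$points_per_loop * protocol$speed_factor
  wrap_phase(-pi + step * seq_len(protocol$points_per_loop))
}

#' Generate one channel-encoded sensorimotor sequence
#'
#' Samples `points_per_loop` phases evenly over (-pi, pi], evaluates the
#' requested curve, projects the 3-D presenter-frame point orthographically
#' onto the observer's image plane as the (y, z) pair, normalizes with the
#' fixed bounds, places the 2-D observation into colour layer 1 (yellow,
#' columns 1-2) or layer 2 (green, columns 3-4) with the other layer zero,
#' and adds seeded Gaussian noise (sd `noise_sigma`) to the active layer to
#' emulate noisy position control of the presenter's end-effector.
#'
#' @param curve One of `"cosine"`, `"square"`, `"circle"`.
#' @param color One of `"yellow"`, `"green"`.
#' @param protocol A [dataset_protocol()].
#' @param seed Integer seed for the observation noise.
#' @param id Sequence identifier string.
#' @return An object of class `sensorimotor_sequence` with fields `values`
#'   (T x 4 normalized matrix), `color_label`, `curve_label`, `sequence_id`,
#'   `seed`.
#' @export
make_sequence <- function(curve, color, protocol = dataset_protocol(),
                          seed = protocol$base_seed,
                          id = paste(curve, color, sep = "_")) {
  curve <- match.arg(curve, CURVE_NAMES)
  color <- match.arg(color, COLOR_NAMES)
  t <- sequence_phases(protocol)
  pts <- curve_points(curve, t, protocol$cosine_y_form)
  bounds <- default_norm_bounds(protocol$cosine_y_form)
  yz <- normalize_coords(pts[, c("y", "z"), drop = FALSE], bounds)
  values <- matrix(0, nrow(yz), 4,
                   dimnames = list(NULL, c("in1", "in2", "in3", "in4")))
  cols <- if (color == "yellow") 1:2 else 3:4
  values[, cols] <- yz
  if (protocol$noise_sigma > 0) {
    set.seed(seed)
    values[, cols] <- values[, cols] +
      rnorm(length(yz), sd = protocol$noise_sigma)
  }
  structure(list(values = values, color_label = color, curve_label = curve,
                 sequence_id = id, seed = as.integer(seed), phases = t,
                 norm_bounds = bounds),
            class = "sensorimotor_sequence")
}

#' @export
print.sensorimotor_sequence <- function(x, ...) {
  cat(sprintf("Sensorimotor sequence '%s': %d steps, %s %s curve\n",
              x$sequence_id, nrow(x$values), x$color_label, x$curve_label))
  invisible(x)
}

# Deterministic per-sequence seed derivation, kept inside 32-bit range.
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 131 + index * 9973) %% 2147483647)
}

#' Generate a full dataset under a protocol
#'
#' Produces `reps_per_class * length(colors) * length(curves)` sequences
#' with unique ids and distinct per-sequence noise seeds derived from
#' `protocol$base_seed`.  With the defaults (5 repetitions x 2 colours x
#' 2 curves, 20 steps) this is the 20-sequence training set.
#'
#' @param protocol A [dataset_protocol()].
#' @return List of [make_sequence()] objects.
#' @export
make_dataset <- function(protocol = dataset_protocol()) {
  combos <- expand.grid(rep = seq_len(protocol$reps_per_class),
                        color = protocol$colors, curve = protocol$curves,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    make_sequence(combos$curve[i], combos$color[i], protocol,
                  seed = derive_seed(protocol$base_seed, i),
                  id = sprintf("%s_%s_r%d", combos$curve[i], combos$color[i],
                               combos$rep[i]))
  })
}

#' Denormalize a value matrix back to presenter-frame coordinates
#'
#' Inverts the fixed affine normalization for reporting: columns 1-2 and
#' 3-4 are mapped back through the horizontal/vertical bounds.
#'
#' @param values T x 4 matrix in normalized units.
#' @param bounds Normalization bounds, see [default_norm_bounds()].
#' @return T x 4 matrix in curve coordinates.
#' @export
denormalize_values <- function(values, bounds = default_norm_bounds()) {
  out <- values
  out[, 1:2] <- denormalize_coords(values[, 1:2, drop = FALSE], bounds)
  out[, 3:4] <- denormalize_coords(values[, 3:4, drop = FALSE], bounds)
  out
}
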