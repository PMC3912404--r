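SEQUENCE_CSV_COLUMNS <- c("sequence_id", "t_index", "in1", "in2", "in3",
                          "in4", "color_label", "curve_label")

#' Write/read sequence CSV files
#'
#' One row per time step, columns `sequence_id, t_index, in1..in4,
#' color_label, curve_label`, header mandatory.  Values are written with 15
#' significant digits, so a write/read round trip is lossless well beyond
#' 12 significant digits.
#'
#' @param dataset List of `sensorimotor_sequence` objects.
#' @param path File path.
#' @return `write_sequences_csv()` returns `path` invisibly;
#'   `read_sequences_csv()` returns a list of `sensorimotor_sequence`
#'   objects (generation metadata such as per-sequence seeds is not stored
#'   in the file and comes back as `NA`).
#' @export
write_sequences_csv <- function(dataset, path) {
  rows <- do.call(rbind, lapply(dataset, function(s) {
    v <- sequence_values(s)
    data.frame(sequence_id = s$sequence_id, t_index = seq_len(nrow(v)),
               in1 = v[, 1], in2 = v[, 2], in3 = v[, 3], in4 = v[, 4],
               color_label = s$color_label, curve_label = s$curve_label,
               stringsAsFactors = FALSE)
  }))
  num <- vapply(rows, is.double, logical(1))
  rows[num] <- lapply(rows[num], function(x) sprintf("%.15g", x))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @export
read_sequences_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("sequence file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SEQUENCE_CSV_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("malformed sequence CSV, missing columns: %s",
                 paste(missing, collapse = ", ")))
  lapply(split(df, factor(df$sequence_id, levels = unique(df$sequence_id))),
         function(d) {
           d <- d[order(d$t_index), ]
           values <- as.matrix(d[, c("in1", "in2", "in3", "in4")])
           dimnames(values) <- list(NULL, c("in1", "in2", "in3", "in4"))
           structure(list(values = values, color_label = d$color_label[1],
                          curve_label = d$curve_label[1],
                          sequence_id = d$sequence_id[1], seed = NA_integer_,
                          phases = NULL, norm_bounds = NULL),
                     class = "sensorimotor_sequence")
         })
}

MODEL_FORMAT <- "rnnpb-model"
MODEL_FORMAT_VERSION <- 1L

# Matrices are stored as {dim, data} (column-major) so the round trip does
# not depend on jsonlite's matrix simplification rules.
encode_matrix <- function(m) list(dim = dim(m), data = as.vector(m))
decode_matrix <- function(e) matrix(unlist(e$data), unlist(e$dim)[1],
                                    unlist(e$dim)[2])

#' Save/load a trained model archive
#'
#' The archive is a single self-describing, format-versioned JSON document
#' holding the network configuration, training parameters, all eight weight
#' matrices as nested decimal arrays, the per-sequence PB table and the
#' normalization bounds.  Numbers are written at full precision, so a
#' save/load round trip reproduces every value exactly.
#'
#' @param model An `rnnpb_model`.
#' @param path File path (conventionally `.json`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the reconstructed `rnnpb_model` (without the training report, which is
#'   logged separately).
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = MODEL_FORMAT, format_version = MODEL_FORMAT_VERSION,
    config = unclass(model$config),
    params = unclass(model$params),
    seed = model$seed,
    weights = lapply(model$weights[WEIGHT_NAMES], encode_matrix),
    norm_bounds = encode_matrix(model$weights$norm_bounds),
    pb_table = lapply(model$pb_table,
                      function(p) list(rho1 = p$rho1, rho2 = p$rho2)))
  # digits = I(17): shortest decimal that round-trips IEEE doubles exactly
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop(sprintf("cannot parse model archive %s: %s",
                                 path, conditionMessage(e))))
  if (!identical(doc$format, MODEL_FORMAT))
    stop(sprintf("not a model archive: %s", path))
  if (!identical(as.integer(doc$format_version), MODEL_FORMAT_VERSION))
    stop(sprintf("unsupported model archive version %s", doc$format_version))
  config <- do.call(network_config,
                    doc$config[c("n_in", "n_d", "n_v", "n_pb1", "n_pb2")])
  params <- do.call(training_params,
                    doc$params[setdiff(names(doc$params), character(0))])
  nb <- decode_matrix(doc$norm_bounds)
  dimnames(nb) <- list(c("lo", "hi"), c("h", "v"))
  weights <- random_weights(config, init = "zero", norm_bounds = nb)
  for (nm in WEIGHT_NAMES) weights[[nm]] <- decode_matrix(doc$weights[[nm]])
  check_weights(weights)
  pb_table <- lapply(doc$pb_table,
                     function(p) pb_vector(unlist(p$rho1), unlist(p$rho2)))
  structure(list(weights = weights, pb_table = pb_table, report = NULL,
                 config = config, params = params,
                 seed = as.integer(doc$seed)),
            class = "rnnpb_model")
}
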