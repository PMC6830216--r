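# The 3D-CNN resolution regressor: build / train / checkpoint / predict.
#
# Architecture (fixed): conv(32 filters, 13x13x13, 'same' zero padding,
# ReLU) -> dropout(0.25, training only, applied to the conv output)
# -> flatten -> dense(512, ReLU) -> dense(1, linear). Loss: MSE on the
# Angstrom-valued label; optimizer: Adam. The compute core lives in
# src/nn.cpp (float32, im2col + BLAS).

#' Network architecture configuration
#'
#' The topology is fixed; this object exists to document and validate it
#' (any deviation is rejected rather than silently accepted).
#'
#' @param conv_filters number of conv filters (32).
#' @param conv_kernel conv kernel edge in voxels (13).
#' @param dense_units hidden dense width (512).
#' @param dropout_p dropout probability on the conv output (0.25).
#' @return A `network_config`.
#' @export
network_config <- function(conv_filters = 32L, conv_kernel = 13L,
                           dense_units = 512L, dropout_p = 0.25) {
  if (conv_filters != 32L || conv_kernel != 13L || dense_units != 512L)
    stop_validation("the architecture is fixed: conv(32 x 13^3) -> ",
                    "dropout -> dense(512) -> dense(1)")
  if (dropout_p < 0 || dropout_p >= 1)
    stop_validation("dropout_p must lie in [0, 1)")
  structure(list(conv_filters = 32L, conv_kernel = 13L, dense_units = 512L,
                 output_units = 1L, activation = "relu",
                 dropout_p = dropout_p, padding = "same"),
            class = "network_config")
}

#' Training configuration
#'
#' Optimizer and loss are fixed (Adam, MSE); the remaining hyperparameters
#' are free. Defaults follow the full-scale recipe (lr 1e-4, batch 256);
#' desk-scale corpora want a larger learning rate and smaller batch (the
#' packaged experiments use lr 1e-3, batch 32).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param validation_fraction held-out fraction for the per-epoch
#'   validation loss (split deterministically under `seed`).
#' @param seed seed fixing initialization order, shuffling and dropout.
#' @param warmup_steps linear learning-rate warmup over this many Adam
#'   steps (0 disables; default 100). Adam moves millions of coordinates
#'   near-coherently, which from a cold start swings the output wildly;
#'   the ramp spends the first steps settling instead of recovering.
#' @param augment rotate/flip each box by a random octahedral symmetry at
#'   every presentation (off by default). The 48 cube symmetries are
#'   exactly label-preserving (the filter bank is radially symmetric), so
#'   this multiplies effective corpus diversity at no extraction cost -
#'   essential for small corpora, irrelevant at full scale.
#' @return A `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 256L,
                            epochs = 20L, validation_fraction = 0.1,
                            seed = 1L, warmup_steps = 100,
                            augment = FALSE) {
  if (learning_rate <= 0) stop_validation("learning_rate must be > 0")
  if (batch_size < 1) stop_validation("batch_size must be >= 1")
  if (epochs < 1) stop_validation("epochs must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop_validation("validation_fraction must lie in [0, 1)")
  if (warmup_steps < 0) stop_validation("warmup_steps must be >= 0")
  structure(list(optimizer = "adam", loss = "mse",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), warmup_steps = warmup_steps,
                 augment = isTRUE(augment)),
            class = "training_config")
}

#' Build an (untrained) regressor
#'
#' He-initialized weights under a fixed seed; the output bias starts at the
#' centre of the band's label range so early training is not spent walking
#' the bias from zero.
#'
#' @param band a [band_spec()]; the regressor may only ever be applied to
#'   maps resampled to this band's voxel size.
#' @param config a [network_config()].
#' @param seed initialization seed.
#' @return A `voxres_regressor` (untrained).
#' @export
build_regressor <- function(band = wide_band(), config = network_config(),
                            seed = 1L) {
  stopifnot(inherits(band, "band_spec"), inherits(config, "network_config"))
  label_range <- c(band$bank$d_min, band$bank$d_max)
  w <- nn_init_cpp(as.integer(seed), mean(label_range))
  structure(list(weights = w[c("Wc", "bc", "W1", "b1", "W2", "b2")],
                 band = band, label_range = label_range, config = config,
                 trained = FALSE, history = NULL,
                 provenance = list(init_seed = as.integer(seed))),
            class = "voxres_regressor")
}

#' @export
print.voxres_regressor <- function(x, ...) {
  cat(sprintf(paste0("<voxres_regressor: conv(32x13^3)->dense(512)->dense(1), ",
                     "band %.2g A/voxel, labels [%.3g, %.3g] A, %s>\n"),
              x$band$voxel_size, x$label_range[1], x$label_range[2],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Train the regressor on a labeled-box corpus
#'
#' Minimizes MSE with Adam; dropout active in training only; a validation
#' split is held out deterministically under the training seed. Labels
#' outside the regressor's band range are an error (they could never be
#' produced by the band's filter bank).
#'
#' @param reg a `voxres_regressor`.
#' @param boxes a `labeled_boxes` corpus (see [extract_training_boxes()],
#'   [make_corpus()]).
#' @param tc a [training_config()].
#' @return The trained `voxres_regressor` with `$history` (per-epoch train
#'   and validation MSE).
#' @export
train_regressor <- function(reg, boxes, tc = training_config()) {
  stopifnot(inherits(reg, "voxres_regressor"),
            inherits(boxes, "labeled_boxes"),
            inherits(tc, "training_config"))
  n <- ncol(boxes$cubes)
  if (n == 0L) stop_validation("empty training corpus")
  bad <- boxes$labels < reg$label_range[1] - 1e-9 |
         boxes$labels > reg$label_range[2] + 1e-9
  if (any(bad))
    stop_validation("label ", boxes$labels[which(bad)[1]],
                    " A outside the regressor band [",
                    reg$label_range[1], ", ", reg$label_range[2], "] A")
  out <- nn_train_cpp(boxes$cubes, boxes$labels, reg$weights,
                      tc$epochs, min(tc$batch_size, n), tc$learning_rate,
                      reg$config$dropout_p, tc$validation_fraction, tc$seed,
                      tc$warmup_steps, tc$augment)
  reg$weights <- out[c("Wc", "bc", "W1", "b1", "W2", "b2")]
  reg$trained <- TRUE
  reg$history <- data.frame(epoch = seq_along(out$train_loss),
                            train_mse = unlist(out$train_loss),
                            val_mse = unlist(out$val_loss))
  reg$provenance$training <- list(
    n_boxes = n, config = unclass(tc),
    label_counts = as.list(table(boxes$labels)),
    corpus_hash = corpus_hash(boxes))
  reg
}

# cheap deterministic content hash (sum-based; provenance, not security)
corpus_hash <- function(boxes) {
  v <- c(dim(boxes$cubes), sum(boxes$cubes), sum(boxes$cubes^2),
         sum(boxes$labels))
  paste(signif(v, 12), collapse = "-")
}

#' Predict resolutions for a set of unit-norm cubes
#'
#' Deterministic given the weights (dropout disabled). Cubes violating the
#' unit-norm training contract (deviation > 1e-3) are an error. Outputs are
#' clipped to the band's label range; the fraction clipped is attached as
#' an attribute since values at the clip boundary signal extrapolation.
#'
#' @param reg a trained `voxres_regressor`, or any function
#'   `f(cubes_matrix) -> numeric` (useful for stub predictors in tests).
#' @param cubes 2197 x n matrix of unit-norm cubes (or a `labeled_boxes`).
#' @return Numeric vector of Angstrom predictions, attribute
#'   `clipped_fraction`.
#' @export
predict_cubes <- function(reg, cubes) {
  if (inherits(cubes, "labeled_boxes")) cubes <- cubes$cubes
  if (is.function(reg)) return(reg(cubes))
  stopifnot(inherits(reg, "voxres_regressor"))
  if (!is.matrix(cubes) || nrow(cubes) != BOX_LEN)
    stop_validation("cubes must be a ", BOX_LEN, " x n matrix")
  if (ncol(cubes) == 0L) return(numeric(0))
  dev <- abs(sqrt(colSums(cubes^2)) - 1)
  if (any(dev > 1e-3))
    stop_validation("cube ", which.max(dev), " deviates from unit norm by ",
                    signif(max(dev), 3), " (> 1e-3): inputs must be ",
                    "normalized exactly as in training")
  p <- nn_predict_cpp(reg$weights, cubes)
  clipped <- p < reg$label_range[1] | p > reg$label_range[2]
  p <- pmin(pmax(p, reg$label_range[1]), reg$label_range[2])
  attr(p, "clipped_fraction") <- mean(clipped)
  p
}

#' Save / load a regressor checkpoint
#'
#' The checkpoint carries the weights plus the band metadata and training
#' provenance needed for valid inference. Stored via R serialization.
#'
#' @param reg a `voxres_regressor`.
#' @param path checkpoint path.
#' @return `path` invisibly / the restored regressor.
#' @export
save_checkpoint <- function(reg, path) {
  stopifnot(inherits(reg, "voxres_regressor"))
  saveRDS(reg, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: ", path)
  reg <- readRDS(path)
  if (!inherits(reg, "voxres_regressor"))
    stop_io(path, " is not a voxres checkpoint")
  reg
}
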