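# Corpus assembly: models -> simulated maps -> filter bank -> labeled boxes.

#' Build a labeled-box training corpus from atomic models
#'
#' For each model: simulate a density map at the band's voxel size,
#' normalize to unit maximum, low-pass filter at every bank cutoff, and
#' extract labeled boxes from each filtered map (mask = thresholded clean
#' map). Box counts are balanced per label by seeded subsampling to
#' `per_label` boxes per model and cutoff.
#'
#' Two sampling schemes: `"mask_centers"` (default) draws boxes centred on
#' masked voxels exactly as sliding-window inference does, so the training
#' and inference box distributions coincide (including mask-boundary
#' windows); `"tiles"` is the grid tiling of
#' [extract_training_boxes()] with an occupancy floor.
#'
#' @param models list of `atomic_model` objects (or a single model).
#' @param band a [band_spec()] (working voxel size + label range).
#' @param bank a [filter_bank_spec()]; must lie within the band's range and
#'   respect Nyquist (checked before any work).
#' @param per_label boxes kept per model per cutoff (NULL = keep all).
#' @param stride lattice spacing: box-centre spacing for `"mask_centers"`,
#'   tile stride for `"tiles"`.
#' @param occupancy_min occupancy floor (`"tiles"` scheme only).
#' @param sampling box sampling scheme (see above).
#' @param mask_quantile threshold for the automatic mask, as a fraction of
#'   the clean map maximum (default 0.1).
#' @param noise_sd Gaussian noise added to each filtered map before
#'   boxing, in units of the unit-maximum-normalized map: a scalar SD, or
#'   a length-2 range from which one SD is drawn per model and cutoff
#'   (default 0 = clean maps, the full-scale recipe). Exposing the
#'   network to a range of noise floors is essential for small corpora:
#'   clean-trained networks read broadband noise as spurious fine detail,
#'   while networks trained at one fixed floor learn the floor level
#'   itself as a (spurious) resolution cue.
#' @param seed seed for the balancing subsample and the training noise.
#' @param verbose log per-model progress to stderr.
#' @return A `labeled_boxes` corpus with a `provenance` attribute
#'   (per-label counts, parameters, seed).
#' @export
make_corpus <- function(models, band = wide_band(), bank = band$bank,
                        per_label = 40L, stride = 5L, occupancy_min = 0.5,
                        mask_quantile = 0.1, noise_sd = 0, seed = 1L,
                        sampling = c("mask_centers", "tiles"),
                        verbose = FALSE) {
  sampling <- match.arg(sampling)
  if (inherits(models, "atomic_model")) models <- list(models)
  if (!length(models)) stop_validation("need at least one model")
  stopifnot(inherits(band, "band_spec"), inherits(bank, "filter_bank_spec"))
  if (bank$d_min < 2 * band$voxel_size)
    stop_validation("bank cutoff ", bank$d_min, " A violates Nyquist at ",
                    band$voxel_size, " A/voxel")
  if (bank$d_min < band$bank$d_min - 1e-9 || bank$d_max > band$bank$d_max + 1e-9)
    stop_validation("bank [", bank$d_min, ", ", bank$d_max,
                    "] A exceeds the band label range [",
                    band$bank$d_min, ", ", band$bank$d_max, "] A")
  restore_rng <- preserve_rng_state()
  on.exit(restore_rng())
  set.seed(seed)
  sets <- list()
  for (mi in seq_along(models)) {
    clean <- scale_to_unit_max(
      model_to_density(models[[mi]], voxel_size = band$voxel_size))
    mask <- mask_from_threshold(clean, mask_quantile * max(clean$data))
    for (d in bank$cutoffs) {
      filt <- lowpass_raised_cosine(clean, filter_spec(d))
      sd_i <- if (length(noise_sd) == 2L)
        runif(1, noise_sd[1], noise_sd[2]) else noise_sd[1]
      if (sd_i > 0)
        filt$data <- filt$data +
          array(rnorm(length(filt$data), 0, sd_i), dim(filt$data))
      if (sampling == "mask_centers") {
        eb <- enumerate_inference_boxes(filt, mask, stride = stride)
        bx <- structure(list(cubes = eb$cubes,
                             labels = rep(d, ncol(eb$cubes)),
                             n_skipped_zero_norm = 0L),
                        class = "labeled_boxes")
      } else {
        bx <- extract_training_boxes(filt, mask, label = d, stride = stride,
                                     occupancy_min = occupancy_min)
      }
      n <- ncol(bx$cubes)
      if (!is.null(per_label) && n > per_label) {
        keep <- sample.int(n, per_label)
        bx$cubes <- bx$cubes[, keep, drop = FALSE]
        bx$labels <- bx$labels[keep]
      }
      sets[[length(sets) + 1L]] <- bx
    }
    if (verbose)
      message(sprintf("model %d/%d: %s boxes so far", mi, length(models),
                      sum(vapply(sets, function(s) ncol(s$cubes), 0))))
  }
  corpus <- bind_boxes(sets)
  attr(corpus, "provenance") <- list(
    n_models = length(models), voxel_size = band$voxel_size,
    cutoffs = bank$cutoffs, per_label = per_label, stride = stride,
    occupancy_min = occupancy_min, mask_quantile = mask_quantile,
    noise_sd = noise_sd, sampling = sampling, seed = seed,
    label_counts = as.list(table(corpus$labels)))
  corpus
}

#' Save / load a box corpus
#'
#' Persisted via R serialization (cubes + labels + provenance). An HDF5
#' container would be the cross-language choice, but no HDF5 binding is
#' available in the supported R stack; the payload and surface are the
#' same.
#'
#' @param corpus a `labeled_boxes` corpus.
#' @param path container path (conventionally `.rds`).
#' @return `path` invisibly / the restored corpus.
#' @export
save_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "labeled_boxes"))
  saveRDS(corpus, path)
  invisible(path)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) stop_io("corpus not found: ", path)
  corpus <- readRDS(path)
  if (!inherits(corpus, "labeled_boxes"))
    stop_io(path, " is not a voxres box corpus")
  corpus
}
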