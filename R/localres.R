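# End-to-end local-resolution inference and the oversharpening audit.

#' Estimate a voxel-wise local resolution map
#'
#' The map and mask are resampled to the regressor band's working voxel
#' size (Fourier resampling; the mask is re-binarized at 0.5), a 13^3
#' sliding window is evaluated at every masked voxel whose window fits in
#' the grid, and the predicted cutoff (Angstrom) is written to the window's
#' centre voxel. Border voxels whose window would leave the grid receive no
#' prediction and are reported in the coverage mask instead of being padded.
#'
#' @param map a [density_map()] with voxel-size metadata.
#' @param mask a [as_mask()] congruent with `map`.
#' @param reg a trained `voxres_regressor` (or a stub function
#'   `f(cubes) -> numeric`, used with `band`).
#' @param band band to use when `reg` is a bare function (default
#'   [wide_band()]).
#' @param stride evaluation-lattice spacing in voxels (default 1 =
#'   a prediction for every masked voxel; larger values subsample the
#'   smooth resolution field for faster distributional summaries, leaving
#'   skipped voxels uncovered).
#' @return A `resolution_map`: `data` (Angstrom values, 0 outside
#'   mask-and-coverage), `voxel_size`, `band`, `coverage` (logical array),
#'   `mask` (working-grid mask), `clipped_fraction`.
#' @export
estimate_local_resolution <- function(map, mask, reg, band = wide_band(),
                                      stride = 1L) {
  stopifnot(inherits(map, "density_map"))
  check_congruent(map, mask)
  if (inherits(reg, "voxres_regressor")) {
    if (!reg$trained)
      warning("regressor is untrained; predictions will be meaningless")
    band <- reg$band
    lr <- reg$label_range
  } else if (is.function(reg)) {
    lr <- c(-Inf, Inf)
  } else stop_validation("reg must be a voxres_regressor or a function")
  wmap <- resample(map, band$voxel_size)
  wmask <- if (identical(dim(wmap$data), dim(map$data))) mask else {
    # same resampler, same voxel ratio => congruent grids; re-binarize at 0.5
    r <- resample(density_map(array(as.numeric(mask$data), dim(map$data)),
                              map$voxel_size, map$origin), band$voxel_size)
    as_mask(array(r$data > 0.5, dim(r$data)))
  }
  if (!any(wmask$data))
    stop_validation("mask is empty after resampling to the working grid")
  boxes <- enumerate_inference_boxes(wmap, wmask, stride = stride)
  if (nrow(boxes$centers) == 0L)
    stop_validation("no masked voxel has a full 13^3 window inside the grid")
  pred <- predict_cubes(reg, boxes$cubes)
  out <- array(0, dim(wmap$data))
  out[boxes$centers] <- pred
  coverage <- array(FALSE, dim(wmap$data))
  coverage[boxes$centers] <- TRUE
  structure(list(data = out, voxel_size = band$voxel_size, band = band,
                 coverage = coverage, mask = wmask$data,
                 label_range = lr,
                 clipped_fraction = attr(pred, "clipped_fraction"),
                 n_uncovered = nrow(boxes$uncovered),
                 origin = map$origin),
            class = "resolution_map")
}

#' @export
print.resolution_map <- function(x, ...) {
  v <- x$data[x$coverage & x$mask]
  cat(sprintf("<resolution_map %s, voxel %.3g A, %d covered voxels, median %.2f A>\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size,
              length(v), stats::median(v)))
  invisible(x)
}

#' Convert a resolution map to a plain density map (for MRC export)
#'
#' Voxels outside mask-and-coverage are 0 by convention, matching common
#' viewer expectations for surface colouring.
#'
#' @param rmap a `resolution_map`.
#' @return A [density_map()].
#' @export
as_density_map <- function(rmap) {
  stopifnot(inherits(rmap, "resolution_map"))
  density_map(rmap$data, rmap$voxel_size, rmap$origin)
}

#' Summarize a resolution map
#'
#' Statistics are computed over masked, covered voxels only.
#'
#' @param rmap a `resolution_map`.
#' @param percentiles percent values for the percentile table (default
#'   includes the 20th used by the oversharpening audit).
#' @param bin_width histogram bin width in Angstrom (default 0.1, the bank
#'   step).
#' @return A `resolution_summary`: `median`, `sd`, `n_voxels`,
#'   `percentiles` (named numeric), `histogram` (`breaks`, `counts`).
#' @export
summarize_resolution <- function(rmap, percentiles = c(5, 20, 25, 50, 75, 95),
                                 bin_width = 0.1) {
  stopifnot(inherits(rmap, "resolution_map"))
  v <- rmap$data[rmap$coverage & rmap$mask]
  if (!length(v)) stop_validation("resolution map has no covered voxel")
  if (any(percentiles <= 0 | percentiles >= 100))
    stop_validation("percentiles must lie in (0, 100)")
  # integer-multiple breaks avoid seq() floating-point drift at the edges
  lo <- floor(min(v) / bin_width) - 1
  hi <- ceiling(max(v) / bin_width) + 1
  breaks <- (lo:hi) * bin_width
  h <- hist(v, breaks = breaks, plot = FALSE)
  structure(list(
    median = median(v), sd = sd(v), n_voxels = length(v),
    percentiles = stats::setNames(as.numeric(quantile(v, percentiles / 100)),
                                  as.character(percentiles)),
    histogram = list(breaks = h$breaks, counts = h$counts),
    clipped_fraction = rmap$clipped_fraction),
    class = "resolution_summary")
}

#' @export
print.resolution_summary <- function(x, ...) {
  cat(sprintf("<resolution_summary: median %.2f A, sd %.2f A, n %d>\n",
              x$median, x$sd, x$n_voxels))
  invisible(x)
}

#' Oversharpening audit via a B-factor sweep
#'
#' Texture-based resolution estimates respond to B-factor sharpening while
#' SNR-based estimators (BlocRes/MonoRes-style) do not; comparing the two
#' detects oversharpening. For each B in `b_grid` the unsharpened map is
#' sharpened, estimated and summarized; the recommended B is the one whose
#' chosen percentile (default the 20th) of the estimated distribution is
#' closest to the same percentile of the SNR-based reference, and any B
#' whose estimate is better (smaller) than the reference is flagged as
#' oversharpening.
#'
#' @param unsharpened a [density_map()] (not yet sharpened).
#' @param mask a [as_mask()] congruent with it.
#' @param reg a trained `voxres_regressor` (or stub function).
#' @param reference the SNR-based local-resolution reference for the same
#'   map, produced externally: a `resolution_map`, a `resolution_summary`,
#'   or a bare numeric Angstrom value already at the chosen percentile.
#' @param b_grid B factors to sweep, Angstrom^2 (e.g. `c(0, -30, -60, -100)`).
#' @param percentile matching percentile in percent (default 20).
#' @param band passed through when `reg` is a function.
#' @param stride evaluation-lattice spacing for each estimate (see
#'   [estimate_local_resolution()]).
#' @return A `sharpen_audit`: data.frame `sweep` (B, percentile value,
#'   median, flagged), `recommended_b`, `reference_value`.
#' @export
audit_sharpening <- function(unsharpened, mask, reg, reference,
                             b_grid = c(0, -30, -60, -100), percentile = 20,
                             band = wide_band(), stride = 1L) {
  if (!length(b_grid)) stop_validation("b_grid must be non-empty")
  if (percentile <= 0 || percentile >= 100)
    stop_validation("percentile must lie in (0, 100)")
  ref_value <- reference_percentile(reference, percentile)
  est <- vapply(b_grid, function(B) {
    m <- if (B == 0) unsharpened else bfactor_apply(unsharpened, B)
    s <- summarize_resolution(
      estimate_local_resolution(m, mask, reg, band = band, stride = stride),
      percentiles = percentile)
    c(s$percentiles[[1]], s$median)
  }, numeric(2))
  sweep_df <- data.frame(B = b_grid, percentile_value = est[1, ],
                         median = est[2, ])
  sweep_df$flagged_oversharpened <- sweep_df$percentile_value < ref_value - 1e-9
  structure(list(sweep = sweep_df,
                 recommended_b = b_grid[which.min(abs(est[1, ] - ref_value))],
                 reference_value = ref_value,
                 percentile = percentile),
            class = "sharpen_audit")
}

reference_percentile <- function(reference, percentile) {
  key <- as.character(percentile)
  if (is.numeric(reference) && length(reference) == 1L) return(reference)
  if (inherits(reference, "resolution_map"))
    reference <- summarize_resolution(reference, percentiles = percentile)
  if (inherits(reference, "resolution_summary")) {
    if (!key %in% names(reference$percentiles))
      stop_validation("reference summary lacks the ", percentile,
                      "% percentile; recompute it with percentiles=",
                      percentile)
    return(reference$percentiles[[key]])
  }
  stop_validation("reference must be a resolution_map, resolution_summary ",
                  "or a single numeric Angstrom value")
}

#' @export
print.sharpen_audit <- function(x, ...) {
  cat(sprintf("<sharpen_audit: reference %.2f A at %g%%, recommended B = %g A^2>\n",
              x$reference_value, x$percentile, x$recommended_b))
  print(x$sweep, row.names = FALSE)
  invisible(x)
}
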