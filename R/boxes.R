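# Labeled training boxes and inference sliding-window enumeration.
#
# A box is a 13x13x13 density cube stored as a 2197-vector in array order
# (x fastest), divided by its L2 norm. The identical normalization at
# training and inference is what makes predictions invariant to global
# intensity scaling of the input map.

BOX_EDGE <- 13L
BOX_LEN <- BOX_EDGE^3

#' Band specification
#'
#' Ties a working sampling rate to its filter bank: the wide band works at
#' 1.0 A/voxel with labels 2.5-13.0 A (physical window edge 13 A), the
#' high-resolution band at 0.5 A/voxel with labels 1.5-6.0 A (edge 6.5 A).
#'
#' @param voxel_size working sampling rate in Angstrom per voxel.
#' @param bank a [filter_bank_spec()] giving the label range.
#' @param box_edge window edge in voxels (fixed at 13 by the network
#'   architecture).
#' @return A `band_spec`.
#' @export
band_spec <- function(voxel_size = 1.0,
                      bank = filter_bank_spec(2.5, 13.0, 0.1),
                      box_edge = BOX_EDGE) {
  if (voxel_size <= 0) stop_validation("voxel_size must be > 0")
  if (box_edge != BOX_EDGE)
    stop_validation("box_edge is fixed at ", BOX_EDGE, " by the architecture")
  if (bank$d_min < 2 * voxel_size)
    stop_validation("bank lower cutoff ", bank$d_min,
                    " A violates Nyquist at ", voxel_size, " A/voxel")
  structure(list(voxel_size = voxel_size, bank = bank,
                 box_edge = as.integer(box_edge)),
            class = "band_spec")
}

#' The two reference bands
#' @rdname band_spec
#' @export
wide_band <- function() band_spec(1.0, filter_bank_spec(2.5, 13.0, 0.1))

#' @rdname band_spec
#' @export
highres_band <- function() band_spec(0.5, filter_bank_spec(1.5, 6.0, 0.1))

# L2-normalize columns of a cube matrix; zero-norm columns flagged
normalize_cubes <- function(cubes) {
  nrm <- sqrt(colSums(cubes^2))
  keep <- nrm > 0
  out <- sweep(cubes[, keep, drop = FALSE], 2, nrm[keep], `/`)
  list(cubes = out, kept = keep)
}

#' Extract labeled training boxes from a filtered map
#'
#' Tiles the map at `stride`, keeps boxes whose mask occupancy is at least
#' `occupancy_min`, L2-normalizes each kept cube and attaches the map's
#' filter cutoff as its label. Zero-norm cubes are skipped and counted.
#'
#' @param map a [density_map()] (already low-pass filtered at `label`).
#' @param mask a [as_mask()] congruent with `map`.
#' @param label the filter cutoff in Angstrom carried by every box.
#' @param stride tiling stride in voxels (default 5; sub-window strides
#'   increase sample diversity at fixed corpus size).
#' @param occupancy_min minimum fraction of in-mask voxels for a box to be
#'   kept (default 0.5, so the network never learns "flat solvent implies
#'   some label").
#' @return A `labeled_boxes` list: `cubes` (2197 x n matrix, unit-norm
#'   columns), `labels` (length n), `n_skipped_zero_norm`.
#' @export
extract_training_boxes <- function(map, mask, label, stride = 5L,
                                   occupancy_min = 0.5) {
  stopifnot(inherits(map, "density_map"))
  check_congruent(map, mask)
  if (stride < 1) stop_validation("stride must be >= 1")
  d <- dim(map$data)
  if (any(d < BOX_EDGE))
    stop_validation("map ", paste(d, collapse = "x"),
                    " is smaller than the ", BOX_EDGE, "-voxel window")
  if (!any(mask$data)) {
    warning("mask has no nonzero voxel inside the grid; no boxes extracted")
    return(empty_boxes())
  }
  starts <- lapply(d, function(n) seq(1L, n - BOX_EDGE + 1L, by = stride))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  cubes <- matrix(0, BOX_LEN, nrow(grid))
  occ <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rx <- grid$x[i]:(grid$x[i] + BOX_EDGE - 1L)
    ry <- grid$y[i]:(grid$y[i] + BOX_EDGE - 1L)
    rz <- grid$z[i]:(grid$z[i] + BOX_EDGE - 1L)
    cubes[, i] <- map$data[rx, ry, rz]
    occ[i] <- mean(mask$data[rx, ry, rz])
  }
  sel <- occ >= occupancy_min
  cubes <- cubes[, sel, drop = FALSE]
  nz <- normalize_cubes(cubes)
  structure(list(cubes = nz$cubes,
                 labels = rep(label, ncol(nz$cubes)),
                 n_skipped_zero_norm = sum(!nz$kept)),
            class = "labeled_boxes")
}

empty_boxes <- function() {
  structure(list(cubes = matrix(0, BOX_LEN, 0), labels = numeric(0),
                 n_skipped_zero_norm = 0L),
            class = "labeled_boxes")
}

#' Concatenate labeled box sets
#' @param ... `labeled_boxes` objects.
#' @return A single `labeled_boxes`.
#' @export
bind_boxes <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "labeled_boxes")) sets <- sets[[1]]
  structure(list(
    cubes = do.call(cbind, lapply(sets, `[[`, "cubes")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    n_skipped_zero_norm = sum(vapply(sets, `[[`, 0L, "n_skipped_zero_norm"))),
    class = "labeled_boxes")
}

#' Enumerate inference boxes over a masked map
#'
#' One 13x13x13 window per masked voxel whose full neighbourhood fits in
#' the grid; each cube is normalized exactly as in training and keyed by
#' its centre voxel, where the prediction will be written back. Masked
#' voxels too close to the border are reported as uncovered rather than
#' padded (padding would feed the network content it never saw).
#'
#' @param map a [density_map()] at the band's working voxel size.
#' @param mask a [as_mask()] congruent with `map`.
#' @param stride evaluate only centres on a `stride`-spaced lattice
#'   (default 1 = every masked voxel, the reference behaviour). The
#'   resolution field varies smoothly, so a sparse lattice gives the same
#'   distributional summaries at a fraction of the cost; skipped voxels
#'   are simply not covered.
#' @return A list: `centers` (n x 3 integer matrix, 1-based), `cubes`
#'   (2197 x n unit-norm matrix), `uncovered` (m x 3 matrix of masked
#'   voxels with no valid window).
#' @export
enumerate_inference_boxes <- function(map, mask, stride = 1L) {
  stopifnot(inherits(map, "density_map"))
  check_congruent(map, mask)
  if (stride < 1) stop_validation("stride must be >= 1")
  d <- dim(map$data)
  if (any(d < BOX_EDGE))
    stop_validation("map ", paste(d, collapse = "x"),
                    " is smaller than the ", BOX_EDGE, "-voxel window")
  h <- BOX_EDGE %/% 2L  # 6
  w <- which(mask$data, arr.ind = TRUE)
  if (stride > 1L) {
    on_lattice <- (w[, 1] %% stride == 0L) & (w[, 2] %% stride == 0L) &
                  (w[, 3] %% stride == 0L)
    w <- w[on_lattice, , drop = FALSE]
  }
  ok <- w[, 1] > h & w[, 1] <= d[1] - h &
        w[, 2] > h & w[, 2] <= d[2] - h &
        w[, 3] > h & w[, 3] <= d[3] - h
  centers <- w[ok, , drop = FALSE]
  uncovered <- w[!ok, , drop = FALSE]
  cubes <- matrix(0, BOX_LEN, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cubes[, i] <- map$data[(centers[i, 1] - h):(centers[i, 1] + h),
                           (centers[i, 2] - h):(centers[i, 2] + h),
                           (centers[i, 3] - h):(centers[i, 3] + h)]
  }
  nrm <- sqrt(colSums(cubes^2))
  zero <- nrm == 0
  if (any(zero)) {
    uncovered <- rbind(uncovered, centers[zero, , drop = FALSE])
    centers <- centers[!zero, , drop = FALSE]
    cubes <- cubes[, !zero, drop = FALSE]
    nrm <- nrm[!zero]
  }
  if (ncol(cubes)) cubes <- sweep(cubes, 2, nrm, `/`)
  list(centers = centers, cubes = cubes, uncovered = uncovered)
}
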