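# Model-to-density simulation, synthetic structure generation, noise.

# save/restore the global RNG state so seeded operations do not perturb the
# caller's random stream
preserve_rng_state <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# Single-Gaussian electron scattering stand-in: amplitude proportional to
# atomic number, width sigma in Angstrom. Spectrally adequate at the
# working cutoffs (>= 1.5 A); the table is exported so a multi-Gaussian
# form factor can be dropped in.
.default_kernel_table <- data.frame(
  element = c("H", "C", "N", "O", "P", "S", "FE", "MG", "ZN", "CA"),
  amplitude = c(1, 6, 7, 8, 15, 16, 26, 12, 30, 20),
  sigma = c(0.9, 1.0, 1.0, 1.0, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1),
  stringsAsFactors = FALSE)

#' Per-element Gaussian scattering kernel
#'
#' Each atom deposits an isotropic 3D Gaussian with peak height
#' `amplitude * occupancy` and width `sigma` (Angstrom). Unknown elements
#' fall back to carbon.
#'
#' @param table data.frame with columns `element`, `amplitude`, `sigma`.
#' @return A `scattering_kernel` object.
#' @export
scattering_kernel <- function(table = .default_kernel_table) {
  stopifnot(all(c("element", "amplitude", "sigma") %in% names(table)))
  if (any(table$sigma <= 0)) stop_validation("kernel widths must be > 0")
  if (!"C" %in% table$element)
    stop_validation("kernel table must define carbon (the fallback element)")
  structure(list(table = table), class = "scattering_kernel")
}

.kernel_lookup <- function(kernel, elements) {
  tab <- kernel$table
  i <- match(toupper(elements), toupper(tab$element))
  i[is.na(i)] <- match("C", toupper(tab$element))
  list(amplitude = tab$amplitude[i], sigma = tab$sigma[i])
}

#' Simulate a density map from an atomic model
#'
#' Every atom deposits an isotropic Gaussian (peak = element amplitude x
#' occupancy, width = element sigma), positioned at its real-valued
#' coordinate; the separable Gaussian is evaluated on the grid, which is
#' equivalent to trilinear sub-voxel placement but exact. The grid covers
#' the model bounding box plus `padding` on every side (padding keeps later
#' Fourier filter wrap-around off the molecule); grid dimensions are rounded
#' up to even numbers, minimum 13.
#'
#' @param model an `atomic_model`.
#' @param voxel_size sampling rate in Angstrom per voxel (1.0 and 0.5 are
#'   the two training bands; any positive value is accepted).
#' @param padding margin in Angstrom around the model bounding box
#'   (default 8; must cover the kernel support).
#' @param kernel a [scattering_kernel()].
#' @return A [density_map()] with `origin` at the padded bounding-box corner.
#' @export
model_to_density <- function(model, voxel_size = 1.0, padding = 8,
                             kernel = scattering_kernel()) {
  stopifnot(inherits(model, "atomic_model"))
  if (nrow(model) == 0L) stop_validation("empty model")
  if (voxel_size <= 0) stop_validation("voxel_size must be > 0")
  par <- .kernel_lookup(kernel, model$element)
  if (padding < 4 * max(par$sigma))
    stop_validation("padding must cover the kernel support (>= 4*sigma = ",
                    signif(4 * max(par$sigma), 3), " A)")
  lo <- c(min(model$x), min(model$y), min(model$z)) - padding
  hi <- c(max(model$x), max(model$y), max(model$z)) + padding
  n <- pmax(13L, as.integer(ceiling((hi - lo) / voxel_size)))
  n <- n + n %% 2L   # even dimensions keep Fourier index bookkeeping simple
  a <- array(0, dim = n)
  ax <- lo[1] + (seq_len(n[1]) - 1L) * voxel_size
  ay <- lo[2] + (seq_len(n[2]) - 1L) * voxel_size
  az <- lo[3] + (seq_len(n[3]) - 1L) * voxel_size
  support <- 4  # sigmas
  for (i in seq_len(nrow(model))) {
    amp <- par$amplitude[i] * model$occupancy[i]
    if (amp == 0) next
    s <- par$sigma[i]
    rx <- which(abs(ax - model$x[i]) <= support * s)
    ry <- which(abs(ay - model$y[i]) <= support * s)
    rz <- which(abs(az - model$z[i]) <= support * s)
    if (!length(rx) || !length(ry) || !length(rz)) next
    gx <- exp(-(ax[rx] - model$x[i])^2 / (2 * s^2))
    gy <- exp(-(ay[ry] - model$y[i])^2 / (2 * s^2))
    gz <- exp(-(az[rz] - model$z[i])^2 / (2 * s^2))
    a[rx, ry, rz] <- a[rx, ry, rz] + amp * (gx %o% gy %o% gz)
  }
  density_map(a, voxel_size, origin = lo)
}

#' Specification of a synthetic polymer-like structure
#'
#' Stands in for a corpus of real macromolecular models: a compact,
#' self-avoiding-ish biased random walk of pseudo-carbon point scatterers
#' at a fixed bond length (3.8 A, the C-alpha virtual bond).
#'
#' @param n_atoms number of scatterers (>= 1; default 150, a small protein
#'   domain).
#' @param step bond length in Angstrom (default 3.8).
#' @param compactness bias of each step toward the current centroid, in
#'   `[0, 1)` (default 0.35; 0 gives an unbiased walk).
#' @param min_dist self-avoidance distance in Angstrom (default 2.0).
#' @param seed RNG seed; the same seed yields the identical structure.
#' @return A `synthetic_structure_spec`.
#' @export
synthetic_structure_spec <- function(n_atoms = 150, step = 3.8,
                                     compactness = 0.35, min_dist = 2.0,
                                     seed = 1) {
  if (n_atoms < 1) stop_validation("n_atoms must be >= 1")
  if (step <= 0) stop_validation("step must be > 0")
  if (compactness < 0 || compactness >= 1)
    stop_validation("compactness must lie in [0, 1)")
  structure(list(n_atoms = as.integer(n_atoms), step = step,
                 compactness = compactness, min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "synthetic_structure_spec")
}

#' Generate a synthetic polymer structure
#'
#' Biased random walk: each step direction is an isotropic random unit
#' vector blended with the unit vector pointing back at the running
#' centroid (weight = `compactness`), then renormalized to `step` length.
#' Proposals closer than `min_dist` to any previous atom are rejected (up
#' to 50 retries, after which the best proposal is accepted so the walk
#' never stalls). Deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_structure_spec()].
#' @return An `atomic_model` of pseudo-carbon atoms, first atom at the
#'   origin.
#' @export
generate_synthetic_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_structure_spec"))
  restore_rng <- preserve_rng_state()
  on.exit(restore_rng())
  set.seed(spec$seed)
  n <- spec$n_atoms
  xyz <- matrix(0, n, 3)
  if (n > 1) {
    centroid <- c(0, 0, 0)
    for (i in 2:n) {
      best <- NULL
      best_d <- -Inf
      for (try in 1:50) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        pull <- centroid - xyz[i - 1, ]
        pn <- sqrt(sum(pull^2))
        if (pn > 1e-9) u <- (1 - spec$compactness) * u + spec$compactness * pull / pn
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + spec$step * u
        d <- sqrt(min(colSums((t(xyz[seq_len(i - 2L), , drop = FALSE]) - cand)^2),
                      Inf))
        if (is.infinite(d) || d >= spec$min_dist) { best <- cand; break }
        if (d > best_d) { best_d <- d; best <- cand }
      }
      xyz[i, ] <- best
      centroid <- centroid + (best - centroid) / i
    }
  }
  atomic_model(xyz, element = "C", occupancy = 1)
}

#' Gaussian noise specification
#'
#' @param sd standard deviation of the additive zero-mean Gaussian noise,
#'   in map units (>= 0). The reference experiments add sd = 0.08 to maps
#'   normalized to unit maximum.
#' @param seed RNG seed.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(sd = 0.08, seed = 1) {
  if (sd < 0) stop_validation("noise sd must be >= 0")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}

#' Add iid Gaussian noise to a map
#'
#' The stated noise level is only meaningful relative to the map amplitude;
#' callers following the reference protocol should normalize the clean map
#' to unit maximum first (see [scale_to_unit_max()]).
#'
#' @param map a [density_map()].
#' @param noise a [noise_spec()].
#' @return A [density_map()] with `input + N(0, sd^2)` at every voxel;
#'   bit-reproducible under `noise$seed`.
#' @export
add_noise <- function(map, noise) {
  stopifnot(inherits(map, "density_map"), inherits(noise, "noise_spec"))
  if (noise$sd == 0) return(map)
  restore_rng <- preserve_rng_state()
  on.exit(restore_rng())
  set.seed(noise$seed)
  density_map(map$data + array(rnorm(length(map$data), 0, noise$sd),
                               dim(map$data)),
              map$voxel_size, map$origin)
}

#' Scale a map so its maximum is 1
#'
#' @param map a [density_map()] with a positive maximum.
#' @return The rescaled [density_map()].
#' @export
scale_to_unit_max <- function(map) {
  stopifnot(inherits(map, "density_map"))
  mx <- max(map$data)
  if (mx <= 0) stop_validation("map maximum must be > 0 to normalize")
  density_map(map$data / mx, map$voxel_size, map$origin)
}

#' Radius of gyration of an atomic model
#' @param model an `atomic_model`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}
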