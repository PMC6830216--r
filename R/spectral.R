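# Fourier-domain map operations.
#
# Frequency convention: normalized frequency f in cycles/voxel, Nyquist at
# 0.5; a resolution d (Angstrom) maps to f_c = voxel_size / d. Spatial
# frequency s = f / voxel_size = 1/d in 1/Angstrom.

# per-axis DFT frequencies in cycles/voxel
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}

# 3D radial normalized-frequency grid for dims d
radial_freq_grid <- function(d) {
  fx <- fft_freqs(d[1]); fy <- fft_freqs(d[2]); fz <- fft_freqs(d[3])
  sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`))
}

fft3 <- function(a) fft(a)
ifft3 <- function(A) fft(A, inverse = TRUE) / length(A)

#' Raised-cosine low-pass filter specification
#'
#' @param cutoff passband-edge resolution d in Angstrom.
#' @param transition_width full width of the raised-cosine transition band
#'   in normalized frequency units (cycles/voxel; default 0.02).
#' @return A `filter_spec`.
#' @export
filter_spec <- function(cutoff, transition_width = 0.02) {
  if (cutoff <= 0) stop_validation("cutoff must be > 0")
  if (transition_width <= 0) stop_validation("transition_width must be > 0")
  structure(list(cutoff = cutoff, transition_width = transition_width),
            class = "filter_spec")
}

#' Filter-bank specification (training label grid)
#'
#' @param d_min,d_max resolution range in Angstrom (`d_min < d_max`).
#' @param step label spacing in Angstrom (> 0). The wide band of the
#'   reference protocol is 2.5-13.0 A every 0.1 A at 1.0 A/voxel; the
#'   high-resolution band is 1.5-6.0 A at 0.5 A/voxel.
#' @return A `filter_bank_spec`; its `cutoffs` field enumerates the bank.
#' @export
filter_bank_spec <- function(d_min, d_max, step) {
  if (!(d_min < d_max)) stop_validation("d_min must be < d_max")
  if (step <= 0) stop_validation("step must be > 0")
  structure(list(d_min = d_min, d_max = d_max, step = step,
                 cutoffs = seq(d_min, d_max, by = step)),
            class = "filter_bank_spec")
}

# raised-cosine transfer function H(f) for normalized radial frequency f
raised_cosine_H <- function(f, f_c, w) {
  H <- numeric(length(f))
  lo <- f_c - w / 2
  hi <- f_c + w / 2
  H[f <= lo] <- 1
  band <- f > lo & f < hi
  H[band] <- 0.5 * (1 + cos(pi * (f[band] - lo) / w))
  H
}

#' Low-pass filter a map with a raised cosine
#'
#' Multiplies the 3D DFT by H(f): 1 up to `f_c - w/2`, a half-cosine roll-off
#' of full width `w = transition_width` centred at `f_c = voxel_size/cutoff`,
#' 0 above. H(0) = 1, so the map mean is preserved exactly.
#'
#' @param map a [density_map()].
#' @param spec a [filter_spec()] (or a bare cutoff in Angstrom).
#' @return The filtered [density_map()].
#' @export
lowpass_raised_cosine <- function(map, spec) {
  stopifnot(inherits(map, "density_map"))
  if (is.numeric(spec)) spec <- filter_spec(spec)
  if (spec$cutoff < 2 * map$voxel_size)
    stop_validation("cutoff ", spec$cutoff, " A is beyond Nyquist (",
                    2 * map$voxel_size, " A) for voxel size ",
                    map$voxel_size, " A")
  f <- radial_freq_grid(dim(map$data))
  H <- array(raised_cosine_H(as.numeric(f), map$voxel_size / spec$cutoff,
                             spec$transition_width), dim(map$data))
  out <- Re(ifft3(fft3(map$data) * H))
  density_map(out, map$voxel_size, map$origin)
}

#' Apply a global B factor (sharpen/blur)
#'
#' Multiplies each Fourier coefficient by `exp(-B s^2 / 4)` with spatial
#' frequency `s = 1/d` in 1/Angstrom. Negative B amplifies high frequencies
#' (sharpening); positive B attenuates them.
#'
#' @param map a [density_map()].
#' @param B B factor in Angstrom^2.
#' @return The weighted [density_map()].
#' @export
bfactor_apply <- function(map, B) {
  stopifnot(inherits(map, "density_map"))
  if (B == 0) return(map)
  s <- radial_freq_grid(dim(map$data)) / map$voxel_size
  G <- exp(-B * s^2 / 4)
  out <- Re(ifft3(fft3(map$data) * G))
  density_map(out, map$voxel_size, map$origin)
}

#' Randomize Fourier phases beyond a resolution cutoff
#'
#' Replaces the phases at spatial frequencies s > 1/beyond with the phases
#' of a seeded white-noise volume (automatically Hermitian, so the output
#' is real); amplitudes are preserved exactly, phases at s <= 1/beyond are
#' untouched. This destroys structural texture without changing the power
#' spectrum - the classic control for texture-reading estimators.
#'
#' @param map a [density_map()].
#' @param beyond resolution cutoff in Angstrom (>= 2 x voxel size).
#' @param seed RNG seed.
#' @return The phase-randomized [density_map()].
#' @export
phase_randomize <- function(map, beyond, seed = 1) {
  stopifnot(inherits(map, "density_map"))
  if (beyond < 2 * map$voxel_size)
    stop_validation("beyond ", beyond, " A is inside Nyquist for voxel size ",
                    map$voxel_size, " A")
  F <- fft3(map$data)
  f <- radial_freq_grid(dim(map$data))
  # corner frequencies beyond the axial Nyquist shell (f > 0.5) are left
  # untouched: the working spectrum is treated as radially band-limited at
  # Nyquist, so "beyond = 2 x voxel" randomizes nothing
  sel <- f > map$voxel_size / beyond & f <= 0.5
  if (any(sel)) {
    restore_rng <- preserve_rng_state()
    on.exit(restore_rng())
    set.seed(seed)
    # phases of the DFT of a real white-noise field satisfy the same
    # Hermitian symmetry as the map's own phases, including the
    # self-conjugate Nyquist planes (where they are 0 or pi)
    Fn <- fft3(array(rnorm(length(map$data)), dim(map$data)))
    phase <- Fn / Mod(Fn)
    phase[Mod(Fn) == 0] <- 1
    F[sel] <- Mod(F[sel]) * phase[sel]
  }
  density_map(Re(ifft3(F)), map$voxel_size, map$origin)
}

#' Resample a map to a new voxel size in Fourier space
#'
#' Band-limited resampling: the centred Fourier spectrum is cropped
#' (downsampling) or zero-padded (upsampling) to the new grid, preserving
#' the physical extent within one voxel and introducing no interpolation
#' blur (trilinear resampling would read as lower resolution downstream).
#' The reported voxel size is exactly `new_voxel_size`.
#'
#' @param map a [density_map()].
#' @param new_voxel_size target sampling rate in Angstrom per voxel.
#' @return The resampled [density_map()].
#' @export
resample <- function(map, new_voxel_size) {
  stopifnot(inherits(map, "density_map"))
  if (new_voxel_size <= 0) stop_validation("new_voxel_size must be > 0")
  d <- dim(map$data)
  if (abs(new_voxel_size - map$voxel_size) < 1e-9 * map$voxel_size) return(map)
  nd <- as.integer(round(d * map$voxel_size / new_voxel_size))
  if (any(nd < 13L))
    stop_validation("resampling to ", new_voxel_size, " A/voxel gives a ",
                    paste(nd, collapse = "x"),
                    " grid, smaller than the 13-voxel window")
  F <- fft3(map$data)
  Fn <- array(0i, dim = nd)
  # copy the overlapping centred frequency components axis by axis
  idx <- function(n_old, n_new) {
    m <- min(n_old, n_new)
    half <- (m - 1L) %/% 2L           # positive freqs 0..half
    neg <- m - 1L - half              # negative freqs -neg..-1
    list(old = c(1:(half + 1L), if (neg > 0) (n_old - neg + 1L):n_old),
         new = c(1:(half + 1L), if (neg > 0) (n_new - neg + 1L):n_new))
  }
  ix <- idx(d[1], nd[1]); iy <- idx(d[2], nd[2]); iz <- idx(d[3], nd[3])
  Fn[ix$new, iy$new, iz$new] <- F[ix$old, iy$old, iz$old]
  # drop any non-self-conjugate Nyquist remnants so the result is real
  out <- Re(ifft3(Fn)) * prod(nd) / prod(d)
  density_map(out, new_voxel_size, map$origin)
}

#' Rotationally averaged power spectrum
#'
#' Diagnostic/oracle helper: total spectral energy per radial frequency
#' shell (shell width one Fourier voxel).
#'
#' @param map a [density_map()].
#' @return data.frame with `f` (shell centre, cycles/voxel) and `energy`.
#' @export
shell_energy <- function(map) {
  stopifnot(inherits(map, "density_map"))
  F <- fft3(map$data)
  f <- as.numeric(radial_freq_grid(dim(map$data)))
  n <- max(dim(map$data))
  shell <- pmin(round(f * n), ceiling(n / 2))
  e <- tapply(as.numeric(Mod(F))^2, shell, sum)
  data.frame(f = as.numeric(names(e)) / n, energy = as.numeric(e))
}
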