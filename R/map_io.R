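# MRC2014 / PDB input-output and mask construction.
#
# Internal grid convention: a density map is an R array `a` with
# dim = c(nx, ny, nz), indexed a[x, y, z], 1-based, x fastest. Because R
# arrays are column-major this is byte-for-byte the MRC file layout
# (columns = x, rows = y, sections = z) whenever MAPC/MAPR/MAPS = 1,2,3;
# any other axis order in the header is normalized to this convention on
# read. The grid origin (Angstrom) is carried through but never used in
# resolution arithmetic: predictions are grid-local.

#' Construct a density map object
#'
#' The universal volume currency of the package: a 3D numeric array plus an
#' isotropic voxel size in Angstrom and a grid origin.
#'
#' @param data 3D numeric array, indexed `[x, y, z]`.
#' @param voxel_size voxel edge length in Angstrom (isotropic, > 0).
#' @param origin grid origin in Angstrom (length-3, defaults to zeros).
#' @return An object of class `density_map` with fields `data`,
#'   `voxel_size`, `origin`.
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("map data must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop_validation("voxel_size must be a single finite value > 0")
  if (!all(is.finite(data)))
    stop_validation("map contains non-finite values")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop_validation("origin must be a finite 3-vector")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map %d x %d x %d, voxel %.4g A, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask congruent with a density map
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @return An object of class `vox_mask` (a logical 3D array wrapper).
#' @export
as_mask <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("mask data must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop_validation("mask values must be strictly 0/1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop_validation("mask must be logical or 0/1 numeric")
  if (!any(data)) stop_validation("mask has no nonzero voxel")
  structure(list(data = data), class = "vox_mask")
}

# ---------------------------------------------------------------------------
# MRC2014

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC/CCP4 volume
#'
#' Reads a subset of MRC2014 sufficient for cryoEM maps: modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16); little- or big-endian via the
#' machine stamp; arbitrary MAPC/MAPR/MAPS axis order (normalized to
#' x-fastest on read); extended headers skipped via NSYMBT.
#'
#' @param path path to a `.mrc`/`.map` file.
#' @param voxel_size optional override (Angstrom) when the header carries a
#'   zero/absent cell; without it a zero voxel size is an error.
#' @return A [density_map()].
#' @export
read_map <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop_io("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024L)
  if (length(hdr_raw) < 1024L) stop_io("truncated MRC header in ", path)
  endian <- "little"
  stamp <- hdr_raw[213:214]
  if (as.integer(stamp[1]) == 0x11) endian <- "big"
  geti <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                 "integer", 1L, 4L, endian = endian)
  getf <- function(word) readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)],
                                 "numeric", 1L, 4L, endian = endian)
  nc <- geti(1); nr <- geti(2); ns <- geti(3)
  mode <- geti(4)
  mx <- geti(8); my <- geti(9); mz <- geti(10)
  cella <- c(getf(11), getf(12), getf(13))
  mapc <- geti(17); mapr <- geti(18); maps <- geti(19)
  nsymbt <- geti(24)
  orig <- c(getf(50), getf(51), getf(52))
  if (any(c(nc, nr, ns) <= 0) || any(c(nc, nr, ns) > 4096L))
    stop_io("implausible MRC dimensions in ", path)
  if (!as.character(mode) %in% names(.mrc_modes))
    stop_io("unsupported MRC mode ", mode, " in ", path)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- as.numeric(nc) * nr * ns
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n, 1L, signed = TRUE, endian = endian)),
    `1` = as.numeric(readBin(con, "integer", n, 2L, signed = TRUE, endian = endian)),
    `2` = readBin(con, "numeric", n, 4L, endian = endian),
    `6` = as.numeric(readBin(con, "integer", n, 2L, signed = FALSE, endian = endian)))
  if (length(vals) != n) stop_io("truncated MRC data in ", path)
  a <- array(vals, dim = c(nc, nr, ns))
  # normalize axis order: column/row/section axes -> x,y,z
  perm <- order(c(mapc, mapr, maps))
  if (!identical(sort(c(mapc, mapr, maps)), 1:3))
    stop_io("invalid MAPC/MAPR/MAPS in ", path)
  if (!identical(perm, 1:3)) a <- aperm(a, perm)
  # MX/MY/MZ and CELLA refer to the cell's X/Y/Z axes irrespective of the
  # file's column/row/section order, so no permutation here
  mxyz <- c(mx, my, mz)
  vox <- if (all(mxyz > 0)) cella / mxyz else c(0, 0, 0)
  if (all(vox == 0) || any(!is.finite(vox))) {
    if (is.null(voxel_size))
      stop_validation("MRC header of ", path, " has no usable voxel size; ",
                      "pass voxel_size= (CLI: --voxel) to supply it")
    vox <- rep(voxel_size, 3)
  }
  if (diff(range(vox)) > 1e-3 * mean(vox))
    stop_validation("anisotropic voxel size ", paste(signif(vox, 5), collapse = "/"),
                    " A in ", path, ": the sliding-window geometry assumes ",
                    "isotropic sampling; resample the map externally first")
  density_map(a, mean(vox), orig)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' @param map a [density_map()] (a `resolution_map` is also accepted; voxels
#'   outside its mask are written as 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "resolution_map")) map <- as_density_map(map)
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wi(d)                                   # NX NY NZ
  wi(2L)                                  # MODE float32
  wi(c(0L, 0L, 0L))                       # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * map$voxel_size)                  # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1L, 2L, 3L))                       # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))                           # ISPG, NSYMBT
  writeBin(raw(100L), con)                # EXTRA (words 26-50 minus origin)
  wf(map$origin)                          # ORIGIN (words 50-52)
  writeChar("MAP ", con, 4L, eos = NULL)  # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.numeric(map$data)))     # RMS
  wi(0L)                                  # NLABL
  writeBin(raw(800L), con)                # labels
  writeBin(as.numeric(map$data), con, 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# PDB

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB atomic model
#'
#' Parses fixed-width ATOM and HETATM records. HETATM atoms are kept by
#' default; water molecules are excluded by default. The element symbol is
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name.
#'
#' @param path path to a PDB file.
#' @param include_het keep HETATM records (default TRUE).
#' @param exclude_waters drop residues HOH/WAT/DOD (default TRUE).
#' @return An `atomic_model`: data.frame with columns `element`, `x`, `y`,
#'   `z`, `occupancy`.
#' @export
read_model <- function(path, include_het = TRUE, exclude_waters = TRUE) {
  if (!file.exists(path)) stop_io("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
  lines <- lines[keep]
  if (exclude_waters && length(lines)) {
    resn <- trimws(substr(lines, 18, 20))
    lines <- lines[!resn %in% .water_resnames]
  }
  if (!length(lines)) stop_validation("no parseable atom records in ", path)
  elem <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  # fall back to first alphabetic character of the atom name
  miss <- elem == ""
  elem[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "", sub("^[0-9]+", "", name[miss])), 1, 1))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  m <- data.frame(
    element = elem,
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occupancy = pmin(pmax(occ, 0), 1),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(m[c("x", "y", "z")]))))
    stop_validation("non-finite coordinates in ", path)
  class(m) <- c("atomic_model", "data.frame")
  m
}

#' Construct an atomic model from coordinates
#'
#' @param xyz n x 3 matrix of coordinates in Angstrom.
#' @param element element symbols (recycled).
#' @param occupancy occupancies in `[0, 1]` (recycled, default 1).
#' @return An `atomic_model` data.frame.
#' @export
atomic_model <- function(xyz, element = "C", occupancy = 1) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (!all(is.finite(xyz))) stop_validation("coordinates must be finite")
  if (any(!nzchar(element))) stop_validation("element symbols must be non-empty")
  m <- data.frame(element = rep_len(as.character(element), nrow(xyz)),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  occupancy = rep_len(as.numeric(occupancy), nrow(xyz)),
                  stringsAsFactors = FALSE)
  if (any(m$occupancy < 0 | m$occupancy > 1))
    stop_validation("occupancy must lie in [0, 1]")
  class(m) <- c("atomic_model", "data.frame")
  m
}

#' Write an atomic model as PDB
#'
#' Synthetic models are written as standard PDB ATOM records (residue ALA,
#' chain A, one atom per residue) so the whole pipeline consumes one format.
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  n <- nrow(model)
  lines <- sprintf(
    "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n) %% 100000L,
    substr(paste0(model$element, "A"), 1, 3),
    ((seq_len(n) - 1L) %% 9999L) + 1L,
    model$x, model$y, model$z, model$occupancy, 0,
    toupper(model$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# masks

#' Threshold-based mask with largest-connected-component cleanup
#'
#' Convenience for when no externally produced mask is supplied: voxels with
#' density strictly above `threshold` are kept, then reduced to the largest
#' 6-connected component (removes disconnected noise blobs).
#'
#' @param map a [density_map()].
#' @param threshold finite density value.
#' @return A [as_mask()] object congruent with `map`.
#' @export
mask_from_threshold <- function(map, threshold) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(threshold)) stop_validation("threshold must be finite")
  raw <- map$data > threshold
  if (!any(raw))
    stop_validation("empty mask: no voxel above threshold ", signif(threshold, 4),
                    " (map maximum is ", signif(max(map$data), 4),
                    "); choose a lower threshold")
  comp <- largest_component_cpp(as.logical(raw), dim(map$data))
  as_mask(array(comp, dim(map$data)))
}

#' Check that a mask is congruent with a map
#' @param map a [density_map()].
#' @param mask a [as_mask()].
#' @return invisibly TRUE; errors otherwise.
#' @export
check_congruent <- function(map, mask) {
  if (!identical(dim(map$data), dim(mask$data)))
    stop_validation("mask dimensions ", paste(dim(mask$data), collapse = "x"),
                    " do not match map ", paste(dim(map$data), collapse = "x"))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# error classes (CLI maps these to exit codes 2/3)

stop_validation <- function(...) {
  stop(structure(class = c("voxres_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("voxres_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
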