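test_that("MRC write/read round trip preserves grid, voxel size and origin", {
  m <- fixture_map(n = 17, voxel = 1.06)
  m$origin <- c(-3.5, 2.25, 0)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  r <- read_map(p)
  expect_identical(dim(r$data), dim(m$data))
  # float32 storage: bit-exact after one float32 round trip
  expect_identical(r$data, array(readBin(writeBin(
    as.numeric(m$data), raw(), size = 4L), "numeric", length(m$data),
    size = 4L), dim(m$data)))
  expect_equal(r$voxel_size, 1.06, tolerance = 1e-6)
  expect_equal(r$origin, m$origin, tolerance = 1e-5)
  # second round trip is bit-identical
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(r, p2)
  expect_identical(read_map(p2)$data, r$data)
})

test_that("13^3 all-zero map survives a round trip", {
  m <- density_map(array(0, c(13, 13, 13)), 1.0)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  r <- read_map(p)
  expect_identical(dim(r$data), c(13L, 13L, 13L))
  expect_true(all(r$data == 0))
})

test_that("voxel size in the header matches an independent raw readBin scan", {
  m <- fixture_map(n = 14, voxel = 1.06)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  con <- file(p, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 10L, 4L, endian = "little")
  cella <- readBin(con, "numeric", 3L, 4L, endian = "little")
  expect_identical(hdr_i[1:3], rep(14L, 3))       # NX NY NZ
  expect_identical(hdr_i[4], 2L)                  # mode float32
  expect_identical(hdr_i[8:10], rep(14L, 3))      # MX MY MZ
  expect_equal(cella / hdr_i[8:10], rep(1.06, 3), tolerance = 1e-6)
})

test_that("maps with non-standard axis order are normalized on read", {
  m <- fixture_map(n = 10)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  # rewrite header claiming the file stores (y, z, x): columns axis = 2 etc.
  raw_all <- readBin(p, "raw", file.size(p))
  perm_data <- aperm(m$data, c(2, 3, 1))  # what the file data would hold
  p2 <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw_all[1:1024], p2)
  con <- file(p2, "r+b")
  seek(con, 64L, rw = "write")  # MAPC/MAPR/MAPS, words 17-19
  writeBin(c(2L, 3L, 1L), con, 4L, endian = "little")
  seek(con, 1024L, rw = "write")
  writeBin(as.numeric(perm_data), con, 4L, endian = "little")
  close(con)
  r <- read_map(p2)
  expect_equal(r$data, m$data, tolerance = 1e-6)
})

test_that("missing voxel size errors unless supplied; anisotropy rejected", {
  m <- fixture_map(n = 13)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  con <- file(p, "r+b")
  seek(con, 40L, rw = "write")  # CELLA, words 11-13
  writeBin(rep(0, 3), con, 4L, endian = "little")
  close(con)
  expect_error(read_map(p), "voxel size", class = "voxres_validation_error")
  expect_equal(read_map(p, voxel_size = 2)$voxel_size, 2)
  con <- file(p, "r+b")
  seek(con, 40L, rw = "write")
  writeBin(c(13, 13, 26), con, 4L, endian = "little")
  close(con)
  expect_error(read_map(p), "anisotropic", class = "voxres_validation_error")
})

test_that("PDB parsing: ATOM/HETATM kept, waters excluded, element inferred", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   2       4.000   5.000   6.000  0.50  0.00           N",
    "ATOM      3  O   ALA A   3       7.000   8.000   9.000  1.00  0.00",
    "HETATM    4 ZN    ZN A 101       0.000   0.000   0.000  1.00  0.00          ZN",
    "HETATM    5  O   HOH A 201       9.000   9.000   9.000  1.00  0.00           O",
    "END"), p)
  m <- read_model(p)
  expect_equal(nrow(m), 4)  # water dropped
  expect_equal(m$element, c("C", "N", "O", "ZN"))
  expect_equal(m$x[1:2], c(1, 4))
  expect_equal(m$occupancy[2], 0.5)
  # oracle: line-level scan of the same file
  lines <- readLines(p)
  atoms <- grepl("^(ATOM  |HETATM)", lines) &
           !trimws(substr(lines, 18, 20)) %in% c("HOH", "WAT")
  expect_equal(nrow(m), sum(atoms))
  expect_equal(nrow(read_model(p, include_het = FALSE)), 3)
  writeLines("REMARK nothing here", p)
  expect_error(read_model(p), "no parseable", class = "voxres_validation_error")
})

test_that("model write/read round trip preserves coordinates to PDB precision", {
  m <- fixture_model(25)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, p)
  r <- read_model(p)
  expect_equal(nrow(r), nrow(m))
  expect_equal(r$x, m$x, tolerance = 5e-4)
  expect_equal(r$z, m$z, tolerance = 5e-4)
  expect_equal(r$element, m$element)
})

test_that("mask_from_threshold keeps the largest connected component only", {
  a <- array(0, c(20, 20, 20))
  a[3:8, 3:8, 3:8] <- 1        # 216 voxels
  a[14:16, 14:16, 14:16] <- 1  # 27 voxels, disjoint
  m <- density_map(a, 1)
  msk <- mask_from_threshold(m, 0.5)
  expect_equal(sum(msk$data), 216)
  expect_true(all(msk$data[3:8, 3:8, 3:8]))
  expect_false(any(msk$data[14:16, 14:16, 14:16]))
  # oracle: flood fill from a seed inside the big blob
  seen <- array(FALSE, dim(a))
  queue <- matrix(c(3L, 3L, 3L), ncol = 3)
  seen[3, 3, 3] <- TRUE
  while (nrow(queue)) {
    v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      w <- v + d
      if (all(w >= 1) && all(w <= 20) && a[w] > 0.5 && !seen[w]) {
        seen[w] <- TRUE
        queue <- rbind(queue, w)
      }
    }
  }
  expect_identical(msk$data, seen)
})

test_that("threshold edge cases: all-ones mask and empty-mask error", {
  m <- fixture_map(15)
  expect_true(all(mask_from_threshold(m, min(m$data) - 1)$data))
  expect_error(mask_from_threshold(m, max(m$data)), "lower threshold",
               class = "voxres_validation_error")
  expect_error(mask_from_threshold(m, NA_real_),
               class = "voxres_validation_error")
})

test_that("mask constructor enforces binarity and congruence checks work", {
  expect_error(as_mask(array(c(0, 0.5, 1), c(3, 1, 1))), "0/1",
               class = "voxres_validation_error")
  expect_error(as_mask(array(FALSE, c(2, 2, 2))), "nonzero",
               class = "voxres_validation_error")
  m <- fixture_map(15)
  expect_error(check_congruent(m, as_mask(array(TRUE, c(4, 4, 4)))),
               class = "voxres_validation_error")
})
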