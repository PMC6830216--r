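test_that("constant stub predictor paints the covered mask and zero elsewhere", {
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:12, 8:12, 8:12] <- TRUE
  rmap <- estimate_local_resolution(m, as_mask(mask), constant_predictor(5))
  inside <- rmap$mask & rmap$coverage
  expect_true(all(rmap$data[inside] == 5))
  expect_true(all(rmap$data[!inside] == 0))
  expect_identical(dim(rmap$data), dim(m$data))
  # every masked voxel here is far from the border: full coverage
  expect_equal(sum(inside), sum(mask))
})

test_that("border voxels are uncovered rather than padded", {
  m <- fixture_map(15)
  mask <- array(FALSE, c(15, 15, 15))
  mask[2, 2, 2] <- TRUE    # too close to the border for a 13^3 window
  mask[8, 8, 8] <- TRUE
  rmap <- estimate_local_resolution(m, as_mask(mask), constant_predictor(4.2))
  expect_equal(sum(rmap$coverage), 1)
  expect_equal(rmap$n_uncovered, 1)
  expect_equal(rmap$data[8, 8, 8], 4.2)
  expect_equal(rmap$data[2, 2, 2], 0)
})

test_that("summaries: constant map, percentile-median agreement, histogram", {
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  rmap <- estimate_local_resolution(m, as_mask(mask), constant_predictor(4.2))
  s <- summarize_resolution(rmap)
  expect_equal(s$median, 4.2)
  expect_equal(s$sd, 0)
  expect_equal(sum(s$histogram$counts), s$n_voxels)
  # non-constant map: percentile(50) equals the sort-based median oracle
  vary <- function(cubes) seq_len(ncol(cubes)) %% 7 + 3
  rv <- estimate_local_resolution(m, as_mask(mask), vary)
  sv <- summarize_resolution(rv, percentiles = c(20, 50))
  vals <- rv$data[rv$mask & rv$coverage]
  expect_equal(sv$percentiles[["50"]], median(vals))
  expect_equal(sum(sv$histogram$counts), length(vals))
  expect_error(summarize_resolution(rv, percentiles = c(0, 50)),
               class = "voxres_validation_error")
})

test_that("global intensity scaling leaves the estimate untouched", {
  m <- fixture_map(18)
  mask <- array(FALSE, c(18, 18, 18)); mask[8:11, 8:11, 8:11] <- TRUE
  reg <- build_regressor(band_spec(1.0, filter_bank_spec(3, 12, 1)), seed = 4)
  r1 <- suppressWarnings(estimate_local_resolution(m, as_mask(mask), reg))
  m2 <- density_map(m$data * 57.3, m$voxel_size)
  r2 <- suppressWarnings(estimate_local_resolution(m2, as_mask(mask), reg))
  expect_identical(r1$data, r2$data)
})

test_that("resolution map exports as MRC with zeros outside the mask", {
  m <- fixture_map(18)
  mask <- array(FALSE, c(18, 18, 18)); mask[8:11, 8:11, 8:11] <- TRUE
  rmap <- estimate_local_resolution(m, as_mask(mask), constant_predictor(6))
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(rmap, p)
  r <- read_map(p)
  expect_equal(sum(r$data == 6), sum(rmap$coverage & rmap$mask))
  expect_equal(sum(r$data != 0), sum(rmap$coverage & rmap$mask))
})

test_that("audit: closest-percentile recommendation and oversharpening flags", {
  # stub world mirroring the reference outcome: percentiles 4.8/4.4/4.0/3.4
  # for B = 0/-30/-60/-100 against a reference of 4.0 -> recommend -60,
  # flag -100 only
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  # stub driven by a closure counter (estimate order follows b_grid)
  i <- 0
  stub <- function(cubes) {
    i <<- i + 1
    rep(c(4.8, 4.4, 4.0, 3.4)[i], ncol(cubes))
  }
  audit <- audit_sharpening(m, as_mask(mask), stub, reference = 4.0,
                            b_grid = c(0, -30, -60, -100))
  expect_equal(audit$recommended_b, -60)
  expect_identical(audit$sweep$flagged_oversharpened,
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(audit$sweep$percentile_value, c(4.8, 4.4, 4.0, 3.4))
})

test_that("audit degenerate case: b_grid = {0} against its own summary", {
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  ref <- summarize_resolution(
    estimate_local_resolution(m, as_mask(mask), constant_predictor(5)),
    percentiles = 20)
  audit <- audit_sharpening(m, as_mask(mask), constant_predictor(5), ref,
                            b_grid = 0)
  expect_equal(audit$recommended_b, 0)
  expect_false(any(audit$sweep$flagged_oversharpened))
})

test_that("audit with a linear stub matches the closed-form crossing point", {
  # prediction improves linearly with |B|: p(B) = 6 - 0.02 * |B|; reference
  # 4.8 A crosses at |B| = 60
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  b_grid <- seq(0, -100, by = -10)
  i <- 0
  stub <- function(cubes) { i <<- i + 1; rep(6 - 0.02 * abs(b_grid[i]), ncol(cubes)) }
  audit <- audit_sharpening(m, as_mask(mask), stub, reference = 4.8,
                            b_grid = b_grid)
  expect_equal(audit$recommended_b, -60)
  expect_identical(audit$sweep$flagged_oversharpened, abs(b_grid) > 60)
})

test_that("audit validates inputs and reference forms", {
  m <- fixture_map(20)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:13, 8:13, 8:13] <- TRUE
  expect_error(audit_sharpening(m, as_mask(mask), constant_predictor(5),
                                reference = 4, b_grid = numeric(0)),
               class = "voxres_validation_error")
  ref_no20 <- summarize_resolution(
    estimate_local_resolution(m, as_mask(mask), constant_predictor(5)),
    percentiles = 50)
  expect_error(audit_sharpening(m, as_mask(mask), constant_predictor(5),
                                ref_no20, b_grid = 0),
               "lacks", class = "voxres_validation_error")
})

test_that("estimate validates inputs", {
  m <- fixture_map(15)
  expect_error(estimate_local_resolution(m, full_mask(m), "not a regressor"),
               class = "voxres_validation_error")
  # mask with voxels only at the border: nothing coverable
  mask <- array(FALSE, c(15, 15, 15)); mask[1, 1, 1] <- TRUE
  expect_error(estimate_local_resolution(m, as_mask(mask),
                                         constant_predictor(5)),
               class = "voxres_validation_error")
})
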