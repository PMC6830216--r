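test_that("architecture is fixed and validated; conv preserves dimensions", {
  expect_error(network_config(conv_filters = 16), "fixed",
               class = "voxres_validation_error")
  expect_error(network_config(dropout_p = 1), class = "voxres_validation_error")
  cfg <- network_config()
  expect_equal(cfg$conv_filters, 32L)
  expect_equal(cfg$padding, "same")
  # dimension preservation: the weight shapes encode conv output 13^3 x 32
  reg <- build_regressor(wide_band(), seed = 1)
  expect_identical(dim(reg$weights$Wc), c(2197L, 32L))
  expect_identical(dim(reg$weights$W1), c(2197L * 32L, 512L))
  expect_identical(dim(reg$weights$W2), c(512L, 1L))
})

test_that("forward pass: finite scalar, deterministic builds and predictions", {
  set.seed(10)
  cube <- rnorm(2197); cube <- matrix(cube / l2(cube), ncol = 1)
  r1 <- build_regressor(wide_band(), seed = 42)
  r2 <- build_regressor(wide_band(), seed = 42)
  p1 <- predict_cubes(r1, cube); p2 <- predict_cubes(r2, cube)
  expect_true(is.finite(p1))
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_identical(as.numeric(predict_cubes(r1, cube)), as.numeric(p1))
  r3 <- build_regressor(wide_band(), seed = 43)
  expect_false(identical(as.numeric(predict_cubes(r3, cube)), as.numeric(p1)))
})

test_that("predictions clip to the band and non-unit-norm cubes are rejected", {
  reg <- build_regressor(band_spec(1.0, filter_bank_spec(3, 12, 1)), seed = 1)
  set.seed(11)
  cubes <- apply(matrix(rnorm(2197 * 10), 2197), 2, function(v) v / l2(v))
  p <- predict_cubes(reg, cubes)
  expect_true(all(p >= 3 & p <= 12))
  expect_error(predict_cubes(reg, cubes * 2), "unit norm",
               class = "voxres_validation_error")
})

test_that("training validates corpus and labels", {
  reg <- build_regressor(band_spec(1.0, filter_bank_spec(3, 12, 1)), seed = 1)
  empty <- structure(list(cubes = matrix(0, 2197, 0), labels = numeric(0),
                          n_skipped_zero_norm = 0L), class = "labeled_boxes")
  expect_error(train_regressor(reg, empty), "empty",
               class = "voxres_validation_error")
  set.seed(12)
  bad <- structure(list(
    cubes = apply(matrix(rnorm(2197 * 4), 2197), 2, function(v) v / l2(v)),
    labels = c(3, 5, 14, 6), n_skipped_zero_norm = 0L),
    class = "labeled_boxes")
  expect_error(train_regressor(reg, bad), "14", class = "voxres_validation_error")
})

test_that("two-box overfit: capacity sanity at a few hundred Adam steps", {
  # two real density boxes labeled 3 and 9 A; dropout disabled because
  # its injected noise precludes exact memorization of two samples
  model <- fixture_model(60, seed = 7)
  band <- band_spec(1.0, filter_bank_spec(3, 12, 1))
  corpus <- make_corpus(model, band = band, bank = filter_bank_spec(3, 9, 6),
                        per_label = 1L, seed = 4L)
  expect_equal(sort(corpus$labels), c(3, 9))
  reg <- build_regressor(band, config = network_config(dropout_p = 0),
                         seed = 2)
  reg <- train_regressor(reg, corpus, training_config(
    learning_rate = 1e-3, batch_size = 2, epochs = 300,
    validation_fraction = 0, seed = 3, warmup_steps = 10))
  p <- predict_cubes(reg, corpus$cubes)
  expect_equal(as.numeric(p), corpus$labels, tolerance = 0.1 / 3)
  # loss history: monotone trend (endpoint far below start)
  h <- reg$history$train_mse
  expect_lt(tail(h, 1), 0.01 * h[1])
})

test_that("training is deterministic under seeds and loss trends down", {
  set.seed(14)
  n <- 60
  cubes <- apply(matrix(rnorm(2197 * n), 2197), 2, function(v) v / l2(v))
  # synthetic learnable signal: label encoded in the cube mean
  labels <- rep(c(4, 8), length.out = n)
  cubes <- sweep(cubes, 2, labels * 1e-3, `+`)
  cubes <- apply(cubes, 2, function(v) v / l2(v))
  boxes <- structure(list(cubes = cubes, labels = labels,
                          n_skipped_zero_norm = 0L), class = "labeled_boxes")
  tc <- training_config(learning_rate = 1e-3, batch_size = 16, epochs = 4,
                        validation_fraction = 0.2, seed = 5,
                        warmup_steps = 4)
  reg0 <- build_regressor(band_spec(1.0, filter_bank_spec(3, 12, 1)), seed = 6)
  r1 <- train_regressor(reg0, boxes, tc)
  r2 <- train_regressor(reg0, boxes, tc)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history$train_mse, 1), r1$history$train_mse[1])
  expect_true(all(is.finite(r1$history$val_mse)))
})

test_that("checkpoint round trip preserves weights and metadata", {
  reg <- build_regressor(wide_band(), seed = 3)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(reg, p)
  r <- load_checkpoint(p)
  expect_identical(r$weights, reg$weights)
  expect_identical(r$band$voxel_size, reg$band$voxel_size)
  expect_error(load_checkpoint(tempfile()), class = "voxres_io_error")
  q <- withr::local_tempfile(fileext = ".ckpt")
  saveRDS(list(1), q)
  expect_error(load_checkpoint(q), class = "voxres_io_error")
})
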