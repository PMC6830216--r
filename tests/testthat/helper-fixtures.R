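# Shared fixtures, all built in code.

# small deterministic test map: smooth blob plus texture, strictly positive
fixture_map <- function(n = 24, voxel = 1.0, seed = 42) {
  set.seed(seed)
  ax <- seq(-1, 1, length.out = n)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  a <- exp(-3 * r2) + 0.05 * array(runif(n^3), c(n, n, n))
  density_map(a, voxel)
}

fixture_model <- function(n_atoms = 60, seed = 7) {
  generate_synthetic_structure(
    synthetic_structure_spec(n_atoms = n_atoms, seed = seed))
}

full_mask <- function(map) as_mask(array(TRUE, dim(map$data)))

l2 <- function(v) sqrt(sum(v^2))

# stub predictor returning a constant (exercises the estimate contract
# without a trained network)
constant_predictor <- function(value) function(cubes) rep(value, ncol(cubes))

# a trained regressor is expensive (~minutes); train it at most once per
# test run and reuse (tests needing it share this cache)
.tiny_reg_cache <- new.env(parent = emptyenv())
tiny_trained_regressor <- function() {
  if (!is.null(.tiny_reg_cache$reg)) return(.tiny_reg_cache$reg)
  set.seed(99)
  band <- band_spec(1.0, filter_bank_spec(3, 12, 3))  # labels 3,6,9,12
  models <- lapply(1:3, function(i) fixture_model(n_atoms = 80, seed = 100 + i))
  corpus <- make_corpus(models, band = band, per_label = 6L, seed = 5L)
  reg <- build_regressor(band, seed = 1L)
  reg <- train_regressor(reg, corpus, training_config(
    learning_rate = 1e-3, batch_size = 32L, epochs = 6L,
    validation_fraction = 0.1, seed = 2L))
  .tiny_reg_cache$reg <- reg
  reg
}
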