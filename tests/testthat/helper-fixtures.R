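# Shared fixtures: small phantom specs and cached tiny datasets so the
# training-path tests do not regenerate data per test.

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(height = 32, width = 32, tumor_count_range = c(1, 2),
         tumor_radius_range = c(3, 5), vessel_count = 1),
    list(...))
  do.call(phantom_spec, args)
}

.fixture_env <- new.env(parent = emptyenv())

# A 32x32 half-noisy train/val/test trio, built once per test run.
tiny_trio <- function() {
  if (is.null(.fixture_env$trio)) {
    dir <- file.path(tempdir(), "noisyseg_tiny_trio")
    .fixture_env$trio <- noisyseg:::make_study_data(
      tiny_spec(), n_train = 8, n_val = 2, n_test = 4, noise_rate = 0.5,
      plan = default_corruption_plan(), dir = dir, seed = 42)
  }
  .fixture_env$trio
}

rand_mask <- function(h, w, p = 0.3, seed = 1) {
  noisyseg:::with_seed(seed, matrix(rbinom(h * w, 1, p), h, w))
}

rand_prob <- function(h, w, seed = 1) {
  noisyseg:::with_seed(seed, matrix(runif(h * w), h, w))
}
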