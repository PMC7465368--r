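# Shared fixtures, generated once per test run and cached on disk.

.fixture_cache <- new.env(parent = emptyenv())

# Default 2-class synthetic dataset (breakhis layout) with its scan,
# split and 64-px patch manifest.
fixture_dataset <- function() {
  if (!is.null(.fixture_cache$ds)) return(.fixture_cache$ds)
  dir <- file.path(tempdir(), "msimf_fixture_ds")
  man <- generate_dataset(synthetic_spec(seed = 7), dir, force = TRUE)
  records <- scan_dataset(dir, "breakhis")
  split <- patient_split(records, 0.7, seed = 7)
  patches <- prepare_patches(records, paste0(dir, "_patches"),
                             out_size = 64L)
  patches$split <- ifelse(patches$source %in% split$train, "train", "test")
  .fixture_cache$ds <- list(dir = dir, manifest = man, records = records,
                            split = split, patches = patches)
  .fixture_cache$ds
}

# A tiny flat texture image with controllable tint.
tinted_texture <- function(w = 48L, h = 40L, tint = c(0.9, 0.7, 0.8),
                           seed = 1L) {
  set.seed(seed)
  base <- matrix(runif(w * h, 0.3, 0.7), w, h)
  img <- array(0, c(w, h, 3L))
  for (ch in 1:3) img[, , ch] <- base * tint[ch]
  img
}

# Small architecture used wherever the full-size network is not the
# point of the test.
tiny_spec <- function(taps = 1:4, n_classes = 2L, input_side = 32L,
                      dropout = 0) {
  suppressWarnings(architecture_spec(
    input_side = input_side, stem_channels = 8L, growth = 4L,
    block_repeats = c(2L, 2L, 2L, 2L), bottleneck_factor = 2L,
    taps = taps, n_classes = n_classes, dropout = dropout))
}
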