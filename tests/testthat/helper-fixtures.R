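# Session-memoised fixtures so expensive synthetic objects are built once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

base_patch <- function(seed = 0, size = 256) {
  memo(sprintf("base_%d_%d", seed, size), generate_base_patch(seed, size))
}

small_dataset <- function() {
  memo("small_ds", generate_dataset(60, seed = 5, out_size = 64))
}

# Small trained network shared by tests that need a plausible (not
# necessarily strong) model.
tiny_fit <- function() {
  memo("tiny_fit", {
    ds <- generate_dataset(150, seed = 9, out_size = 64)
    qnet(ds, config = qnet_config_reduced(epochs = 2), seed = 1)
  })
}

rect_region <- function(x0, y0, x1, y1) {
  list(shape = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}
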