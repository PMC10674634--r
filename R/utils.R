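# Internal helpers shared across modules.

# Run code under a given RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed for a pipeline sub-stage. Linear congruential
# mix kept below 2^31 - 1 so the result is a valid 32-bit seed.
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stage) * 8191
  as.integer(s %% 2147483647) + 1L
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# 8-bit raster in [0, 255] -> numeric in [0, 1] for png writing.
to_unit <- function(img) clip255(img) / 255

# png::readPNG output (numeric in [0, 1]) -> integer 0..255 matrix/array.
from_unit <- function(x) {
  storage.mode(x) <- "double"
  array(as.integer(round(x * 255)), dim = dim(x))
}

is_binary_raster <- function(x) {
  is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))
}
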