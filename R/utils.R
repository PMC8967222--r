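#' @importFrom rlang .data
#' @importFrom stats rnorm runif rexp rpois sd mad median optim setNames
#'   quantile complete.cases var
#' @importFrom utils head tail
NULL

# Derive a reproducible substream seed from a master seed, a stage name and a
# counter, so independent stages (simulation, fitting, rendering) never share
# an RNG stream. Plain 32-bit mixing; result always in [0, 2^31 - 2].
substream_seed <- function(seed, stage, counter = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 7919 + as.double(counter) * 104729 + 1) %% 2147483647)
}

# Run code under a local RNG state without disturbing the caller's stream.
with_substream <- function(seed, stage, counter, code) {
  withr::with_seed(substream_seed(seed, stage, counter), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
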