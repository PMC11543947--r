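#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from a single master seed through this
#' function, so that any experiment cell (a particular size, noise level,
#' replication, ...) can be re-executed in isolation. Mixing uses a Lehmer
#' multiplicative congruential step modulo the Mersenne prime 2^31 - 1, which
#' keeps every intermediate value exactly representable in a double.
#'
#' @param seed integer master seed.
#' @param ... further keys (integers, doubles, or character strings) that
#'   identify the child stream, e.g. `derive_seed(1, "size", 400, 2)`.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "fit", 3)
#' derive_seed(1, "fit", 3) == derive_seed(1, "fit", 3)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  a <- 48271
  state <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  keys <- list(...)
  for (k in keys) {
    ints <- if (is.character(k)) {
      as.numeric(utf8ToInt(paste(k, collapse = "|")))
    } else {
      # fold doubles to integers deterministically (handles e.g. 0.25)
      as.numeric(utf8ToInt(paste(format(k, digits = 15), collapse = ",")))
    }
    for (v in ints) {
      state <- (state * a + v + 1) %% m
      if (state == 0) state <- 1
    }
    state <- (state * a) %% m
    if (state == 0) state <- 1
  }
  as.integer(state)
}
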