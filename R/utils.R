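#' Derive a reproducible substream seed
#'
#' Hashes a root seed together with integer stream coordinates (for example
#' iteration, year index, species index) into a deterministic 32-bit seed.
#' Simulation functions use this so that any slice of a Monte-Carlo run --
#' a single iteration, year, or species row -- can be regenerated in
#' isolation, independently of execution order.
#'
#' @param root integer root seed.
#' @param ... integer stream coordinates.
#' @return A single integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, 3, 7)
#' @export
substream_seed <- function(root, ...) {
  # multiplicative congruential mix; 2^31 * 69069 < 2^53 so double
  # arithmetic stays exact
  h <- abs(as.numeric(root)) %% 2147483647
  for (x in as.numeric(c(...))) {
    h <- (h * 69069 + x + 12345) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
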