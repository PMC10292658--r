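`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from one master seed
#'
#' Many pipeline stages (one per trial, animal, or replicate) each need their
#' own seed while the whole run must be reproducible from a single integer.
#' Sub-seeds are drawn once from the master seed, so stage k always receives
#' the same seed regardless of how many stages run before it.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# scalar-in-range check used by the parameter constructors
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_invalid(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  as.numeric(x)
}
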