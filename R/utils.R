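#' Round to nearest integer, ties away from zero
#'
#' Reported percentages use commercial rounding (0.5 rounds up), not R's
#' round-half-even, so that printed values like 90\% are stable.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Internal: stop with a formatted message.
fail <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: derive a stage-specific RNG seed from a master seed, keeping the
# result inside the 32-bit integer range expected by set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647L)
}
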