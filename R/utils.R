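# Shared internal helpers: rounding, validation, seeded RNG.

#' Round half away from zero
#'
#' Printed Venn percentages follow the round-half-up convention (5 always
#' rounds away from zero at the last kept digit), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.05, 1)   # 0.1, where round() would give 0
#' round_half_up(6.4211, 1) # 6.4
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop with a classed condition so tests can match on class
stop_cmpn <- function(msg, class) {
  rlang::abort(msg, class = paste0("cmpnomics_", class))
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_cmpn(sprintf("`%s` must be a single integer >= %d", name, min),
              "invalid_config")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_cmpn(sprintf("`%s` must be a single number in [0, 1]", name),
              "invalid_config")
  }
  invisible(as.numeric(x))
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a stage-specific 32-bit sub-seed from a master seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
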