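# Rounding conventions used when matching published whole-percent tables.

#' Round to the nearest integer, halves away from zero
#'
#' Published percentage tables are conventionally produced with half-up
#' rounding (0.5 rounds to 1), whereas base R's `round()` uses IEEE
#' round-half-even. `round_half_up()` implements the half-up convention for
#' non-negative values; a small epsilon guards against binary representation
#' placing an exact arithmetic half a few ulps below 0.5.
#'
#' @param x Numeric vector of non-negative values.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, 2.6))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x), all(is.na(x) | x >= 0))
  floor(x + 0.5 + 1e-9)
}

# Dispatch on a rounding convention name ("half-up" matches printed tables,
# "half-even" probes sensitivity of feasibility findings to the convention).
round_percent <- function(x, rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  if (rounding == "half-up") round_half_up(x) else round(x)
}

# Internal: stop with a clear message unless a condition holds.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Internal: check a vector of probabilities.
check_prob <- function(p, name) {
  assert_that(is.numeric(p) && !anyNA(p) && all(p >= 0 & p <= 1),
              sprintf("'%s' must contain probabilities in [0, 1]", name))
}

# Internal: check a named categorical distribution sums to 1.
check_distribution <- function(p, name, levels) {
  check_prob(p, name)
  assert_that(setequal(names(p), levels),
              sprintf("'%s' must be named with levels: %s", name,
                      paste(levels, collapse = ", ")))
  assert_that(abs(sum(p) - 1) <= 1e-9,
              sprintf("'%s' must sum to 1 (got %.12f)", name, sum(p)))
}
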