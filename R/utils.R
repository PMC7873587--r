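#' Round half away from zero
#'
#' Converts unrounded household counts (fraction times denominator) to
#' integers. Ties round away from zero, so `round_half_away(0.5)` is 1 and
#' `round_half_away(-0.5)` is -1, unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Validate that `x` is a single number within [lo, hi]; `name` appears in the
# error so callers learn which field failed.
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s], got %s",
                 name, format(lo), format(hi),
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and non-missing", name),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under `seed` without disturbing the caller's RNG state; a NULL
# seed leaves the global stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
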