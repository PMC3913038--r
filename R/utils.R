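# Internal helpers shared across modules.

# Error function via the normal CDF; erf(x) = 2*pnorm(x*sqrt(2)) - 1.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Scalar validators. `what` appears in the error message.
check_scalar <- function(x, what, positive = FALSE, nonneg = FALSE,
                         lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", what))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", what))
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", what, format(lower), format(upper)))
  }
  invisible(x)
}

check_increasing <- function(t, what = "t") {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t)) {
    abort(sprintf("`%s` must be a numeric vector without NAs.", what))
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing.", what))
  }
  invisible(t)
}

# Seed handling: generators accept `seed = NULL` (use current RNG state) or an
# integer, in which case the global seed is set so runs are bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    check_scalar(seed, "seed")
    set.seed(as.integer(seed))
  }
  force(code)
}
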