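# Internal helpers shared across modules.

logit <- function(p) qlogis(p)
invlogit <- function(x) plogis(x)

# Validate that `x` is a probability (vectorised); `name` appears in errors.
assert_prob <- function(x, name, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad) || (!allow_na && anyNA(x))) {
    abort(sprintf("`%s` must be a proportion in [0, 1] (got %s).",
                  name, paste(format(x[bad | is.na(x)]), collapse = ", ")),
          class = "ltfu_validation_error")
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (anyNA(x) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive.", name),
          class = "ltfu_validation_error")
  }
  invisible(x)
}

# Jeffreys (Beta(1/2, 1/2) prior) interval for a binomial proportion.
jeffreys_ci <- function(x, n, level = 0.95) {
  alpha <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, qbeta(alpha, x + 0.5, n - x + 0.5))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha, x + 0.5, n - x + 0.5))
  c(lo, hi)
}

# Printing conventions used throughout: correction factors to 2 decimals,
# mortality percentages to 1 decimal.
fmt_factor <- function(c) formatC(round(c, 2), format = "f", digits = 2)
fmt_pct <- function(p) formatC(round(100 * p, 1), format = "f", digits = 1)

`%||%` <- function(x, y) if (is.null(x)) y else x
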