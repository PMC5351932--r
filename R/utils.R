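#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test fisher.test ks.test lm median pchisq
#'   pnorm pt qchisq qlogis qnorm plogis quantile residuals rbinom rgeom
#'   rnorm runif sd setNames t.test var complete.cases model.matrix rpois
#' @importFrom utils head tail
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  bad <- !is.finite(x) | x < 0 | x > 1 |
    (open_left & x == 0) | (open_right & x == 1)
  if (any(bad)) {
    stopf("%s must lie in %s0,1%s; offending value(s): %s", name,
          if (open_left) "(" else "[", if (open_right) ")" else "]",
          paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  invisible(x)
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) withr::with_seed(seed, code)

# Derive a distinct child seed from a base seed; stays within 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}
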