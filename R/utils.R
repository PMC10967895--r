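# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamps tiny negative mass to -Inf.
logdiffexp <- function(a, b) {
  if (b > a) {
    if (b - a < 1e-9) return(-Inf)
    warning("negative mass in log-diff-exp; clamping to zero")
    return(-Inf)
  }
  if (is.infinite(b)) return(a)
  a + log1p(-exp(b - a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# NA-tolerant scalar predicates: absent (NA/NULL) scores FALSE.
is_true_num <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)
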