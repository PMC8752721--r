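# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing randomness is funnelled through this.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# p-values are clamped away from 0 so downstream -log() stays finite.
clamp_p <- function(p) pmin(pmax(p, 1e-300), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Elementwise integer matrix power by repeated squaring; falls back to `^`
# for non-integer exponents. Cheaper than exp/log pow on large matrices.
elem_power <- function(x, beta) {
  if (beta == 1) return(x)
  if (beta != round(beta)) return(x^beta)
  b <- as.integer(beta)
  out <- NULL
  base <- x
  while (b > 0L) {
    if (b %% 2L == 1L) out <- if (is.null(out)) base else out * base
    b <- b %/% 2L
    if (b > 0L) base <- base * base
  }
  out
}

# Rows scaled to zero mean, unit variance, divided by sqrt(n-1) so that
# tcrossprod() of the result is the Pearson correlation matrix.
scale_rows_cor <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  xc / ss
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
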