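# Internal helpers shared across modules.

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and non-missing.", what))
  }
  invisible(x)
}

assert_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  invisible(x)
}

assert_rate <- function(x, what) {
  assert_finite(x, what)
  if (any(x < 0)) abort(sprintf("`%s` must be non-negative.", what))
  if (any(x > 1)) abort(sprintf("`%s` greater than 1 is rejected.", what))
  invisible(x)
}

as_chr <- function(x) as.character(x)

# Trailing moving average; the first (window - 1) entries average over
# whatever is available. NA entries are skipped in the average.
running_mean <- function(x, window) {
  n <- length(x)
  if (window < 1L) abort("`window` must be >= 1.")
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  cs <- cumsum(v)
  cn <- cumsum(as.numeric(ok))
  lag_cs <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  lag_cn <- c(rep(0, min(window, n)), cn[seq_len(max(0L, n - window))])
  num <- cs - lag_cs
  den <- cn - lag_cn
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

# Derive independent replicate seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
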