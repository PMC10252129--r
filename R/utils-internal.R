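# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row variances with n-1 denominator; rows of a numeric matrix.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_proportion <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !lo_ok || x > 1) {
    stop(sprintf("'%s' must be a proportion in %s", name,
                 if (allow_zero) "[0, 1]" else "(0, 1]"), call. = FALSE)
  }
  invisible(x)
}

# Deterministic per-study seed stream: adding a study never reshuffles the
# draws of earlier studies. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}
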