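# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stopf("%s must be finite and non-negative", what)
  invisible(x)
}

check_fraction <- function(x, what) {
  check_nonneg(x, what)
  if (any(x > 1)) stopf("%s must lie in [0, 1]", what)
  invisible(x)
}

# presentation rounding: computation stays full precision, tables round late
round1 <- function(x) round(x, 1)
pct_int <- function(x) round(x, 0)

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# config fingerprint without a heavyweight digest dependency.
# 32-bit modular multiply done in split halves (exact in doubles).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # bytes only touch the low 8 bits, so XOR just that byte
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h is a double holding a 32-bit value; format the halves as hex
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# truncated-normal draws (lower bound 0) via inverse CDF; sd of 0 collapses
# to the mean, matching the degenerate no-noise contract
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(0, mean, sd)
  qnorm(runif(n, plo, 1), mean, sd)
}
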