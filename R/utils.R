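# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > lo & x < hi) else all(x >= lo & x <= hi)
  if (!ok) stopf("`%s` must lie in %s%g, %g%s", name,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < min || x != round(x))
    stopf("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' @noRd
softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# 32-bit FNV-1a hash of a serialized R object; used to fingerprint configs
# in run manifests. Multiplication is split into 16-bit halves to stay
# within exact double-precision integer arithmetic.
fnv1a32 <- function(raw) {
  h <- 2166136261
  prime <- 16777619
  two32 <- 4294967296
  for (b in as.integer(raw)) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% two32
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # xor for doubles holding 32-bit unsigned values
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

#' Fingerprint an R object
#'
#' Stable 32-bit hash of a configuration object, reported in run manifests
#' so that outputs can be traced back to the exact configuration that
#' produced them.
#'
#' @param x Any serializable R object.
#' @return Hex string of the 32-bit FNV-1a hash.
#' @export
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # skip the serialization header (R version dependent)
  h <- fnv1a32(raw[-seq_len(14)])
  # h is a double in [0, 2^32): format as hex 16 bits at a time
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# deterministic lexicographic order for sample/variant ids
lex_order <- function(x) order(as.character(x), method = "radix")
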