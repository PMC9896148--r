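#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector of log values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## FNV-1a 32-bit hash of a character scalar; used to stamp output files with
## a provenance hash of the configuration
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                       # b < 256: xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    ## 32-bit modular multiply in two 16-bit halves (stays within double precision)
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  ## h is a double below 2^32; render the two 16-bit halves as hex
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .strip_classes))
  x
}

config_hash <- function(config) {
  .fnv1a(jsonlite::toJSON(.strip_classes(config), auto_unbox = TRUE,
                          digits = NA))
}
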