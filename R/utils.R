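# shared internal helpers

# format a double so that read-back agrees to < 1e-9 relative error and the
# byte representation is stable across runs
fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

# round times before set operations / matching; FE time grids are decimal
# fractions without exact binary representations
round_time <- function(t) round(t, 9)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over a UTF-8 string; fingerprints configs in provenance
# records (not cryptographic). 16777619 = 2^24 + 403, split to stay within
# double-precision exact-integer range.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
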