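`%||%` <- function(a, b) if (is.null(a)) b else a

# djb2-style hash of a character scalar, as 8 hex digits; used to stamp
# outputs with a fingerprint of the configuration they came from.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

pkg_version <- function() {
  as.character(utils::packageVersion("fibrildis"))
}
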