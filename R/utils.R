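# Internal helpers shared across modules.

#' Normalize an entity surface form into a graph id
#'
#' Entity ids are the surface names normalized by Unicode NFC and
#' whitespace trimming; no further canonicalization is applied (relation
#' canonicalization is a separate, LLM-mediated step).
#'
#' @param x character vector of surface names.
#' @return character vector of normalized ids.
#' @export
normalize_entity_id <- function(x) {
  stringi::stri_trans_nfc(trimws(enc2utf8(as.character(x))))
}

# 32-bit FNV-1a hash of a UTF-8 string, returned as 8 hex digits.
# Used to key LLM transcripts; the full prompt text stored alongside the
# hash is the authority, the hash is only an index.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(bitwAnd2_32(h)), b)
    h <- mulmod32(h, 16777619)
  }
  h <- h %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# (a * b) mod 2^32 without 53-bit overflow: split a into 16-bit halves.
mulmod32 <- function(a, b) {
  a <- as.double(a) %% 4294967296; b <- as.double(b)
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# Reduce a double in [0, 2^32) to a value usable by bitwXor (signed 32-bit).
bitwAnd2_32 <- function(x) {
  x <- x %% 4294967296
  if (x >= 2147483648) x - 4294967296 else x
}

# Derive a reproducible integer sub-seed (< 2^31) from a base seed and a
# module label, so all randomness flows from one configuration seed.
derive_seed <- function(seed, label) {
  h <- strtoi(substr(fnv1a32(paste0(label, ":", seed)), 1, 7), 16L)
  (as.integer(seed) %% 100003L) * 10007L %% 2147483647L + h %% 1000003L
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library internals never perturb user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mfh <- function(msg, class, ..., call. = FALSE) {
  cnd <- structure(
    class = c(class, "mfhrag_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  )
  stop(cnd)
}
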