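# Internal helpers: deterministic seeding, RNG scoping, small validators.

# Derive a per-stream seed from a master seed and a string key, so that
# adding a sample to a cohort never perturbs the reads of another sample.
# Polynomial rolling hash modulo the Mersenne prime 2^31 - 1.
derive_seed <- function(master_seed, key) {
  h <- as.double(master_seed) %% 2147483647
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Random DNA string(s) of the given length(s).
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 decoding/encoding of quality strings.
quality_to_phred <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

phred_to_quality <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used only to
# stamp outputs with a provenance hash of the run configuration.
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (c in utf8ToInt(paste(x, collapse = "\n"))) {
    # xor on the low byte only (h exceeds the integer range bitwXor allows)
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), as.integer(c %% 256))
    # 32-bit modular multiply by the FNV prime 16777619; split into 16-bit
    # halves so intermediate products stay exact in double arithmetic
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
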