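# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's C++ k-mer core: they work on
# character vectors with substring()/set operations only, so equality
# against them is a real cross-check.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of one sequence (windows containing N dropped), canonicalized
# by lexicographic min with the reverse complement; set semantics.
oracle_kmers <- function(seq, k, canonical = TRUE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("N", kms, fixed = TRUE)]
  if (!length(kms)) return(character(0))
  if (canonical) kms <- pmin(kms, oracle_revcomp(kms))
  unique(kms)
}

# Number of distinct canonical k-mers of `read` present in the k-mer set of
# the target read collection.
oracle_shared_count <- function(read, target_seqs, k, canonical = TRUE) {
  target <- unique(unlist(lapply(target_seqs, oracle_kmers, k = k,
                                 canonical = canonical)))
  sum(oracle_kmers(read, k, canonical) %in% target)
}

# Directional shared-read percentage by explicit per-read set intersection.
oracle_similarity_pct <- function(query_seqs, target_seqs, k, t,
                                  canonical = TRUE) {
  target <- unique(unlist(lapply(target_seqs, oracle_kmers, k = k,
                                 canonical = canonical)))
  shared <- vapply(query_seqs, function(r) {
    sum(oracle_kmers(r, k, canonical) %in% target) >= t
  }, logical(1))
  100 * sum(shared) / length(query_seqs)
}

# Benjamini-Hochberg by direct sorting and step-up, independent of p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Small in-memory library from explicit sequences (uniform high quality).
make_lib <- function(seqs, sample_id = "S1", subject_id = "X1",
                     role = "recipient", timepoint = "BL2",
                     quality_char = "G", donor_id = NA_character_) {
  sample_library(
    sample_id, subject_id, role, timepoint,
    data.frame(read_id = sprintf("%s_r%04d", sample_id, seq_along(seqs)),
               sequence = seqs,
               quality = strrep(quality_char, nchar(seqs)),
               stringsAsFactors = FALSE),
    donor_id = donor_id)
}

# Random read set drawn from a fresh random genome (reads exact substrings).
random_reads <- function(n, read_len = 60, genome_len = 5000) {
  g <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
             collapse = "")
  pos <- sample.int(genome_len - read_len + 1, n, replace = TRUE)
  substring(g, pos, pos + read_len - 1)
}

# Abundance profile built directly from a named percent vector.
as_profile <- function(abundance, sample_id = "P1") {
  abundance <- 100 * abundance / sum(abundance)
  structure(list(sample_id = sample_id, abundance = abundance,
                 n_assigned = 1000L, evaluable = TRUE),
            class = "abundance_profile")
}
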