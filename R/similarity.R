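# Alignment-free sample-to-sample similarity: a read of one sample is
# "shared" with another sample when it contains at least t distinct
# (canonical) k-mers that occur anywhere in the other sample's reads.

#' Similarity kernel configuration
#'
#' Defaults are the study parameterization: `k = 30`, `t = 2`, canonical
#' k-mers (a k-mer and its reverse complement are identified, so strand
#' never affects matching). Note that a read of length exactly `k`
#' contributes a single k-mer and can therefore never reach `t = 2`; this
#' is a documented boundary, not an error.
#'
#' @param k k-mer length in bases (1..31).
#' @param t minimum number of distinct shared k-mers for a read to count as
#'   shared.
#' @param canonical identify k-mers with their reverse complements.
#' @return an object of class `similarity_config`.
#' @export
similarity_config <- function(k = 30, t = 2, canonical = TRUE) {
  stopifnot(k >= 1, k <= 31, t >= 1)
  structure(list(k = as.integer(k), t = as.integer(t),
                 canonical = isTRUE(canonical)),
            class = "similarity_config")
}

#' Build a canonical k-mer index over a sample's reads
#'
#' The index is the exact set of canonical k-mers observed across all reads
#' (windows containing `N` are skipped). Exact membership is used rather
#' than a probabilistic filter: desk-scale libraries fit comfortably in
#' memory and exact sets make the kernel equal to its brute-force oracle.
#'
#' @param x a [sample_library()] or character vector of sequences.
#' @param config a [similarity_config()].
#' @param sample_id label carried on the index.
#' @return an object of class `kmer_index` (`k`, `canonical`, `n_kmers`,
#'   and an external-pointer membership structure, valid for the session;
#'   use [write_kmer_index()] for persistence).
#' @export
kmer_index <- function(x, config = similarity_config(),
                       sample_id = NA_character_) {
  seqs <- if (inherits(x, "sample_library")) {
    if (is.na(sample_id)) sample_id <- x$sample_id
    x$reads$sequence
  } else {
    as.character(x)
  }
  ptr <- cpp_kmer_set_build(seqs, config$k, config$canonical)
  structure(list(ptr = ptr, k = config$k, canonical = config$canonical,
                 n_kmers = cpp_kmer_set_size(ptr), sample_id = sample_id),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index%s: %s canonical %d-mers\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              format(x$n_kmers, big.mark = ","), x$k))
  invisible(x)
}

#' List the canonical k-mers stored in an index
#' @param index a [kmer_index()].
#' @return character vector of the stored k-mers, lexicographically sorted.
#' @export
index_kmers <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_kmer_set_dump(index$ptr, index$k)
}

#' Count distinct shared k-mers per read against an index
#'
#' @param reads a [sample_library()] or character vector of read sequences.
#' @param index a [kmer_index()].
#' @return integer vector: per read, the number of distinct canonical
#'   k-mers present in the index (0 for reads shorter than `k`).
#' @export
shared_kmer_count <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- if (inherits(reads, "sample_library")) reads$reads$sequence
          else as.character(reads)
  cpp_shared_kmer_counts(seqs, index$ptr, index$k, index$canonical)
}

# One direction: percent of query reads shared with the target index.
similarity_to_index <- function(query, index, config = similarity_config()) {
  if (index$k != config$k) {
    stopf("index was built at k=%d but config requests k=%d",
          index$k, config$k)
  }
  seqs <- if (inherits(query, "sample_library")) query$reads$sequence
          else as.character(query)
  if (!length(seqs)) stopf("query library is empty: similarity is undefined")
  n_shared <- sum(shared_kmer_count(seqs, index) >= config$t)
  list(n_reads = length(seqs), n_shared = n_shared,
       pct = 100 * n_shared / length(seqs))
}

#' Pairwise shared-read similarity between two samples
#'
#' Computes, in both directions, the percentage of reads of one sample that
#' are shared with the other (a read is shared when it contains at least
#' `t` distinct canonical k-mers present anywhere in the other sample's
#' reads), plus the symmetric score
#' `100 * (shared_q_in_t + shared_t_in_q) / (n_q + n_t)`.
#'
#' @param query,target [sample_library()] objects (or character vectors of
#'   read sequences); both must be non-empty.
#' @param config a [similarity_config()].
#' @param target_index optional pre-built [kmer_index()] of `target`
#'   (reused across pairs); `query_index` likewise.
#' @param query_index optional pre-built index of `query`.
#' @return an object of class `similarity_result` with fields `query_id`,
#'   `target_id`, `n_query_reads`, `n_query_shared`, `pct_query_in_target`,
#'   the reverse-direction fields, and `symmetric_pct`.
#' @export
similarity <- function(query, target, config = similarity_config(),
                       target_index = NULL, query_index = NULL) {
  qid <- if (inherits(query, "sample_library")) query$sample_id else "query"
  tid <- if (inherits(target, "sample_library")) target$sample_id else "target"
  if (is.null(target_index)) target_index <- kmer_index(target, config, tid)
  if (is.null(query_index)) query_index <- kmer_index(query, config, qid)
  fwd <- similarity_to_index(query, target_index, config)
  rev <- similarity_to_index(target, query_index, config)
  structure(list(
    query_id = qid, target_id = tid,
    n_query_reads = fwd$n_reads, n_query_shared = fwd$n_shared,
    pct_query_in_target = fwd$pct,
    n_target_reads = rev$n_reads, n_target_shared = rev$n_shared,
    pct_target_in_query = rev$pct,
    symmetric_pct = 100 * (fwd$n_shared + rev$n_shared) /
      (fwd$n_reads + rev$n_reads)
  ), class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Shared-read similarity %s vs %s\n", x$query_id, x$target_id))
  cat(sprintf("  %s in %s: %.2f%% (%d / %d reads)\n", x$query_id,
              x$target_id, x$pct_query_in_target, x$n_query_shared,
              x$n_query_reads))
  cat(sprintf("  %s in %s: %.2f%% (%d / %d reads)\n", x$target_id,
              x$query_id, x$pct_target_in_query, x$n_target_shared,
              x$n_target_reads))
  cat(sprintf("  symmetric: %.2f%%\n", x$symmetric_pct))
  invisible(x)
}

#' @method as.data.frame similarity_result
#' @export
as.data.frame.similarity_result <- function(x, ...) {
  data.frame(query_id = x$query_id, target_id = x$target_id,
             n_query_reads = x$n_query_reads,
             n_query_shared = x$n_query_shared,
             pct_query_in_target = x$pct_query_in_target,
             n_target_reads = x$n_target_reads,
             n_target_shared = x$n_target_shared,
             pct_target_in_query = x$pct_target_in_query,
             symmetric_pct = x$symmetric_pct, stringsAsFactors = FALSE)
}

#' Save / load a k-mer index as sorted text
#'
#' The first line records `k`, canonicalization and the sample id; one
#' canonical k-mer per following line, lexicographically sorted.
#'
#' @param index a [kmer_index()].
#' @param path file path.
#' @return the path (write) or a `kmer_index` (read).
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#kmer_index\tk=%d\tcanonical=%d\tsample=%s",
                     index$k, as.integer(index$canonical),
                     index$sample_id), con)
  writeLines(cpp_kmer_set_dump(index$ptr, index$k), con)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (hdr[1] != "#kmer_index") stopf("not a k-mer index file: %s", path)
  field <- function(key) sub(paste0(key, "="), "",
                             grep(paste0("^", key, "="), hdr, value = TRUE))
  k <- as.integer(field("k"))
  canonical <- field("canonical") == "1"
  kmers <- lines[-1]
  # each stored k-mer is already canonical; one window per line rebuilds it
  ptr <- cpp_kmer_set_build(kmers, k, canonical)
  structure(list(ptr = ptr, k = k, canonical = canonical,
                 n_kmers = cpp_kmer_set_size(ptr),
                 sample_id = field("sample")),
            class = "kmer_index")
}
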