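# Read quality-control cascade: host-read screen, exact-duplicate removal,
# ambiguous-end trimming, prefix-quality/length filter, and the
# sequencing-depth gate that marks samples CNBP ("could not be performed").

#' Quality-control configuration
#'
#' Defaults follow the HiSeq-like setting: reads are screened over their
#' first 80 bases and must remain at least 80 bp after end-trimming; use
#' `prefix_length = 120` for MiSeq-like 150 bp reads. A read fails the
#' quality rule when its mean Phred score over the first `prefix_length`
#' bases is below `min_quality` (the rule is deliberately a mean, not
#' per-base: a per-base threshold at Phred 6 would discard nearly every real
#' library because of isolated bad cycles). The depth gate defaults to the
#' production value of ten million reads; desk-scale simulated runs pass an
#' explicitly smaller `min_reads_after_filtering`.
#'
#' @param prefix_length bases over which the quality rule is evaluated.
#' @param min_quality minimum mean Phred score over the prefix.
#' @param min_length minimum read length after end-trimming (defaults to
#'   `prefix_length`).
#' @param min_reads_after_filtering depth gate; samples with fewer surviving
#'   reads are flagged CNBP and excluded from similarity analysis.
#' @param host_kmer_length k-mer length of the host screen.
#' @param host_min_shared_kmers distinct host k-mers a read must share to be
#'   called host-derived (mirrors the similarity kernel's shared-k-mer rule).
#' @param max_host_fraction optional second CNBP trigger: samples whose
#'   host-removed fraction exceeds this are flagged CNBP (default 1 =
#'   disabled).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(prefix_length = 80, min_quality = 6,
                      min_length = prefix_length,
                      min_reads_after_filtering = 1e7,
                      host_kmer_length = 31, host_min_shared_kmers = 2,
                      max_host_fraction = 1) {
  stopifnot(prefix_length > 0, min_quality > 0, min_length > 0,
            min_reads_after_filtering > 0, host_kmer_length >= 1,
            host_kmer_length <= 31, host_min_shared_kmers >= 1,
            max_host_fraction > 0)
  structure(list(prefix_length = as.integer(prefix_length),
                 min_quality = min_quality,
                 min_length = as.integer(min_length),
                 min_reads_after_filtering = min_reads_after_filtering,
                 host_kmer_length = as.integer(host_kmer_length),
                 host_min_shared_kmers = as.integer(host_min_shared_kmers),
                 max_host_fraction = max_host_fraction),
            class = "qc_config")
}

#' Remove host-derived reads by canonical k-mer screening
#'
#' A read is called host-derived (and removed) when it shares at least
#' `host_min_shared_kmers` distinct canonical k-mers of length
#' `host_kmer_length` with the host reference. The order of surviving reads
#' is preserved.
#'
#' @param library a [sample_library()].
#' @param host_reference character vector of host reference sequence(s), or
#'   a FASTA path.
#' @param config a [qc_config()].
#' @return list with elements `library` (filtered), `removed_count` and
#'   `removed_ids`.
#' @export
remove_host_reads <- function(library, host_reference, config = qc_config()) {
  stopifnot(inherits(library, "sample_library"))
  if (length(host_reference) == 1 && file.exists(host_reference)) {
    host_reference <- as.character(Biostrings::readDNAStringSet(host_reference))
  }
  if (!length(host_reference) || !any(nzchar(host_reference))) {
    stopf("host reference is empty")
  }
  if (nrow(library$reads) == 0) {
    return(list(library = library, removed_count = 0L,
                removed_ids = character(0)))
  }
  xp <- cpp_kmer_set_build(host_reference, config$host_kmer_length, TRUE)
  hits <- cpp_shared_kmer_counts(library$reads$sequence, xp,
                                 config$host_kmer_length, TRUE)
  drop <- hits >= config$host_min_shared_kmers
  out <- library
  out$reads <- library$reads[!drop, , drop = FALSE]
  list(library = out, removed_count = sum(drop),
       removed_ids = library$reads$read_id[drop])
}

#' Remove exact duplicate reads
#'
#' Among reads with byte-identical raw sequences (duplicates are assessed
#' before any trimming), only the first occurrence is retained. Mates of
#' paired libraries are treated as independent reads.
#'
#' @inheritParams remove_host_reads
#' @return list with `library`, `removed_count`, `removed_ids`.
#' @export
remove_duplicates <- function(library) {
  stopifnot(inherits(library, "sample_library"))
  dup <- duplicated(library$reads$sequence)
  out <- library
  out$reads <- library$reads[!dup, , drop = FALSE]
  list(library = out, removed_count = sum(dup),
       removed_ids = library$reads$read_id[dup])
}

#' Trim ambiguous bases from read ends
#'
#' Removes leading and trailing runs of `N` from sequence and quality in
#' lockstep; interior `N`s are untouched. A read consisting entirely of `N`
#' becomes empty (and is then removed by the length filter).
#'
#' @param sequence,quality character vectors of equal lengths per element.
#' @return list with trimmed `sequence` and `quality` vectors.
#' @export
trim_ambiguous_ends <- function(sequence, quality) {
  stopifnot(length(sequence) == length(quality),
            all(nchar(sequence) == nchar(quality)))
  lead <- nchar(sequence) - nchar(sub("^N+", "", sequence))
  trail <- nchar(sequence) - nchar(sub("N+$", "", sequence))
  # an all-N read must not be trimmed twice over
  all_n <- lead == nchar(sequence)
  trail[all_n] <- 0L
  from <- lead + 1L
  to <- nchar(sequence) - trail
  list(sequence = substring(sequence, from, to),
       quality = substring(quality, from, to))
}

#' Filter reads on prefix quality and post-trimming length
#'
#' A read is removed when (a) its mean Phred score over the first
#' `prefix_length` bases (or over the whole read if shorter) is below
#' `min_quality`, or (b) its length after trimming is below `min_length`.
#'
#' @inheritParams remove_host_reads
#' @return list with `library`, `removed_count`, and the reason split
#'   (`removed_short_ids`, `removed_low_quality_ids`).
#' @export
quality_filter <- function(library, config = qc_config()) {
  stopifnot(inherits(library, "sample_library"))
  reads <- library$reads
  len <- nchar(reads$sequence)
  short <- len < config$min_length
  qmean <- vapply(quality_to_phred(reads$quality), function(s) {
    if (!length(s)) return(0)
    mean(s[seq_len(min(length(s), config$prefix_length))])
  }, numeric(1))
  lowq <- !short & qmean < config$min_quality
  drop <- short | lowq
  out <- library
  out$reads <- reads[!drop, , drop = FALSE]
  list(library = out, removed_count = sum(drop),
       removed_short_ids = reads$read_id[short],
       removed_low_quality_ids = reads$read_id[lowq])
}

#' Apply the full quality-control cascade to a sample
#'
#' Stage order: host removal, duplicate removal, ambiguous-end trimming,
#' quality/length filter. Because the host screen runs first, a host read is
#' never counted as a duplicate. The report reconciles exactly: input reads
#' equal the per-stage removals plus the reads remaining. The sample is
#' flagged CNBP when fewer than `min_reads_after_filtering` reads survive,
#' or when the host-removed fraction exceeds `max_host_fraction`.
#'
#' @inheritParams remove_host_reads
#' @param host_reference host reference sequence(s) or FASTA path; `NULL`
#'   skips the host stage.
#' @return list with the filtered `library` and a `report` of class
#'   `qc_report` (per-stage counts and fractions, `reads_remaining`,
#'   `cnbp`).
#' @export
apply_qc <- function(library, host_reference = NULL, config = qc_config()) {
  stopifnot(inherits(library, "sample_library"))
  n_in <- nrow(library$reads)
  if (!is.null(host_reference)) {
    host <- remove_host_reads(library, host_reference, config)
  } else {
    host <- list(library = library, removed_count = 0L)
  }
  dedup <- remove_duplicates(host$library)
  lib <- dedup$library
  trimmed <- trim_ambiguous_ends(lib$reads$sequence, lib$reads$quality)
  lib$reads$sequence <- trimmed$sequence
  lib$reads$quality <- trimmed$quality
  qf <- quality_filter(lib, config)
  n_out <- nrow(qf$library$reads)
  counts <- c(host = host$removed_count, duplicate = dedup$removed_count,
              short = length(qf$removed_short_ids),
              low_quality = length(qf$removed_low_quality_ids))
  stopifnot(sum(counts) + n_out == n_in)
  host_frac <- if (n_in > 0) counts[["host"]] / n_in else 0
  report <- structure(list(
    sample_id = library$sample_id,
    reads_in = n_in,
    removed = counts,
    fractions = if (n_in > 0) counts / n_in else counts * 0,
    host_fraction = host_frac,
    reads_remaining = n_out,
    cnbp = n_out < config$min_reads_after_filtering ||
      host_frac > config$max_host_fraction
  ), class = "qc_report")
  list(library = qf$library, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for %s: %d reads in, %d remaining%s\n",
              x$sample_id, x$reads_in, x$reads_remaining,
              if (x$cnbp) " [CNBP]" else ""))
  cat(sprintf("  removed: host %d, duplicate %d, short %d, low-quality %d\n",
              x$removed[["host"]], x$removed[["duplicate"]],
              x$removed[["short"]], x$removed[["low_quality"]]))
  invisible(x)
}

# qc_report list -> one-row data.frame (for the pipeline's TSV output)
qc_report_row <- function(r) {
  data.frame(sample_id = r$sample_id, reads_in = r$reads_in,
             removed_host = r$removed[["host"]],
             removed_duplicate = r$removed[["duplicate"]],
             removed_short = r$removed[["short"]],
             removed_low_quality = r$removed[["low_quality"]],
             reads_remaining = r$reads_remaining,
             cnbp = r$cnbp, stringsAsFactors = FALSE)
}
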