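# Read-level simulation: sample libraries, FASTQ I/O, and the generator's
# ground-truth sidecar used to validate the QC cascade.

QUAL_GOOD <- 38L  # error-free base
QUAL_ERR <- 8L    # substituted base
QUAL_BAD <- 2L    # injected uniformly low-quality read

#' Construct a sample library of sequencing reads
#'
#' A sample library groups reads (sequence plus Phred quality, both as
#' strings of equal length) with the sample's study metadata: subject,
#' role (donor or recipient), donor pairing and timepoint label.
#'
#' @param sample_id,subject_id character scalars; `sample_id` must be unique
#'   within a cohort.
#' @param role `"donor"` or `"recipient"`.
#' @param timepoint one of the labels in [timepoint_labels()].
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   and optionally `mate` (1, 2 or NA).
#' @param donor_id id of the paired donor subject (recipients only).
#' @param paired logical flag for paired-end libraries.
#' @param truth optional generator ground-truth sidecar (see
#'   [generate_reads()]).
#' @return an object of class `sample_library`.
#' @export
sample_library <- function(sample_id, subject_id, role, timepoint, reads,
                           donor_id = NA_character_, paired = FALSE,
                           truth = NULL) {
  role <- match.arg(role, c("donor", "recipient"))
  if (!timepoint %in% TIMEPOINT_LEVELS) {
    stopf("unknown timepoint label '%s' (expected one of %s)", timepoint,
          paste(TIMEPOINT_LEVELS, collapse = ", "))
  }
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  if (!all(c("read_id", "sequence", "quality") %in% names(reads))) {
    stopf("reads must have columns read_id, sequence, quality")
  }
  if (is.null(reads$mate)) reads$mate <- rep(NA_integer_, nrow(reads))
  if (anyDuplicated(reads$read_id)) {
    stopf("read ids must be unique within a library")
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stopf("sequence and quality lengths differ for some reads")
  }
  if (nrow(reads) && any(grepl("[^ACGTN]", reads$sequence))) {
    stopf("read sequences may only contain A, C, G, T, N")
  }
  structure(list(sample_id = sample_id, subject_id = subject_id, role = role,
                 timepoint = timepoint, donor_id = donor_id, paired = paired,
                 reads = reads, truth = truth),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat(sprintf("Sample library %s: %s %s (%s), %d reads%s\n",
              x$sample_id, x$role, x$subject_id, x$timepoint, nrow(x$reads),
              if (x$paired) ", paired-end" else ""))
  invisible(x)
}

#' Number of reads in a sample library
#' @param x a [sample_library()].
#' @return integer read count.
#' @export
n_reads <- function(x) {
  stopifnot(inherits(x, "sample_library"))
  nrow(x$reads)
}

#' Simulate shotgun reads from a community at a given ground-truth abundance
#'
#' Emulates Illumina-like shotgun output from a synthetic community.
#' Fragment start positions are uniform over each genome, strands are chosen
#' uniformly (minus-strand reads are reverse-complemented), a `host_fraction`
#' of reads is drawn from the host reference, per-base substitution errors
#' are applied at `model$error_rate` (substituted bases get Phred 8 instead
#' of 38), a `bad_read_fraction` of reads gets a uniform Phred-2 quality
#' string, and a `duplicate_fraction` of reads is re-emitted verbatim with
#' fresh read ids. The returned library carries a ground-truth sidecar
#' (`$truth`) recording each read's origin, the injected host / duplicate /
#' bad-read ids and the true abundances, for downstream validation.
#'
#' Deterministic given `model$seed` and `sample_id` (the per-sample stream is
#' derived by hashing the two, so adding a sample never perturbs another).
#'
#' @param model a [community_model()].
#' @param abundance named percent abundance vector over `model$species_ids`
#'   summing to 100 (e.g. from [mix_communities()]).
#' @param n_reads number of (pre-duplication) reads; in paired mode the total
#'   is rounded up to an even count.
#' @param read_length read length in bp (93 emulates the HiSeq-like setting,
#'   150 the MiSeq-like one); must not exceed the genome length.
#' @param sample_id,subject_id,role,timepoint,donor_id sample metadata
#'   (see [sample_library()]).
#' @param paired emit mate pairs from opposite ends of a fragment.
#' @param insert_size fragment length in paired mode.
#' @return a [sample_library()] with ground truth in `$truth`.
#' @export
generate_reads <- function(model, abundance, n_reads, read_length = 93,
                           sample_id, subject_id = sample_id,
                           role = "recipient", timepoint = "BL2",
                           donor_id = NA_character_, paired = FALSE,
                           insert_size = 300) {
  stopifnot(inherits(model, "community_model"))
  if (n_reads < 1) stopf("n_reads must be >= 1")
  check_abundance(abundance, "abundance", tol = 1e-6)
  glen <- nchar(model$genomes)
  if (read_length > min(glen)) {
    stopf("read_length %d exceeds the shortest genome (%d bp)",
          read_length, min(glen))
  }
  frag_len <- if (paired) insert_size else read_length
  if (paired && insert_size > min(glen)) {
    stopf("insert_size %d exceeds the shortest genome", insert_size)
  }

  with_seed(derive_seed(model$seed, sample_id), {
    n_frag <- if (paired) ceiling(n_reads / 2) else n_reads
    is_host <- runif(n_frag) < model$host_fraction
    origin <- character(n_frag)
    origin[is_host] <- "host"
    n_mic <- sum(!is_host)
    if (n_mic > 0) {
      origin[!is_host] <- sample(model$species_ids, n_mic, replace = TRUE,
                                 prob = abundance / 100)
    }
    src_seq <- ifelse(origin == "host", model$host_reference %||% "",
                      model$genomes[origin])
    src_len <- nchar(src_seq)
    pos <- 1 + floor(runif(n_frag) * (src_len - frag_len + 1))
    frags <- substring(src_seq, pos, pos + frag_len - 1)
    minus <- runif(n_frag) < 0.5
    if (any(minus)) frags[minus] <- reverse_complement(frags[minus])

    if (paired) {
      seqs <- c(rbind(substring(frags, 1, read_length),
                      reverse_complement(
                        substring(frags, frag_len - read_length + 1,
                                  frag_len))))
      origin <- rep(origin, each = 2)
      mate <- rep(c(1L, 2L), n_frag)
    } else {
      seqs <- frags
      mate <- rep(NA_integer_, n_frag)
    }
    n_emit <- length(seqs)

    # substitution errors with a two-level quality model
    quals <- rep(strrep(intToUtf8(QUAL_GOOD + 33L), read_length), n_emit)
    if (model$error_rate > 0) {
      n_err <- rbinom(n_emit, read_length, model$error_rate)
      for (i in which(n_err > 0)) {
        at <- sample.int(read_length, n_err[i])
        s <- seqs[i]
        q <- quals[i]
        for (p in at) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          substr(q, p, p) <- intToUtf8(QUAL_ERR + 33L)
        }
        seqs[i] <- s
        quals[i] <- q
      }
    }

    bad <- runif(n_emit) < model$bad_read_fraction
    quals[bad] <- strrep(intToUtf8(QUAL_BAD + 33L), read_length)

    # verbatim duplicate copies appended with fresh ids
    n_dup <- round(model$duplicate_fraction * n_emit)
    dup_src <- if (n_dup > 0) sample.int(n_emit, n_dup, replace = TRUE)
               else integer(0)
  })

  all_seqs <- c(seqs, seqs[dup_src])
  all_quals <- c(quals, quals[dup_src])
  all_origin <- c(origin, origin[dup_src])
  total <- length(all_seqs)
  ids <- sprintf("%s_r%06d", sample_id, seq_len(total))
  if (paired) {
    all_mate <- c(mate, mate[dup_src])
    ids <- paste0(ids, "/", all_mate)
  } else {
    all_mate <- rep(NA_integer_, total)
  }

  dup_new_ids <- ids[n_emit + seq_len(n_dup)]
  truth <- list(
    abundance = abundance,
    origin = setNames(all_origin, ids),
    host_ids = ids[all_origin == "host"],
    duplicate_ids = dup_new_ids,
    duplicate_of = setNames(ids[dup_src], dup_new_ids),
    bad_ids = ids[c(bad, bad[dup_src])],
    n_emitted = total,
    n_primary = n_emit
  )
  sample_library(sample_id, subject_id, role, timepoint,
                 data.frame(read_id = ids, sequence = all_seqs,
                            quality = all_quals, mate = all_mate,
                            stringsAsFactors = FALSE),
                 donor_id = donor_id, paired = paired, truth = truth)
}

#' Expected QC outcome from generator ground truth
#'
#' Replays the QC cascade's stage order (host removal, duplicate removal,
#' end-trimming, quality/length filter) as pure bookkeeping on the
#' generator's sidecar: host reads are those the generator drew from the
#' host reference, duplicates are non-first occurrences of a sequence among
#' the reads surviving the host stage, low-quality reads are the injected
#' Phred-2 reads, and short reads are those below `min_length`. Exact for
#' `error_rate = 0`; with errors the host-screen prediction remains a very
#' close approximation (an error can at most perturb shared k-mer counts).
#'
#' @param library a [generate_reads()] library carrying `$truth`.
#' @param config a [qc_config()].
#' @return list with per-stage expected removal id vectors and counts.
#' @export
expected_qc_counts <- function(library, config = qc_config()) {
  stopifnot(inherits(library, "sample_library"))
  if (is.null(library$truth)) stopf("library carries no ground-truth sidecar")
  reads <- library$reads
  host_ids <- intersect(reads$read_id, library$truth$host_ids)
  rest <- reads[!reads$read_id %in% host_ids, , drop = FALSE]
  dup_ids <- rest$read_id[duplicated(rest$sequence)]
  rest <- rest[!rest$read_id %in% dup_ids, , drop = FALSE]
  short_ids <- rest$read_id[nchar(gsub("^N+|N+$", "", rest$sequence)) <
                              config$min_length]
  rest <- rest[!rest$read_id %in% short_ids, , drop = FALSE]
  bad_ids <- intersect(rest$read_id, library$truth$bad_ids)
  remaining <- setdiff(rest$read_id, bad_ids)
  list(host_ids = host_ids, duplicate_ids = dup_ids, short_ids = short_ids,
       low_quality_ids = bad_ids,
       counts = c(host = length(host_ids), duplicate = length(dup_ids),
                  short = length(short_ids),
                  low_quality = length(bad_ids)),
       reads_remaining = length(remaining))
}

#' Write / read a sample library as FASTQ (Phred+33)
#'
#' @param library a [sample_library()].
#' @param path FASTQ file path.
#' @return `write_sample_fastq` returns `path` invisibly; `read_sample_fastq`
#'   returns a [sample_library()].
#' @export
write_sample_fastq <- function(library, path) {
  stopifnot(inherits(library, "sample_library"))
  seqs <- Biostrings::DNAStringSet(library$reads$sequence)
  names(seqs) <- library$reads$read_id
  Biostrings::writeXStringSet(
    seqs, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(library$reads$quality))
  invisible(path)
}

#' @rdname write_sample_fastq
#' @param sample_id,subject_id,role,timepoint,donor_id,paired metadata for
#'   the reconstructed library (FASTQ itself stores none).
#' @export
read_sample_fastq <- function(path, sample_id, subject_id = sample_id,
                              role = "recipient", timepoint = "BL2",
                              donor_id = NA_character_, paired = FALSE) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- names(x)
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L,
                                               NA_integer_))
  sample_library(sample_id, subject_id, role, timepoint,
                 data.frame(read_id = ids, sequence = as.character(x),
                            quality = as.character(S4Vectors::mcols(x)$qualities),
                            mate = mate, stringsAsFactors = FALSE),
                 donor_id = donor_id, paired = paired)
}
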