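# Species-specific marker database: the stand-in for a clade-specific
# marker-gene catalogue used by the read profiler.

#' Build a species-specific marker database from a community model
#'
#' Draws `markers_per_species` subsequences of length `marker_length` from
#' each species' genome, rejection-sampling candidates until no marker k-mer
#' (at the profiler's `kmer_length`) is shared between two species. The
#' uniqueness property is what lets [profile_abundance()] assign each read
#' to at most one species.
#'
#' @param model a [community_model()].
#' @param markers_per_species markers drawn per species.
#' @param marker_length marker length in bp; must exceed `kmer_length`.
#' @param kmer_length k-mer length the downstream profiler will use.
#' @param max_retries rejection-sampling attempts per marker before failing.
#' @return an object of class `marker_db`: a marker table
#'   (`marker_id`, `species`, `sequence`) plus the profiling k-mer length.
#' @export
make_marker_db <- function(model, markers_per_species = 10,
                           marker_length = 300, kmer_length = 24,
                           max_retries = 100) {
  stopifnot(inherits(model, "community_model"))
  if (marker_length <= kmer_length) {
    stopf("marker_length (%d) must exceed the profiler k-mer length (%d)",
          marker_length, kmer_length)
  }
  glen <- nchar(model$genomes)
  if (marker_length > min(glen)) {
    stopf("marker_length %d exceeds the shortest genome", marker_length)
  }
  claimed <- new.env(parent = emptyenv(), hash = TRUE)
  rows <- vector("list", length(model$species_ids) * markers_per_species)
  i <- 0L
  with_seed(derive_seed(model$seed, "marker_db"), {
    for (sp in model$species_ids) {
      g <- model$genomes[[sp]]
      for (m in seq_len(markers_per_species)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          pos <- sample.int(nchar(g) - marker_length + 1, 1)
          cand <- substr(g, pos, pos + marker_length - 1)
          kms <- kmer_strings(cand, kmer_length)
          owners <- unlist(mget(kms, envir = claimed, ifnotfound = NA),
                           use.names = FALSE)
          if (!any(!is.na(owners) & owners != sp)) {
            for (km in kms) assign(km, sp, envir = claimed)
            i <- i + 1L
            rows[[i]] <- data.frame(
              marker_id = sprintf("%s_m%02d", sp, m), species = sp,
              sequence = cand, stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stopf("could not draw a unique marker for %s after %d retries",
                sp, max_retries)
        }
      }
    }
  })
  db <- structure(list(markers = do.call(rbind, rows[seq_len(i)]),
                       kmer_length = kmer_length, canonical = TRUE),
                  class = "marker_db")
  # construction guarantee: no k-mer claimed by two species
  built <- marker_kmer_map(db)
  if (built$n_collisions > 0) {
    stopf("marker database violates the uniqueness property (%d collisions)",
          built$n_collisions)
  }
  db
}

# Canonical k-mer strings of a sequence (set semantics, sorted).
kmer_strings <- function(sequence, k, canonical = TRUE) {
  xp <- cpp_kmer_set_build(sequence, as.integer(k), canonical)
  cpp_kmer_set_dump(xp, as.integer(k))
}

# k-mer -> species-index map for read assignment; species levels attached.
marker_kmer_map <- function(db) {
  stopifnot(inherits(db, "marker_db"))
  species <- unique(db$markers$species)
  built <- cpp_kmer_map_build(db$markers$sequence,
                              match(db$markers$species, species),
                              as.integer(db$kmer_length), db$canonical)
  built$species <- species
  built
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf(
    "Marker database: %d markers over %d species (%d bp, profiling k = %d)\n",
    nrow(x$markers), length(unique(x$markers$species)),
    nchar(x$markers$sequence[1]), x$kmer_length))
  invisible(x)
}

#' Write / read a marker database as FASTA
#'
#' Headers carry the species id and marker id separated by `|`.
#'
#' @param db a [make_marker_db()] database.
#' @param path FASTA file path.
#' @param kmer_length profiling k-mer length to attach on read-back.
#' @return the path (write) or a `marker_db` (read).
#' @export
write_marker_fasta <- function(db, path) {
  stopifnot(inherits(db, "marker_db"))
  x <- Biostrings::DNAStringSet(db$markers$sequence)
  names(x) <- paste(db$markers$species, db$markers$marker_id, sep = "|")
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_marker_fasta
#' @export
read_marker_fasta <- function(path, kmer_length = 24) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  structure(list(
    markers = data.frame(
      marker_id = vapply(parts, function(p) p[min(2, length(p))], ""),
      species = vapply(parts, `[[`, "", 1),
      sequence = as.character(x), stringsAsFactors = FALSE),
    kmer_length = kmer_length, canonical = TRUE), class = "marker_db")
}
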