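# Synthetic community models: the ground truth that downstream estimators
# (similarity, DSI, taxonomic rules) are tested against.

#' Construct a synthetic donor/recipient community model
#'
#' A community model holds everything needed to simulate a donor-recipient
#' pair of gut metagenomes: per-species synthetic genomes, donor and
#' recipient relative-abundance vectors (percent, each summing to 100),
#' an engraftment schedule mapping post-transplant timepoints to the mixing
#' fraction pi in \[0, 1\] (the ground-truth analogue of engraftment that the
#' Donor Similarity Index estimates), and the read-level noise model
#' (host-read contamination, per-base substitution errors, duplicate reads,
#' and an optional fraction of uniformly low-quality "bad" reads).
#'
#' @param species_ids character vector of species identifiers.
#' @param genomes named character vector of genome sequences, one per species.
#' @param donor_abundance,recipient_abundance numeric vectors of percent
#'   abundances (same order as `species_ids`); each must sum to 100 within
#'   1e-9. Species absent from a subject have abundance 0.
#' @param engraftment_schedule named numeric vector mapping post-transplant
#'   timepoint labels to mixing fractions pi in \[0, 1\].
#' @param host_fraction fraction in \[0, 1) of reads drawn from the host
#'   reference (human-DNA contamination analogue).
#' @param error_rate per-base substitution probability.
#' @param duplicate_fraction fraction of reads re-emitted verbatim
#'   (PCR/optical duplicate analogue).
#' @param bad_read_fraction fraction of reads whose quality string is set
#'   uniformly to Phred 2, to exercise the quality filter.
#' @param host_reference host reference sequence (single character string);
#'   defaults to a 100 kb random sequence when `host_fraction > 0`.
#' @param seed master integer seed; all per-sample streams derive from it.
#' @return an object of class `community_model`.
#' @seealso [make_community()] for randomly drawn models,
#'   [mix_communities()], [generate_reads()].
#' @export
community_model <- function(species_ids, genomes, donor_abundance,
                            recipient_abundance,
                            engraftment_schedule = numeric(0),
                            host_fraction = 0, error_rate = 0,
                            duplicate_fraction = 0, bad_read_fraction = 0,
                            host_reference = NULL, seed = 1L) {
  species_ids <- as.character(species_ids)
  n <- length(species_ids)
  if (n < 2) stopf("a community model needs at least 2 species, got %d", n)
  if (length(genomes) != n || length(donor_abundance) != n ||
      length(recipient_abundance) != n) {
    stopf("genomes and abundance vectors must match species_ids in length")
  }
  for (nm in c("host_fraction", "error_rate", "duplicate_fraction",
               "bad_read_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      stopf("%s must be in [0, 1), got %s", nm, format(v))
    }
  }
  check_abundance(donor_abundance, "donor_abundance")
  check_abundance(recipient_abundance, "recipient_abundance")
  if (length(engraftment_schedule) &&
      (any(engraftment_schedule < 0) || any(engraftment_schedule > 1))) {
    stopf("engraftment fractions must lie in [0, 1]")
  }
  if (is.null(host_reference) && host_fraction > 0) {
    host_reference <- with_seed(derive_seed(seed, "host"), random_dna(1e5))
  }
  structure(list(
    species_ids = species_ids,
    genomes = setNames(as.character(genomes), species_ids),
    donor_abundance = setNames(as.numeric(donor_abundance), species_ids),
    recipient_abundance = setNames(as.numeric(recipient_abundance), species_ids),
    engraftment_schedule = engraftment_schedule,
    host_fraction = host_fraction,
    error_rate = error_rate,
    duplicate_fraction = duplicate_fraction,
    bad_read_fraction = bad_read_fraction,
    host_reference = host_reference,
    seed = as.integer(seed)
  ), class = "community_model")
}

check_abundance <- function(x, what, total = 100, tol = 1e-9) {
  if (any(x < 0)) stopf("%s has negative entries", what)
  if (abs(sum(x) - total) > tol) {
    stopf("%s must sum to %g within %g (got %.12g)", what, total, tol, sum(x))
  }
  invisible(x)
}

#' Draw a random donor/recipient community model
#'
#' Species abundances are drawn log-normally (long-tailed, as observed in
#' gut metagenomes) and renormalized to 100 percent within each subject.
#' `overlap_fraction` controls the fraction of the species pool shared by
#' donor and recipient; non-shared species are split between donor-only and
#' recipient-only pools and have abundance exactly 0 in the other subject.
#'
#' @inheritParams community_model
#' @param n_species total number of species across both subjects (>= 2).
#' @param overlap_fraction fraction in \[0, 1\] of species shared between
#'   donor and recipient.
#' @param genome_length length in bp of each synthetic genome.
#' @param sigma log-scale standard deviation of the log-normal abundance draw.
#' @param species_prefix prefix of the generated species identifiers (lets
#'   several pair-level models coexist in one cohort without id clashes).
#' @return a [community_model()] object; deterministic given `seed`.
#' @export
make_community <- function(n_species = 20, overlap_fraction = 0.5,
                           genome_length = 20000, sigma = 1,
                           engraftment_schedule = c(WK1 = 0.6, MO1 = 0.4,
                                                    MO2_3 = 0.1),
                           host_fraction = 0, error_rate = 0,
                           duplicate_fraction = 0, bad_read_fraction = 0,
                           host_reference = NULL, species_prefix = "sp",
                           seed = 1L) {
  if (n_species < 2) stopf("n_species must be >= 2, got %d", n_species)
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stopf("overlap_fraction must be in [0, 1], got %g", overlap_fraction)
  }
  species_ids <- sprintf("%s%02d", species_prefix, seq_len(n_species))
  n_shared <- round(overlap_fraction * n_species)
  n_rest <- n_species - n_shared
  donor_only <- recipient_only <- character(0)
  if (n_rest > 0) {
    rest <- species_ids[(n_shared + 1):n_species]
    donor_only <- rest[seq_len(ceiling(n_rest / 2))]
    recipient_only <- setdiff(rest, donor_only)
  }
  shared <- species_ids[seq_len(n_shared)]
  with_seed(derive_seed(seed, "community"), {
    genomes <- random_dna(rep(genome_length, n_species))
    draw <- function(support) {
      x <- setNames(numeric(n_species), species_ids)
      x[support] <- rlnorm(length(support), meanlog = 0, sdlog = sigma)
      100 * x / sum(x)
    }
    donor_ab <- draw(c(shared, donor_only))
    recipient_ab <- draw(c(shared, recipient_only))
  })
  community_model(species_ids, genomes, donor_ab, recipient_ab,
                  engraftment_schedule = engraftment_schedule,
                  host_fraction = host_fraction, error_rate = error_rate,
                  duplicate_fraction = duplicate_fraction,
                  bad_read_fraction = bad_read_fraction,
                  host_reference = host_reference, seed = seed)
}

#' Mix donor and recipient communities at a scheduled engraftment fraction
#'
#' Returns the post-transplant ground-truth abundance vector
#' `(1 - pi) * recipient + pi * donor` for the mixing fraction pi recorded in
#' the model's engraftment schedule at `timepoint_label`. At pi = 0 the
#' community is exactly the recipient's; at pi = 1 exactly the donor's
#' (perfect engraftment).
#'
#' @param model a [community_model()].
#' @param timepoint_label a label present in `model$engraftment_schedule`,
#'   or one of `BL1`/`BL2` (returned as the pure recipient community).
#' @return named numeric vector of percent abundances summing to 100.
#' @export
mix_communities <- function(model, timepoint_label) {
  stopifnot(inherits(model, "community_model"))
  if (timepoint_label %in% c("BL1", "BL2", "TP")) {
    return(model$recipient_abundance)
  }
  if (!timepoint_label %in% names(model$engraftment_schedule)) {
    stopf("timepoint '%s' is not in the engraftment schedule (%s)",
          timepoint_label,
          paste(names(model$engraftment_schedule), collapse = ", "))
  }
  pi <- model$engraftment_schedule[[timepoint_label]]
  (1 - pi) * model$recipient_abundance + pi * model$donor_abundance
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "Synthetic community model: %d species, genomes %s bp\n",
    length(x$species_ids),
    format(nchar(x$genomes[[1]]), big.mark = ",")))
  cat(sprintf("  donor support: %d species; recipient support: %d species\n",
              sum(x$donor_abundance > 0), sum(x$recipient_abundance > 0)))
  if (length(x$engraftment_schedule)) {
    cat("  engraftment schedule:",
        paste(sprintf("%s=%.2f", names(x$engraftment_schedule),
                      x$engraftment_schedule), collapse = ", "), "\n")
  }
  cat(sprintf(
    "  noise: host %.3f, error %.4f, duplicates %.3f, bad reads %.3f\n",
    x$host_fraction, x$error_rate, x$duplicate_fraction,
    x$bad_read_fraction))
  invisible(x)
}
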