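# Cohort-level simulation: donor/recipient pairs with a known engraftment
# schedule, a shared host reference, and a combined marker database.

#' Simulate a donor/recipient FMT cohort with known engraftment ground truth
#'
#' Generates `n_pairs` independent donor-recipient pairs. Each pair gets its
#' own community model (its own synthetic genomes, so donors are mutually
#' distinguishable) and the samples of a longitudinal study: donor `BL2`,
#' recipient `BL1` and `BL2` (both drawn from the pure recipient community),
#' and post-transplant samples at the timepoints of `engraftment_schedule`,
#' drawn from the donor/recipient mixture at that timepoint's ground-truth
#' fraction pi. All samples share one host reference. Defaults emulate the
#' study conditions at desk scale: 93 bp reads, a long-tailed species
#' abundance profile, an engraftment schedule that rises at week 1 and
#' decays by 2-3 months, low-level host contamination, sequencing error,
#' duplicates and occasional junk reads.
#'
#' @param n_pairs number of donor-recipient pairs.
#' @param n_reads reads per sample (before duplicate re-emission).
#' @param read_length read length in bp.
#' @param engraftment_schedule named vector of ground-truth mixing
#'   fractions pi per post-transplant timepoint (shared by all pairs unless
#'   `schedules` is given).
#' @param schedules optional list of per-pair engraftment schedules
#'   (length `n_pairs`), overriding `engraftment_schedule`.
#' @param include_bl1 also emit a `BL1` sample per recipient.
#' @param markers_per_species,marker_length,profile_kmer_length marker
#'   database parameters (see [make_marker_db()]); set
#'   `markers_per_species = 0` to skip building one.
#' @inheritParams make_community
#' @param seed master seed; every per-sample stream derives from it.
#' @return list with `samples` (named list of [sample_library()]),
#'   `metadata` (data.frame), `models` (per-pair [community_model()]),
#'   `marker_db`, `host_reference`, `truth` (per-sample ground-truth pi and
#'   abundances) and `seed`.
#' @export
simulate_cohort <- function(n_pairs = 3, n_species = 12,
                            overlap_fraction = 0.3, genome_length = 20000,
                            sigma = 1,
                            engraftment_schedule = c(WK1 = 0.6, MO1 = 0.4,
                                                     MO2_3 = 0.1),
                            schedules = NULL,
                            n_reads = 20000, read_length = 93,
                            error_rate = 0.005, host_fraction = 0.02,
                            duplicate_fraction = 0.05,
                            bad_read_fraction = 0.005,
                            include_bl1 = TRUE,
                            markers_per_species = 10, marker_length = 300,
                            profile_kmer_length = 24, seed = 1L) {
  if (!is.null(schedules) && length(schedules) != n_pairs) {
    stopf("schedules must have one entry per pair")
  }
  host_ref <- with_seed(derive_seed(seed, "host"), random_dna(1e5))
  samples <- list()
  metadata <- list()
  models <- list()
  truth <- list()
  dbs <- list()
  for (i in seq_len(n_pairs)) {
    sched <- if (is.null(schedules)) engraftment_schedule else schedules[[i]]
    model <- make_community(
      n_species = n_species, overlap_fraction = overlap_fraction,
      genome_length = genome_length, sigma = sigma,
      engraftment_schedule = sched, host_fraction = host_fraction,
      error_rate = error_rate, duplicate_fraction = duplicate_fraction,
      bad_read_fraction = bad_read_fraction, host_reference = host_ref,
      species_prefix = sprintf("p%d_sp", i),
      seed = derive_seed(seed, sprintf("pair%d", i)))
    models[[i]] <- model
    donor_sub <- sprintf("D%d", i)
    rec_sub <- sprintf("R%d", i)

    emit <- function(subject, role, tp, abundance, donor_id = NA_character_) {
      sid <- sprintf("%s_%s", subject, tp)
      lib <- generate_reads(model, abundance, n_reads, read_length,
                            sample_id = sid, subject_id = subject,
                            role = role, timepoint = tp,
                            donor_id = donor_id)
      samples[[sid]] <<- lib
      metadata[[sid]] <<- data.frame(
        sample_id = sid, subject_id = subject, role = role,
        donor_id = donor_id, timepoint = tp, read_length = read_length,
        stringsAsFactors = FALSE)
      pi <- if (tp %in% names(sched)) sched[[tp]] else 0
      truth[[sid]] <<- list(pi = pi, abundance = abundance,
                            qc = lib$truth[c("host_ids", "duplicate_ids",
                                             "bad_ids")])
    }

    emit(donor_sub, "donor", "BL2", model$donor_abundance)
    if (include_bl1) {
      emit(rec_sub, "recipient", "BL1", model$recipient_abundance,
           donor_id = donor_sub)
    }
    emit(rec_sub, "recipient", "BL2", model$recipient_abundance,
         donor_id = donor_sub)
    for (tp in names(sched)) {
      emit(rec_sub, "recipient", tp, mix_communities(model, tp),
           donor_id = donor_sub)
    }
    if (markers_per_species > 0) {
      dbs[[i]] <- make_marker_db(model, markers_per_species, marker_length,
                                 profile_kmer_length)
    }
  }
  marker_db <- NULL
  if (length(dbs)) {
    marker_db <- structure(list(
      markers = do.call(rbind, lapply(dbs, `[[`, "markers")),
      kmer_length = profile_kmer_length, canonical = TRUE),
      class = "marker_db")
    built <- marker_kmer_map(marker_db)
    if (built$n_collisions > 0) {
      stopf("cross-pair marker k-mer collision (%d); use a larger k",
            built$n_collisions)
    }
  }
  meta <- do.call(rbind, metadata)
  rownames(meta) <- NULL
  list(samples = samples, metadata = meta, models = models,
       marker_db = marker_db, host_reference = host_ref, truth = truth,
       seed = as.integer(seed))
}
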