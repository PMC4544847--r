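# Marker-based species profiling, Shannon diversity, and the species-level
# engraftment rules (transplanted species, large changes, paired
# donor-vs-recipient test with FDR correction).

#' Taxonomic analysis configuration
#'
#' @param min_transplant_gain percent abundance a species undetectable at
#'   baseline must reach post-transplant to count as transplanted
#'   (default 0.2).
#' @param large_change_abs absolute abundance change (percentage points)
#'   flagged as large (default 5, i.e. flag changes greater than 5).
#' @param log_change_threshold magnitude in log10 units flagged as a
#'   log-scale change (default 1, "one logarithm").
#' @param detection_floor abundance at or below which a species counts as
#'   undetectable (default 0: exactly absent, as marker profilers report 0
#'   for species without assigned reads; exposed because real profilers
#'   have detection limits).
#' @param fdr_alpha Benjamini-Hochberg q-value threshold (default 0.05).
#' @return an object of class `taxonomy_config`.
#' @export
taxonomy_config <- function(min_transplant_gain = 0.2, large_change_abs = 5,
                            log_change_threshold = 1, detection_floor = 0,
                            fdr_alpha = 0.05) {
  stopifnot(min_transplant_gain >= 0, large_change_abs >= 0,
            log_change_threshold >= 0, detection_floor >= 0,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(min_transplant_gain = min_transplant_gain,
                 large_change_abs = large_change_abs,
                 log_change_threshold = log_change_threshold,
                 detection_floor = detection_floor,
                 fdr_alpha = fdr_alpha),
            class = "taxonomy_config")
}

#' Profile species relative abundance from marker-gene k-mers
#'
#' Each read is assigned to the unique species whose marker k-mers it
#' shares (at least `min_hits` distinct shared k-mers at the database's
#' k-mer length); reads matching no marker are unassigned. Because marker
#' k-mers are unique to one species by construction, a read matching two
#' species indicates a corrupt database and raises an error. Relative
#' abundance is 100 x reads assigned to the species / total assigned reads.
#'
#' @param library a (QC'd) [sample_library()].
#' @param marker_db a [make_marker_db()] database.
#' @param min_hits distinct shared marker k-mers required to assign a read.
#' @return an object of class `abundance_profile`: `sample_id`, `abundance`
#'   (named percent vector over the database's species, summing to 100 when
#'   any read is assigned), `n_assigned`, and `evaluable` (`FALSE` when no
#'   read was assigned).
#' @export
profile_abundance <- function(library, marker_db, min_hits = 1) {
  stopifnot(inherits(library, "sample_library"),
            inherits(marker_db, "marker_db"))
  map <- marker_kmer_map(marker_db)
  assign <- cpp_kmer_map_assign(library$reads$sequence, map$ptr,
                                as.integer(marker_db$kmer_length),
                                marker_db$canonical, as.integer(min_hits))
  if (any(assign == -1L)) {
    stopf("%d read(s) match markers of more than one species: %s",
          sum(assign == -1L),
          "marker uniqueness violated (corrupt marker database)")
  }
  counts <- tabulate(assign[assign > 0], nbins = length(map$species))
  names(counts) <- map$species
  n_assigned <- sum(counts)
  abundance <- if (n_assigned > 0) 100 * counts / n_assigned else counts * 0
  structure(list(sample_id = library$sample_id, abundance = abundance,
                 n_assigned = n_assigned, evaluable = n_assigned > 0),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("Abundance profile %s: %d assigned reads, %d species detected%s\n",
              x$sample_id, x$n_assigned, sum(x$abundance > 0),
              if (!x$evaluable) " [unevaluable]" else ""))
  if (x$evaluable) {
    top <- sort(x$abundance[x$abundance > 0], decreasing = TRUE)
    print(round(head(top, 8), 2))
  }
  invisible(x)
}

# percent abundance of species sp in a profile (0 if absent)
profile_ab <- function(profile, sp) {
  a <- profile$abundance[sp]
  ifelse(is.na(a), 0, a)
}

#' Shannon diversity of an abundance profile
#'
#' `H = -sum(p_i log p_i)` over species with `p_i > 0`, where
#' `p_i = abundance / 100`. Natural log by default (nats); the base is
#' configurable since the index is sometimes reported in bits or using
#' log10.
#'
#' @param profile an [profile_abundance()] result, or a numeric vector of
#'   percent abundances.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index (0 for a single-species community).
#' @export
shannon_index <- function(profile, base = exp(1)) {
  a <- if (inherits(profile, "abundance_profile")) {
    if (!profile$evaluable) {
      stopf("profile %s has no assigned reads: diversity undefined",
            profile$sample_id)
    }
    profile$abundance
  } else {
    as.numeric(profile)
  }
  p <- a[a > 0] / 100
  if (!length(p)) stopf("empty profile: diversity undefined")
  if (abs(sum(p) - 1) > 1e-6) stopf("abundances must sum to 100 percent")
  -sum(p * log(p, base = base))
}

#' Detect transplanted species in one recipient
#'
#' A species counts as transplanted when it is undetectable (at or below
#' the detection floor) in BOTH recipient baselines (`BL1` and `BL2`),
#' present in the donor, and reaches at least `min_transplant_gain` percent
#' abundance at one or more post-transplant timepoints. Qualifying species
#' are subtyped by when they appear: `transient` (1 week only),
#' `persistent` (every post-transplant timepoint), `late` (first at 1 month
#' or later), or `intermittent` (present at week 1 and again later but not
#' throughout).
#'
#' @param recipient_profiles named list of [profile_abundance()] results
#'   keyed by timepoint; must include `BL1` and `BL2`.
#' @param donor_profile the donor baseline profile.
#' @param config a [taxonomy_config()].
#' @return data.frame with one row per species in the donor-or-recipient
#'   universe: abundances, `qualifies`, and the `call` subtype (`NA` for
#'   non-qualifying species).
#' @export
detect_transplanted_species <- function(recipient_profiles, donor_profile,
                                        config = taxonomy_config()) {
  if (!all(c("BL1", "BL2") %in% names(recipient_profiles))) {
    stopf("both baseline profiles (BL1, BL2) are required")
  }
  post <- intersect(POST_TIMEPOINTS, names(recipient_profiles))
  if (!length(post)) stopf("no post-transplant profiles supplied")
  universe <- unique(c(names(donor_profile$abundance),
                       unlist(lapply(recipient_profiles,
                                     function(p) names(p$abundance)))))
  floor <- config$detection_floor
  gain <- config$min_transplant_gain
  rows <- lapply(universe, function(sp) {
    donor_ab <- profile_ab(donor_profile, sp)
    bl1 <- profile_ab(recipient_profiles$BL1, sp)
    bl2 <- profile_ab(recipient_profiles$BL2, sp)
    post_ab <- vapply(post, function(tp) {
      profile_ab(recipient_profiles[[tp]], sp)
    }, numeric(1))
    qualifies <- bl1 <= floor && bl2 <= floor && donor_ab > floor &&
      any(post_ab >= gain)
    call <- NA_character_
    if (qualifies) {
      present <- post_ab >= gain
      at_wk1 <- "WK1" %in% names(present) && present[["WK1"]]
      call <- if (at_wk1 && sum(present) == 1) {
        "transient"
      } else if (all(present)) {
        "persistent"
      } else if (!at_wk1) {
        "late"
      } else {
        "intermittent"
      }
    }
    cbind(data.frame(species = sp, donor = donor_ab, BL1 = bl1, BL2 = bl2,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(post_ab)),
          data.frame(qualifies = qualifies, call = call,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag large abundance changes between two profiles
#'
#' Computes, over the union of the two profiles' species, the absolute
#' change in percentage points and the log10 fold change (where both
#' abundances are positive; appearances from zero and disappearances to
#' zero are flagged instead of pseudocounted). Returns the species flagged
#' as either a large absolute change (`> large_change_abs` points) or a
#' log-scale change (`|log10 change| >= log_change_threshold`), or an
#' appearance/disappearance.
#'
#' @param pre_profile,post_profile [profile_abundance()] results (or named
#'   percent vectors).
#' @param config a [taxonomy_config()].
#' @return data.frame with columns `species`, `pre`, `post`, `abs_change`,
#'   `log_change`, `from_zero`, `to_zero`, `large_abs`, `log_flag`; empty
#'   for identical profiles.
#' @export
detect_large_changes <- function(pre_profile, post_profile,
                                 config = taxonomy_config()) {
  as_ab <- function(x) {
    if (inherits(x, "abundance_profile")) x$abundance else x
  }
  pre <- as_ab(pre_profile)
  post <- as_ab(post_profile)
  universe <- union(names(pre), names(post))
  p0 <- setNames(ifelse(is.na(pre[universe]), 0, pre[universe]), universe)
  p1 <- setNames(ifelse(is.na(post[universe]), 0, post[universe]), universe)
  abs_change <- abs(p1 - p0)
  log_change <- ifelse(p0 > 0 & p1 > 0, log10(p1 / p0), NA_real_)
  from_zero <- p0 == 0 & p1 > 0
  to_zero <- p0 > 0 & p1 == 0
  large_abs <- abs_change > config$large_change_abs
  log_flag <- !is.na(log_change) &
    abs(log_change) >= config$log_change_threshold
  keep <- large_abs | log_flag | from_zero | to_zero
  out <- data.frame(species = universe, pre = p0, post = p1,
                    abs_change = abs_change, log_change = log_change,
                    from_zero = from_zero, to_zero = to_zero,
                    large_abs = large_abs, log_flag = log_flag,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired donor-versus-recipient species abundance test with FDR correction
#'
#' For every species present in at least one sample, a paired two-tailed
#' t test compares donor and recipient abundances across donor-recipient
#' pairs; p values are corrected with the Benjamini-Hochberg false
#' discovery rate procedure. Species with `q < fdr_alpha` are flagged
#' significant; species reaching `p < 0.05` but not surviving correction
#' are flagged nominal-only. When every pairwise difference for a species
#' is zero the t statistic is undefined; such species are reported with
#' status `"constant"` and `NA` p (by convention they never enter the FDR
#' step).
#'
#' @param donor_profiles,recipient_profiles lists of
#'   [profile_abundance()] results, paired by position (donor i with
#'   recipient i); at least 2 pairs.
#' @param config a [taxonomy_config()].
#' @return an object of class `species_test`: a data.frame (`species`,
#'   `mean_donor`, `mean_recipient`, `t`, `p`, `q`, `significant`,
#'   `nominal_only`, `status`) plus a `status` attribute (`"ok"` or
#'   `"skipped"` when fewer than 2 pairs were supplied).
#' @export
donor_recipient_species_test <- function(donor_profiles, recipient_profiles,
                                         config = taxonomy_config()) {
  if (length(donor_profiles) != length(recipient_profiles)) {
    stopf("donor and recipient profile lists must be paired")
  }
  n <- length(donor_profiles)
  if (n < 2) {
    out <- data.frame()
    attr(out, "status") <- "skipped: fewer than 2 donor-recipient pairs"
    class(out) <- c("species_test", "data.frame")
    return(out)
  }
  universe <- unique(unlist(lapply(c(donor_profiles, recipient_profiles),
                                   function(p) names(p$abundance))))
  rows <- lapply(universe, function(sp) {
    d <- vapply(donor_profiles, profile_ab, numeric(1), sp)
    r <- vapply(recipient_profiles, profile_ab, numeric(1), sp)
    if (all(d == 0) && all(r == 0)) return(NULL)
    diffs <- d - r
    if (all(abs(diffs - diffs[1]) < .Machine$double.eps * 100) &&
        diffs[1] == 0) {
      return(data.frame(species = sp, mean_donor = mean(d),
                        mean_recipient = mean(r), t = NA_real_,
                        p = NA_real_, status = "constant",
                        stringsAsFactors = FALSE))
    }
    tt <- tryCatch(t.test(d, r, paired = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      return(data.frame(species = sp, mean_donor = mean(d),
                        mean_recipient = mean(r), t = NA_real_,
                        p = NA_real_, status = "constant",
                        stringsAsFactors = FALSE))
    }
    data.frame(species = sp, mean_donor = mean(d), mean_recipient = mean(r),
               t = unname(tt$statistic), p = tt$p.value, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q < config$fdr_alpha
  out$nominal_only <- !is.na(out$p) & out$p < 0.05 & !out$significant
  out <- out[, c("species", "mean_donor", "mean_recipient", "t", "p", "q",
                 "significant", "nominal_only", "status")]
  attr(out, "status") <- "ok"
  class(out) <- c("species_test", "data.frame")
  out
}
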