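# The cohort-level engraftment estimator: QC every sample, compute each
# recipient's DSI trajectory against their donor, classify patterns,
# evaluate the endpoint, and (with >= 2 donors) the donor-specificity check.

#' Estimate donor engraftment for a cohort of FMT samples
#'
#' The central fitting function of the package. Every sample library is
#' passed through the QC cascade ([apply_qc()]); samples failing the depth
#' gate are flagged CNBP and excluded from similarity computation (their
#' trajectory entries are reported as missing, never zero). For each
#' recipient, the baseline recipient-to-donor similarity `S0` (recipient
#' `BL2` versus donor `BL2`) and the post-transplant similarities `St` are
#' computed with the shared-k-mer kernel, giving the Donor Similarity Index
#' `DSI = 100 (St - S0) / (100 - S0)` per timepoint, the trajectory pattern,
#' and the endpoint evaluation. With at least two donors the
#' recipient-versus-all-donors specificity matrix is also computed.
#'
#' @param samples named list of [sample_library()] objects (names are sample
#'   ids); each library carries its subject, role, donor pairing and
#'   timepoint. Cohorts from [simulate_cohort()] can be passed directly.
#' @param host_reference host reference sequence(s) or FASTA path for the
#'   host-read screen; `NULL` skips host removal.
#' @param qc a [qc_config()].
#' @param similarity a [similarity_config()].
#' @param direction similarity direction used for S in the DSI (see
#'   [dsi_trajectory()]).
#' @param rise_threshold pattern-classifier threshold (see
#'   [classify_pattern()]).
#' @param endpoint_threshold,endpoint_timepoint endpoint rule: DSI strictly
#'   greater than `endpoint_threshold` percent at `endpoint_timepoint`.
#' @return an object of class `engraftment` with components
#'   `trajectories` (per-recipient [dsi_trajectory()] objects), `dsi`
#'   (recipients x post-timepoints matrix, `NA` = CNBP), `S0`, `patterns`,
#'   `endpoint`, `pairwise` (or `NULL`), `qc_reports`, `cnbp_samples` and
#'   the configuration used. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_pairs = 2, n_reads = 2000, seed = 42)
#' fit <- engraft(cohort$samples,
#'                host_reference = cohort$host_reference,
#'                qc = qc_config(min_reads_after_filtering = 500))
#' coef(fit)
#' summary(fit)
#' }
#' @export
engraft <- function(samples, host_reference = NULL, qc = qc_config(),
                    similarity = similarity_config(),
                    direction = c("recipient_to_donor", "symmetric"),
                    rise_threshold = 40, endpoint_threshold = 50,
                    endpoint_timepoint = "MO1") {
  direction <- match.arg(direction)
  if (is.list(samples) && !is.null(samples$samples)) {
    if (is.null(host_reference)) host_reference <- samples$host_reference
    samples <- samples$samples
  }
  stopifnot(length(samples) > 0,
            all(vapply(samples, inherits, TRUE, "sample_library")))
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(names(samples))) stopf("duplicate sample ids in cohort")

  qc_out <- lapply(samples, apply_qc, host_reference = host_reference,
                   config = qc)
  clean <- lapply(qc_out, `[[`, "library")
  reports <- lapply(qc_out, `[[`, "report")
  cnbp <- vapply(reports, `[[`, TRUE, "cnbp")

  meta <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, subject_id = s$subject_id,
               role = s$role, donor_id = s$donor_id,
               timepoint = s$timepoint, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL

  donor_bl2 <- meta$sample_id[meta$role == "donor" & meta$timepoint == "BL2"]
  donors <- setNames(clean[donor_bl2],
                     meta$subject_id[match(donor_bl2, meta$sample_id)])

  recipients <- unique(meta$subject_id[meta$role == "recipient"])
  trajectories <- list()
  for (r in recipients) {
    rows <- meta[meta$subject_id == r & meta$role == "recipient", ]
    if (!"BL2" %in% rows$timepoint) {
      stopf("recipient %s has no BL2 baseline sample", r)
    }
    rsamples <- setNames(clean[rows$sample_id], rows$timepoint)
    rcnbp <- rows$timepoint[cnbp[rows$sample_id]]
    did <- rows$donor_id[rows$timepoint == "BL2"][1]
    if (is.na(did) || !did %in% names(donors)) {
      stopf("recipient %s is paired with unknown donor '%s'", r, did)
    }
    dsam <- donors[[did]]
    # a CNBP donor baseline makes the whole trajectory CNBP
    if (cnbp[[dsam$sample_id]]) rcnbp <- union(rcnbp, "BL2")
    trajectories[[r]] <- dsi_trajectory(rsamples, dsam, similarity,
                                        direction = direction, cnbp = rcnbp)
    trajectories[[r]]$pattern <-
      classify_pattern(trajectories[[r]], rise_threshold)
  }

  dsi <- matrix(NA_real_, length(recipients), length(POST_TIMEPOINTS),
                dimnames = list(recipients, POST_TIMEPOINTS))
  for (r in recipients) {
    tab <- trajectories[[r]]$table
    dsi[r, tab$timepoint] <- tab$dsi
  }

  pairwise <- NULL
  usable_donors <- donors[!cnbp[vapply(donors, `[[`, "", "sample_id")]]
  if (length(usable_donors) >= 2) {
    rec_pairs <- list()
    for (r in recipients) {
      rows <- meta[meta$subject_id == r & meta$role == "recipient", ]
      ok <- rows$timepoint %in% c("BL2", "WK1") & !cnbp[rows$sample_id]
      libs <- setNames(clean[rows$sample_id[ok]], rows$timepoint[ok])
      if (all(c("BL2", "WK1") %in% names(libs))) rec_pairs[[r]] <- libs
    }
    if (length(rec_pairs)) {
      pairwise <- pairwise_donor_matrix(rec_pairs, usable_donors, similarity,
                                        direction)
    }
  }

  structure(list(
    trajectories = trajectories,
    dsi = dsi,
    S0 = vapply(trajectories, `[[`, numeric(1), "S0"),
    patterns = vapply(trajectories, function(t) unclass(t$pattern), ""),
    endpoint = endpoint_evaluation(trajectories, endpoint_threshold,
                                   endpoint_timepoint),
    pairwise = pairwise,
    qc_reports = reports,
    cnbp_samples = names(cnbp)[cnbp],
    direction = direction,
    config = list(qc = qc, similarity = similarity,
                  rise_threshold = rise_threshold,
                  endpoint_threshold = endpoint_threshold,
                  endpoint_timepoint = endpoint_timepoint),
    n_samples = length(samples)
  ), class = "engraftment")
}

#' @export
print.engraftment <- function(x, ...) {
  cat(sprintf(
    "Engraftment analysis: %d samples, %d recipients (k = %d, t = %d)\n",
    x$n_samples, nrow(x$dsi), x$config$similarity$k, x$config$similarity$t))
  if (length(x$cnbp_samples)) {
    cat("  CNBP samples:", paste(x$cnbp_samples, collapse = ", "), "\n")
  }
  cat("\nDSI (%) by post-transplant timepoint (NA = CNBP):\n")
  print(round(x$dsi, 1))
  invisible(x)
}

#' Extract the DSI matrix from an engraftment fit
#' @param object an [engraft()] fit.
#' @param ... unused.
#' @return numeric matrix, recipients x post-transplant timepoints; `NA`
#'   marks CNBP entries.
#' @method coef engraftment
#' @export
coef.engraftment <- function(object, ...) object$dsi

#' @method summary engraftment
#' @export
summary.engraftment <- function(object, ...) {
  qc <- do.call(rbind, lapply(object$qc_reports, qc_report_row))
  rownames(qc) <- NULL
  structure(list(fit = object, qc_table = qc), class = "summary.engraftment")
}

#' @export
print.summary.engraftment <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nBaseline similarity S0 (%%): %s\n",
              paste(sprintf("%s=%.1f", names(f$S0), f$S0), collapse = ", ")))
  cat("\nTrajectory patterns:\n")
  for (r in names(f$patterns)) cat(sprintf("  %-4s %s\n", r, f$patterns[r]))
  ep <- f$endpoint
  cat(sprintf("\nEndpoint (DSI > %g%% at %s): %d of %d evaluable recipients\n",
              ep$threshold, ep$timepoint, ep$n_passing, ep$n_evaluable))
  if (!is.null(f$pairwise)) {
    ok <- f$pairwise$specific
    cat(sprintf("Donor specificity at WK1: %d / %d recipients specific\n",
                sum(ok, na.rm = TRUE), sum(!is.na(ok))))
  }
  cat("\nQC summary:\n")
  print(x$qc_table)
  invisible(x)
}

#' Plot DSI trajectories of an engraftment fit
#'
#' One line per recipient over the post-transplant timepoints; CNBP entries
#' are left as gaps. A dashed horizontal line marks the endpoint threshold.
#'
#' @param x an [engraft()] fit.
#' @param ... passed to [graphics::matplot()].
#' @return the fit, invisibly.
#' @method plot engraftment
#' @export
plot.engraftment <- function(x, ...) {
  m <- t(x$dsi)
  graphics::matplot(seq_len(nrow(m)), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "timepoint", ylab = "DSI (%)",
                    main = "Donor Similarity Index trajectories", ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m))
  graphics::abline(h = x$config$endpoint_threshold, lty = 2,
                   col = "grey40")
  graphics::legend("topright", legend = colnames(m), bty = "n",
                   col = seq_len(ncol(m)), lty = 1, pch = 19, cex = 0.8)
  invisible(x)
}
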