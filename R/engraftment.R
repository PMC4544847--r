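# Donor Similarity Index and trajectory analysis.

#' Donor Similarity Index
#'
#' `DSI = 100 * (St - S0) / (100 - S0)`: the percent change in recipient-to-
#' donor similarity relative to baseline, i.e. the fraction of the headroom
#' between the pre-transplant baseline similarity `S0` and perfect donor
#' similarity (100) that has been closed at time t. It is 0 when `St = S0`,
#' 100 when `St = 100` (perfect engraftment), and negative when similarity
#' falls below baseline; values are deliberately not clamped.
#'
#' @param s0 baseline (pre-transplant) recipient-to-donor similarity percent,
#'   in \[0, 100).
#' @param st post-transplant similarity percent at time t, in \[0, 100\].
#' @return signed DSI percent (vectorized over `s0`/`st`; `NA` propagates).
#' @examples
#' compute_dsi(25, 25)   # 0: no change from baseline
#' compute_dsi(40, 100)  # 100: perfect engraftment
#' compute_dsi(50, 60)   # 20: a fifth of the headroom closed
#' @export
compute_dsi <- function(s0, st) {
  ok <- !is.na(s0) & !is.na(st)
  if (any(ok & (s0 < 0 | s0 > 100 | st < 0 | st > 100))) {
    stopf("similarities must be percentages in [0, 100]")
  }
  if (any(ok & s0 == 100)) {
    stopf("degenerate baseline: S0 = 100 leaves no headroom (division by zero)")
  }
  100 * (st - s0) / (100 - s0)
}

#' Classify a DSI trajectory into the two observed engraftment patterns
#'
#' Formalizes the two patterns seen in recipients: a moderate 1-week rise in
#' DSI followed by decline, versus a low 1-week DSI followed by a gradual
#' rise. The rule: with `w = DSI(WK1)` and `last` the latest non-CNBP DSI
#' after week 1, the trajectory is `moderate_rise_then_decline` when
#' `w >= rise_threshold` and `last < w`; `low_then_gradual_rise` when
#' `w < rise_threshold` and `last > w`; otherwise `indeterminate`. Fewer
#' than two usable post-transplant values (e.g. late timepoints all CNBP)
#' yield `indeterminate` with the reason attached. The rule is a documented
#' formalization of a narrative description, not a published algorithm, so
#' the threshold (default 40) is an explicit parameter.
#'
#' @param x a [dsi_trajectory()] object, or a numeric vector of
#'   post-transplant DSI values (named with timepoint labels, or length 3
#'   taken as `WK1`, `MO1`, `MO2_3`); `NA` marks CNBP timepoints.
#' @param rise_threshold DSI percent separating "moderate" from "low"
#'   1-week rises.
#' @return character scalar (`moderate_rise_then_decline`,
#'   `low_then_gradual_rise` or `indeterminate`) with a `reason` attribute.
#' @export
classify_pattern <- function(x, rise_threshold = 40) {
  dsi <- if (inherits(x, "dsi_trajectory")) {
    setNames(x$table$dsi, x$table$timepoint)
  } else {
    x
  }
  if (is.null(names(dsi))) {
    if (length(dsi) != 3) {
      stopf("unnamed DSI vectors must have length 3 (WK1, MO1, MO2_3)")
    }
    names(dsi) <- POST_TIMEPOINTS
  }
  if (!"WK1" %in% names(dsi)) stopf("trajectory has no WK1 timepoint")
  w <- dsi[["WK1"]]
  later <- dsi[names(dsi) != "WK1"]
  later <- later[!is.na(later)]
  out <- function(lab, why) structure(lab, reason = why)
  if (is.na(w)) {
    return(out("indeterminate", "week-1 DSI is CNBP"))
  }
  if (!length(later)) {
    return(out("indeterminate",
               "fewer than 2 usable post-transplant DSI values"))
  }
  last <- later[[length(later)]]
  if (w >= rise_threshold && last < w) {
    out("moderate_rise_then_decline",
        sprintf("DSI(WK1) = %.1f >= %g and latest DSI %.1f declined",
                w, rise_threshold, last))
  } else if (w < rise_threshold && last > w) {
    out("low_then_gradual_rise",
        sprintf("DSI(WK1) = %.1f < %g and latest DSI %.1f rose",
                w, rise_threshold, last))
  } else {
    out("indeterminate", "trajectory fits neither pattern")
  }
}

sim_pct <- function(res, direction) {
  switch(direction,
         recipient_to_donor = res$pct_query_in_target,
         symmetric = res$symmetric_pct,
         stopf("unknown dsi direction '%s'", direction))
}

#' DSI trajectory of one recipient against their donor
#'
#' Computes the baseline recipient-to-donor similarity `S0` once from the
#' recipient's `BL2` sample (the baseline obtained immediately prior to
#' transplant) against the donor's `BL2` sample, then the post-transplant
#' similarity `St` and DSI for each available follow-up timepoint.
#' Timepoints whose samples failed QC are carried as CNBP (missing, never
#' zero). Alongside the donor-direction similarities, each post-transplant
#' sample's similarity to the recipient's own baseline is emitted, and when
#' a `BL1` sample is available the `BL1`-vs-`BL2` similarity is reported as
#' a baseline-drift control.
#'
#' @param recipient_samples named list of [sample_library()] objects keyed
#'   by timepoint label; must contain `BL2`.
#' @param donor_bl2_sample the donor's `BL2` [sample_library()].
#' @param config a [similarity_config()].
#' @param direction `"recipient_to_donor"` (percent of recipient reads
#'   shared with the donor; the default, matching the plotted
#'   recipient-to-donor-baseline similarity) or `"symmetric"`.
#' @param cnbp character vector of timepoint labels flagged CNBP by QC.
#' @return an object of class `dsi_trajectory`: `S0`, a per-timepoint table
#'   (`timepoint`, `St`, `dsi`, `cnbp`, `sim_own_baseline`), the classified
#'   `pattern`, and `baseline_drift`.
#' @export
dsi_trajectory <- function(recipient_samples, donor_bl2_sample,
                           config = similarity_config(),
                           direction = c("recipient_to_donor", "symmetric"),
                           cnbp = character(0)) {
  direction <- match.arg(direction)
  if (!"BL2" %in% names(recipient_samples)) {
    stopf("recipient has no BL2 baseline sample")
  }
  rec_id <- recipient_samples$BL2$subject_id
  donor_id <- donor_bl2_sample$subject_id
  post <- intersect(POST_TIMEPOINTS, names(recipient_samples))
  all_cnbp <- "BL2" %in% cnbp
  tab <- data.frame(timepoint = post, St = NA_real_, dsi = NA_real_,
                    cnbp = TRUE, sim_own_baseline = NA_real_,
                    stringsAsFactors = FALSE)
  s0 <- NA_real_
  drift <- NA_real_
  if (!all_cnbp) {
    donor_index <- kmer_index(donor_bl2_sample, config)
    bl2_index <- kmer_index(recipient_samples$BL2, config)
    s0 <- sim_pct(similarity(recipient_samples$BL2, donor_bl2_sample, config,
                             target_index = donor_index), direction)
    if ("BL1" %in% names(recipient_samples) && !"BL1" %in% cnbp) {
      drift <- sim_pct(similarity(recipient_samples$BL1,
                                  recipient_samples$BL2, config,
                                  target_index = bl2_index), direction)
    }
    for (i in seq_along(post)) {
      tp <- post[i]
      if (tp %in% cnbp) next
      lib <- recipient_samples[[tp]]
      st <- sim_pct(similarity(lib, donor_bl2_sample, config,
                               target_index = donor_index), direction)
      tab$St[i] <- st
      tab$dsi[i] <- compute_dsi(s0, st)
      tab$cnbp[i] <- FALSE
      tab$sim_own_baseline[i] <-
        sim_pct(similarity(lib, recipient_samples$BL2, config,
                           target_index = bl2_index), direction)
    }
  }
  traj <- structure(list(recipient_id = rec_id, donor_id = donor_id,
                         S0 = s0, table = tab, baseline_drift = drift,
                         direction = direction),
                    class = "dsi_trajectory")
  traj$pattern <- classify_pattern(traj)
  traj
}

#' @export
print.dsi_trajectory <- function(x, ...) {
  cat(sprintf("DSI trajectory: recipient %s vs donor %s (S0 = %s)\n",
              x$recipient_id, x$donor_id,
              if (is.na(x$S0)) "CNBP" else sprintf("%.2f%%", x$S0)))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-6s %s\n", tab$timepoint[i],
                if (tab$cnbp[i]) "CNBP"
                else sprintf("St = %6.2f%%  DSI = %6.1f", tab$St[i],
                             tab$dsi[i])))
  }
  cat("  pattern:", unclass(x$pattern), "\n")
  invisible(x)
}

#' Recipient-versus-all-donors similarity matrices
#'
#' For each recipient, the `BL2` (pre-transplant) and `WK1` (1 week
#' post-transplant) samples are compared to every donor's `BL2` sample.
#' A recipient is donor-specific when the 1-week increase in similarity
#' toward their own donor (WK1 minus BL2) is strictly greater than the
#' increase toward every other donor.
#'
#' @param recipients named list (by recipient subject) of lists with
#'   elements `BL2` and `WK1`, each a [sample_library()].
#' @param donors named list (by donor sample label) of donor `BL2`
#'   [sample_library()] objects; two labels may share one donor subject
#'   (stool collected at different times), in which case both columns count
#'   as "own" for that donor's recipients.
#' @param config a [similarity_config()].
#' @param direction see [dsi_trajectory()].
#' @return an object of class `pairwise_donor_matrix`: `bl2` and `wk1`
#'   percent matrices (recipients x donors), the `increase` matrix, a
#'   logical `own` matrix, and a per-recipient `specific` flag (`NA` when
#'   fewer than 2 donors or the recipient lacks a usable pair of samples).
#' @export
pairwise_donor_matrix <- function(recipients, donors,
                                  config = similarity_config(),
                                  direction = c("recipient_to_donor",
                                                "symmetric")) {
  direction <- match.arg(direction)
  rn <- names(recipients)
  dn <- names(donors)
  indexes <- lapply(donors, kmer_index, config = config)
  bl2 <- wk1 <- matrix(NA_real_, length(rn), length(dn),
                       dimnames = list(rn, dn))
  own <- matrix(FALSE, length(rn), length(dn), dimnames = list(rn, dn))
  for (r in rn) {
    pair <- recipients[[r]]
    for (d in dn) {
      own[r, d] <- identical(pair$BL2$donor_id, donors[[d]]$subject_id)
      if (!is.null(pair$BL2)) {
        bl2[r, d] <- sim_pct(similarity(pair$BL2, donors[[d]], config,
                                        target_index = indexes[[d]]),
                             direction)
      }
      if (!is.null(pair$WK1)) {
        wk1[r, d] <- sim_pct(similarity(pair$WK1, donors[[d]], config,
                                        target_index = indexes[[d]]),
                             direction)
      }
    }
  }
  increase <- wk1 - bl2
  specific <- setNames(rep(NA, length(rn)), rn)
  if (length(dn) >= 2) {
    for (r in rn) {
      inc <- increase[r, ]
      if (any(own[r, ]) && !anyNA(inc)) {
        specific[r] <- min(inc[own[r, ]]) > max(inc[!own[r, ]])
      }
    }
  }
  structure(list(bl2 = bl2, wk1 = wk1, increase = increase, own = own,
                 specific = specific),
            class = "pairwise_donor_matrix")
}

#' @export
print.pairwise_donor_matrix <- function(x, ...) {
  cat("Recipient-vs-all-donors similarity (percent)\n")
  cat("1-week increase over baseline:\n")
  print(round(x$increase, 2))
  cat("donor-specific:",
      paste(sprintf("%s=%s", names(x$specific), x$specific),
            collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the engraftment endpoint at a named timepoint
#'
#' The primary-endpoint rule: engraftment at a follow-up timepoint is a DSI
#' strictly greater than `threshold` (default 50 percent at 1 month). CNBP
#' timepoints are not evaluable and never counted as failures.
#'
#' @param x a list of [dsi_trajectory()] objects, or a data.frame with a
#'   `recipient` column plus one numeric column per timepoint (`NA` = CNBP).
#' @param threshold DSI percent the timepoint value must exceed.
#' @param timepoint timepoint label to evaluate (one of
#'   `timepoint_labels(post_only = TRUE)`).
#' @return list with `per_recipient` (named logical; `NA` = not evaluable),
#'   `n_evaluable`, `n_passing`, and the rule parameters.
#' @export
endpoint_evaluation <- function(x, threshold = 50, timepoint = "MO1") {
  if (!timepoint %in% POST_TIMEPOINTS) {
    stopf("unknown post-transplant timepoint '%s'", timepoint)
  }
  vals <- if (is.data.frame(x)) {
    if (!timepoint %in% names(x)) {
      stopf("data frame has no '%s' column", timepoint)
    }
    setNames(x[[timepoint]], x$recipient)
  } else {
    vapply(x, function(tr) {
      i <- match(timepoint, tr$table$timepoint)
      if (is.na(i)) NA_real_ else tr$table$dsi[i]
    }, numeric(1), USE.NAMES = FALSE) |>
      setNames(vapply(x, `[[`, "", "recipient_id"))
  }
  res <- ifelse(is.na(vals), NA, vals > threshold)
  list(per_recipient = res, n_evaluable = sum(!is.na(res)),
       n_passing = sum(res, na.rm = TRUE), threshold = threshold,
       timepoint = timepoint)
}

#' Published reference engraftment-score trajectories
#'
#' Engraftment scores (DSI percent at 1 week, 1 month and 2-3 months) for
#' the six analyzable recipients of a published single-administration FMT
#' cohort in ulcerative colitis, as printed in that study's outcome table.
#' `NA` marks timepoints where the similarity analysis could not be
#' performed (CNBP). Used as worked inputs for the pattern classifier and
#' endpoint rule.
#'
#' @return data.frame with columns `recipient`, `WK1`, `MO1`, `MO2_3`.
#' @export
reference_engraftment_scores <- function() {
  path <- system.file("extdata", "reference_engraftment_scores.tsv",
                      package = "fmtdsi", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character"))
  for (tp in POST_TIMEPOINTS) {
    tab[[tp]] <- suppressWarnings(
      as.numeric(ifelse(tab[[tp]] == "CNBP", NA, tab[[tp]])))
  }
  tab
}
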