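# End-to-end orchestration: configuration validation, file-based runs with
# deterministic TSV/JSON outputs, and the bundled demo cohort.

#' Assemble and validate a pipeline run configuration
#'
#' `run_config()` collects paths and analysis parameters; cross-field
#' constraints are checked by `validate_run_config()`, which either stops
#' with every problem listed or (with `stop_on_error = FALSE`) returns the
#' character vector of problems.
#'
#' The metadata TSV must have columns `sample_id`, `subject_id`, `role`
#' (`donor`/`recipient`), `donor_id` and `timepoint`, optionally
#' `read_length`; each sample's reads are read from
#' `<reads_dir>/<sample_id>.fastq`.
#'
#' @param reads_dir directory of per-sample FASTQ files.
#' @param metadata path to the metadata TSV, or an equivalent data.frame.
#' @param out_dir output directory (created if missing).
#' @param host_fasta optional host reference FASTA for the host screen.
#' @param marker_fasta optional marker database FASTA; enables the
#'   taxonomic analyses.
#' @param marker_kmer_length profiling k-mer length for `marker_fasta`.
#' @param qc,similarity,taxonomy module configurations.
#' @param direction,rise_threshold,endpoint_threshold,endpoint_timepoint
#'   see [engraft()].
#' @param seed master seed recorded in the run provenance.
#' @return an object of class `run_config`.
#' @export
run_config <- function(reads_dir, metadata, out_dir,
                       host_fasta = NULL, marker_fasta = NULL,
                       marker_kmer_length = 24,
                       qc = qc_config(), similarity = similarity_config(),
                       taxonomy = taxonomy_config(),
                       direction = "recipient_to_donor",
                       rise_threshold = 40, endpoint_threshold = 50,
                       endpoint_timepoint = "MO1", seed = 1L) {
  structure(list(reads_dir = reads_dir, metadata = metadata,
                 out_dir = out_dir, host_fasta = host_fasta,
                 marker_fasta = marker_fasta,
                 marker_kmer_length = marker_kmer_length, qc = qc,
                 similarity = similarity, taxonomy = taxonomy,
                 direction = direction, rise_threshold = rise_threshold,
                 endpoint_threshold = endpoint_threshold,
                 endpoint_timepoint = endpoint_timepoint,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_metadata <- function(metadata) {
  if (is.character(metadata)) {
    read.delim(metadata, stringsAsFactors = FALSE)
  } else {
    as.data.frame(metadata, stringsAsFactors = FALSE)
  }
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param stop_on_error stop with an aggregated message (default) or return
#'   the problems.
#' @export
validate_run_config <- function(config, stop_on_error = TRUE) {
  stopifnot(inherits(config, "run_config"))
  errs <- character(0)
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))
  if (!dir.exists(config$reads_dir)) {
    note("reads_dir does not exist: %s", config$reads_dir)
  }
  for (f in c("host_fasta", "marker_fasta")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      note("%s does not exist: %s", f, config[[f]])
    }
  }
  meta <- tryCatch(read_metadata(config$metadata), error = function(e) {
    note("cannot read metadata: %s", conditionMessage(e))
    NULL
  })
  if (!is.null(meta)) {
    need <- c("sample_id", "subject_id", "role", "donor_id", "timepoint")
    missing_cols <- setdiff(need, names(meta))
    if (length(missing_cols)) {
      note("metadata lacks columns: %s", paste(missing_cols, collapse = ", "))
    } else {
      bad_tp <- setdiff(unique(meta$timepoint), TIMEPOINT_LEVELS)
      if (length(bad_tp)) {
        note("unrecognized timepoint labels: %s (expected %s)",
             paste(bad_tp, collapse = ", "),
             paste(TIMEPOINT_LEVELS, collapse = ", "))
      }
      if (anyDuplicated(meta$sample_id)) note("duplicate sample ids")
      donors <- meta$subject_id[meta$role == "donor" &
                                  meta$timepoint == "BL2"]
      for (r in unique(meta$subject_id[meta$role == "recipient"])) {
        rows <- meta[meta$subject_id == r & meta$role == "recipient", ]
        if (!"BL2" %in% rows$timepoint) {
          note("recipient %s has no BL2 baseline sample", r)
        }
        did <- unique(rows$donor_id)
        did <- did[!is.na(did)]
        if (!length(did)) {
          note("recipient %s has no donor_id", r)
        } else if (!any(did %in% donors)) {
          note("recipient %s paired with donor %s, who has no BL2 sample",
               r, paste(did, collapse = "/"))
        }
      }
      if (dir.exists(config$reads_dir)) {
        fq <- file.path(config$reads_dir, paste0(meta$sample_id, ".fastq"))
        gone <- meta$sample_id[!file.exists(fq)]
        if (length(gone)) {
          note("missing FASTQ for sample(s): %s", paste(gone, collapse = ", "))
        }
      }
      if ("read_length" %in% names(meta) &&
          any(meta$read_length < config$similarity$k)) {
        note("similarity k = %d exceeds the declared read length (%d)",
             config$similarity$k, min(meta$read_length))
      }
    }
  }
  if (length(errs) && stop_on_error) {
    stopf("invalid run configuration:\n%s",
          paste("  -", errs, collapse = "\n"))
  }
  if (stop_on_error) invisible(config) else errs
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full engraftment pipeline from files on disk
#'
#' Reads the cohort's FASTQ files and metadata, applies QC, computes DSI
#' trajectories, patterns, endpoint and (when two or more donors are
#' present) the donor-specificity matrix, and — when a marker database is
#' configured — species abundance profiles, Shannon diversity, transplanted
#' species calls, large-change flags and the paired donor-versus-recipient
#' species test. All tables are written as TSV under `out_dir`, plus a
#' `run_summary.json` provenance block (configuration hash, seed, package
#' version). Outputs are deterministic for fixed inputs and seed; a CNBP
#' sample never aborts the cohort.
#'
#' @param config a validated [run_config()].
#' @return an object of class `run_report`: the [engraft()] fit, the
#'   taxonomy tables (or `NULL`), and the paths written.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  meta <- read_metadata(config$metadata)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  samples <- lapply(seq_len(nrow(meta)), function(i) {
    read_sample_fastq(
      file.path(config$reads_dir, paste0(meta$sample_id[i], ".fastq")),
      sample_id = meta$sample_id[i], subject_id = meta$subject_id[i],
      role = meta$role[i], timepoint = meta$timepoint[i],
      donor_id = meta$donor_id[i])
  })
  names(samples) <- meta$sample_id

  fit <- engraft(samples, host_reference = config$host_fasta,
                 qc = config$qc, similarity = config$similarity,
                 direction = config$direction,
                 rise_threshold = config$rise_threshold,
                 endpoint_threshold = config$endpoint_threshold,
                 endpoint_timepoint = config$endpoint_timepoint)

  paths <- c(qc = file.path(config$out_dir, "qc_report.tsv"),
             dsi = file.path(config$out_dir, "dsi_trajectories.tsv"),
             endpoint = file.path(config$out_dir, "endpoint.tsv"))
  qc_tab <- do.call(rbind, lapply(fit$qc_reports, qc_report_row))
  rownames(qc_tab) <- NULL
  write_tsv(qc_tab, paths[["qc"]])
  write_tsv(trajectory_table(fit), paths[["dsi"]])
  ep <- fit$endpoint
  write_tsv(data.frame(recipient = names(ep$per_recipient),
                       passing = ifelse(is.na(ep$per_recipient), "CNBP",
                                        ep$per_recipient),
                       threshold = ep$threshold, timepoint = ep$timepoint,
                       stringsAsFactors = FALSE),
            paths[["endpoint"]])
  if (!is.null(fit$pairwise)) {
    paths[["pairwise"]] <- file.path(config$out_dir, "pairwise_donors.tsv")
    pw <- as.data.frame(fit$pairwise$increase)
    pw <- cbind(recipient = rownames(pw), pw,
                specific = fit$pairwise$specific)
    write_tsv(pw, paths[["pairwise"]])
  }

  taxonomy <- NULL
  if (!is.null(config$marker_fasta)) {
    db <- read_marker_fasta(config$marker_fasta, config$marker_kmer_length)
    profiles <- lapply(samples[meta$sample_id], function(s) {
      qc_lib <- apply_qc(s, config$host_fasta, config$qc)$library
      profile_abundance(qc_lib, db)
    })
    taxonomy <- taxonomy_tables(profiles, meta, fit, db, config$taxonomy)
    for (nm in names(taxonomy$tables)) {
      paths[[nm]] <- file.path(config$out_dir, paste0(nm, ".tsv"))
      write_tsv(taxonomy$tables[[nm]], paths[[nm]])
    }
  }

  summary_path <- file.path(config$out_dir, "run_summary.json")
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  jsonlite::write_json(list(
    config_hash = fnv1a_hash(deparse(unclass(cfg_for_hash))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fmtdsi")),
    n_samples = length(samples),
    cnbp_samples = fit$cnbp_samples,
    endpoint = list(threshold = ep$threshold, timepoint = ep$timepoint,
                    n_evaluable = ep$n_evaluable, n_passing = ep$n_passing)
  ), summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["summary"]] <- summary_path

  structure(list(fit = fit, taxonomy = taxonomy, paths = paths,
                 out_dir = config$out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run complete; outputs in", x$out_dir, "\n")
  print(x$fit)
  invisible(x)
}

# The outcome-table analogue: one row per recipient, DSI per timepoint with
# explicit CNBP markers, plus S0 and the classified pattern.
trajectory_table <- function(fit) {
  rows <- lapply(fit$trajectories, function(tr) {
    vals <- setNames(rep("CNBP", length(POST_TIMEPOINTS)), POST_TIMEPOINTS)
    tab <- tr$table
    for (i in seq_len(nrow(tab))) {
      if (!tab$cnbp[i]) {
        vals[tab$timepoint[i]] <- sprintf("%.1f", tab$dsi[i])
      }
    }
    cbind(data.frame(recipient = tr$recipient_id, donor = tr$donor_id,
                     S0 = ifelse(is.na(tr$S0), "CNBP",
                                 sprintf("%.2f", tr$S0)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), stringsAsFactors = FALSE),
          data.frame(pattern = unclass(tr$pattern),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Assemble the taxonomy output tables for a profiled cohort.
taxonomy_tables <- function(profiles, meta, fit, db, tax_config) {
  abundance <- do.call(rbind, lapply(profiles, function(p) p$abundance))
  rownames(abundance) <- vapply(profiles, `[[`, "", "sample_id")
  ab_tab <- cbind(data.frame(sample_id = rownames(abundance),
                             stringsAsFactors = FALSE),
                  as.data.frame(abundance))
  diversity <- data.frame(
    sample_id = rownames(abundance),
    n_assigned = vapply(profiles, `[[`, numeric(1), "n_assigned"),
    shannon = vapply(profiles, function(p) {
      if (p$evaluable) shannon_index(p) else NA_real_
    }, numeric(1)), stringsAsFactors = FALSE)

  calls <- list()
  for (r in unique(meta$subject_id[meta$role == "recipient"])) {
    rows <- meta[meta$subject_id == r & meta$role == "recipient", ]
    profs <- setNames(profiles[rows$sample_id], rows$timepoint)
    did <- rows$donor_id[!is.na(rows$donor_id)][1]
    dsid <- meta$sample_id[meta$subject_id == did & meta$timepoint == "BL2"]
    if (!all(c("BL1", "BL2") %in% names(profs)) || !length(dsid)) next
    tc <- detect_transplanted_species(profs, profiles[[dsid[1]]], tax_config)
    tc <- tc[tc$qualifies, , drop = FALSE]
    if (nrow(tc)) calls[[r]] <- cbind(recipient = r, tc)
  }
  transplant <- if (length(calls)) do.call(rbind, calls) else
    data.frame(recipient = character(0), species = character(0))
  rownames(transplant) <- NULL

  donors <- recs <- list()
  for (r in unique(meta$subject_id[meta$role == "recipient"])) {
    rid <- meta$sample_id[meta$subject_id == r & meta$timepoint == "BL2" &
                            meta$role == "recipient"]
    did <- unique(meta$donor_id[meta$subject_id == r &
                                  !is.na(meta$donor_id)])[1]
    dsid <- meta$sample_id[meta$subject_id == did & meta$timepoint == "BL2"]
    if (length(rid) && length(dsid)) {
      recs[[r]] <- profiles[[rid[1]]]
      donors[[r]] <- profiles[[dsid[1]]]
    }
  }
  sp_test <- donor_recipient_species_test(donors, recs, tax_config)

  list(profiles = profiles,
       tables = list(abundance = ab_tab, diversity = diversity,
                     transplanted_species = transplant,
                     species_test = as.data.frame(sp_test)))
}

#' Write a self-contained synthetic demo cohort to disk
#'
#' Simulates a small cohort ([simulate_cohort()]) and writes everything a
#' file-based pipeline run needs: per-sample FASTQ, `metadata.tsv`,
#' `host.fasta`, `markers.fasta` and a `truth.json` ground-truth sidecar
#' (true mixing fractions, per-sample injected host/duplicate/bad-read
#' ids). Sized for a full pipeline run in well under 15 minutes on one CPU.
#'
#' @param seed master seed.
#' @param out_dir directory to create the bundle in.
#' @param n_pairs,n_reads cohort size (passed to [simulate_cohort()]).
#' @param ... further arguments to [simulate_cohort()].
#' @return a ready-to-run [run_config()] for the bundle, invisibly.
#' @export
make_demo <- function(seed = 1L, out_dir, n_pairs = 3, n_reads = 5000, ...) {
  cohort <- simulate_cohort(n_pairs = n_pairs, n_reads = n_reads,
                            seed = seed, ...)
  reads_dir <- file.path(out_dir, "fastq")
  dir.create(reads_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$samples) {
    write_sample_fastq(s, file.path(reads_dir, paste0(s$sample_id, ".fastq")))
  }
  write_tsv(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  host_path <- file.path(out_dir, "host.fasta")
  host <- Biostrings::DNAStringSet(cohort$host_reference)
  names(host) <- "host_synthetic"
  Biostrings::writeXStringSet(host, host_path)
  marker_path <- file.path(out_dir, "markers.fasta")
  write_marker_fasta(cohort$marker_db, marker_path)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run_config(
    reads_dir = reads_dir, metadata = file.path(out_dir, "metadata.tsv"),
    out_dir = file.path(out_dir, "results"), host_fasta = host_path,
    marker_fasta = marker_path,
    marker_kmer_length = cohort$marker_db$kmer_length,
    qc = qc_config(min_reads_after_filtering = max(100, n_reads / 10)),
    seed = seed))
}
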