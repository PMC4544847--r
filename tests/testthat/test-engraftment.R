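test_that("the DSI formula satisfies its identities and errors", {
  expect_equal(compute_dsi(25, 25), 0)
  expect_equal(compute_dsi(40, 100), 100)
  expect_equal(compute_dsi(50, 60), 20)
  expect_lt(compute_dsi(30, 20), 0)
  # round-trip: St = S0 + DSI * (100 - S0) / 100
  for (s0 in c(0, 12.5, 60, 99)) {
    for (st in c(0, 30, 99.5, 100)) {
      dsi <- compute_dsi(s0, st)
      expect_equal(s0 + dsi * (100 - s0) / 100, st)
    }
  }
  # strictly increasing in St for fixed S0
  expect_true(all(diff(compute_dsi(37, seq(0, 100, 5))) > 0))
  expect_error(compute_dsi(100, 50), "degenerate baseline")
  expect_error(compute_dsi(101, 50), "\\[0, 100\\]")
  expect_error(compute_dsi(50, -2), "\\[0, 100\\]")
  expect_true(is.na(compute_dsi(NA, 50)))
})

test_that("pattern classification reproduces the reference grouping", {
  ref <- reference_engraftment_scores()
  got <- vapply(seq_len(nrow(ref)), function(i) {
    unclass(classify_pattern(c(WK1 = ref$WK1[i], MO1 = ref$MO1[i],
                               MO2_3 = ref$MO2_3[i])))
  }, character(1))
  names(got) <- ref$recipient
  expect_equal(unname(got[c("R3", "R5", "R6")]),
               rep("moderate_rise_then_decline", 3))
  expect_equal(unname(got[c("R1", "R7")]),
               rep("low_then_gradual_rise", 2))
  expect_equal(unname(got["R2"]), "indeterminate")
})

test_that("pattern classification handles degenerate trajectories", {
  expect_equal(as.character(classify_pattern(c(WK1 = NA, MO1 = 20, MO2_3 = 30))),
               "indeterminate")
  one_point <- classify_pattern(c(WK1 = 10, MO1 = NA, MO2_3 = NA))
  expect_equal(as.character(one_point), "indeterminate")
  expect_match(attr(one_point, "reason"), "fewer than 2")
  # a flat high trajectory fits neither pattern
  expect_equal(as.character(classify_pattern(c(WK1 = 50, MO1 = 50, MO2_3 = 50))),
               "indeterminate")
  expect_error(classify_pattern(c(1, 2)), "length 3")
})

test_that("the endpoint rule counts reference recipients correctly", {
  ref <- reference_engraftment_scores()
  at50 <- endpoint_evaluation(ref, threshold = 50, timepoint = "MO1")
  expect_equal(at50$n_evaluable, 4)  # R1, R2 are CNBP at 1 month
  expect_equal(at50$n_passing, 0)
  at40 <- endpoint_evaluation(ref, threshold = 40, timepoint = "MO1")
  expect_equal(at40$n_passing, 2)    # 47.9 and 41.1
  expect_equal(names(which(at40$per_recipient)), c("R3", "R5"))
  expect_error(endpoint_evaluation(ref, timepoint = "BL9"), "timepoint")
})

test_that("DSI trajectories track a monotone engraftment schedule", {
  cohort <- simulate_cohort(
    n_pairs = 1, n_species = 8, overlap_fraction = 0,
    engraftment_schedule = c(WK1 = 0.6, MO1 = 0.4, MO2_3 = 0.1),
    n_reads = 4000, error_rate = 0, host_fraction = 0,
    duplicate_fraction = 0, bad_read_fraction = 0,
    markers_per_species = 0, seed = 61)
  fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 100))
  dsi <- coef(fit)["R1", ]
  expect_true(dsi["WK1"] > dsi["MO1"] && dsi["MO1"] > dsi["MO2_3"])
  # disjoint communities: DSI approximately tracks 100 * pi
  expect_equal(unname(dsi), c(60, 40, 10), tolerance = 0.15)
  expect_lt(fit$S0[["R1"]], 5)
})

test_that("CNBP samples propagate as missing without aborting the cohort", {
  cohort <- simulate_cohort(
    n_pairs = 1, n_species = 6, overlap_fraction = 0.5,
    n_reads = 1500, markers_per_species = 0, include_bl1 = FALSE,
    error_rate = 0, host_fraction = 0, duplicate_fraction = 0,
    bad_read_fraction = 0, seed = 67)
  # shrink the 1-month sample below the depth gate
  cohort$samples$R1_MO1$reads <- cohort$samples$R1_MO1$reads[1:50, ]
  fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 500))
  expect_equal(fit$cnbp_samples, "R1_MO1")
  dsi <- coef(fit)["R1", ]
  expect_true(is.na(dsi[["MO1"]]))
  expect_false(anyNA(dsi[c("WK1", "MO2_3")]))
  tr <- fit$trajectories$R1
  expect_true(tr$table$cnbp[tr$table$timepoint == "MO1"])
  # a CNBP recipient baseline blanks the whole trajectory
  cohort$samples$R1_BL2$reads <- cohort$samples$R1_BL2$reads[1:50, ]
  fit2 <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 500))
  expect_true(all(is.na(coef(fit2)["R1", ])))
})

test_that("recipients are more similar to their own donor than to others", {
  cohort <- simulate_cohort(
    n_pairs = 3, n_species = 6, overlap_fraction = 0,
    engraftment_schedule = c(WK1 = 0.5), include_bl1 = FALSE,
    n_reads = 2500, error_rate = 0, host_fraction = 0,
    duplicate_fraction = 0, bad_read_fraction = 0,
    markers_per_species = 0, seed = 71)
  fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 100))
  pw <- fit$pairwise
  expect_false(is.null(pw))
  expect_true(all(pw$specific))
  expect_true(all(pw$bl2 >= 0 & pw$bl2 <= 100))
  # own-donor columns carry the signal
  for (r in rownames(pw$increase)) {
    expect_gt(pw$increase[r, pw$own[r, ]],
              max(pw$increase[r, !pw$own[r, ]]))
  }
})

test_that("a recipient with no engraftment is not donor-specific", {
  cohort <- simulate_cohort(
    n_pairs = 2, n_species = 6, overlap_fraction = 0,
    schedules = list(c(WK1 = 0.5), c(WK1 = 0)), include_bl1 = FALSE,
    n_reads = 2500, error_rate = 0, host_fraction = 0,
    duplicate_fraction = 0, bad_read_fraction = 0,
    markers_per_species = 0, seed = 73)
  fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 100))
  expect_true(fit$pairwise$specific[["R1"]])
  expect_false(isTRUE(fit$pairwise$specific[["R2"]]))
})

test_that("trajectories report own-baseline similarity and drift control", {
  cohort <- simulate_cohort(
    n_pairs = 1, n_species = 6, overlap_fraction = 0.5,
    engraftment_schedule = c(WK1 = 0.6), n_reads = 2000,
    error_rate = 0, host_fraction = 0, duplicate_fraction = 0,
    bad_read_fraction = 0, markers_per_species = 0, seed = 79)
  fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 100))
  tr <- fit$trajectories$R1
  # BL1 and BL2 are draws from the same community: drift control is high
  expect_gt(tr$baseline_drift, 90)
  wk1 <- tr$table[tr$table$timepoint == "WK1", ]
  # the 1-week sample is a mixture: similarity to own baseline drops
  expect_lt(wk1$sim_own_baseline, tr$baseline_drift)
  expect_gt(wk1$St, fit$S0[["R1"]])
})
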