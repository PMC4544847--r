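test_that("profiling recovers single-species and 50/50 compositions", {
  m <- make_community(n_species = 2, overlap_fraction = 1,
                      genome_length = 6000, seed = 83)
  db <- make_marker_db(m, markers_per_species = 5, marker_length = 200,
                       kmer_length = 21)
  one <- generate_reads(m, setNames(c(100, 0), m$species_ids), 2000,
                        sample_id = "ONE")
  p1 <- profile_abundance(one, db)
  expect_equal(unname(p1$abundance[m$species_ids[1]]), 100)
  expect_equal(sum(p1$abundance), 100)

  even <- generate_reads(m, setNames(c(50, 50), m$species_ids), 4000,
                         sample_id = "EVEN")
  p2 <- profile_abundance(even, db)
  # within 4 sd of binomial sampling error at the number of assigned reads
  se <- 100 * sqrt(0.25 / p2$n_assigned)
  expect_lt(abs(p2$abundance[[1]] - 50), 4 * se)
  # permuting read order changes nothing
  shuf <- even
  shuf$reads <- even$reads[rev(seq_len(nrow(even$reads))), ]
  expect_equal(sort(profile_abundance(shuf, db)$abundance),
               sort(p2$abundance))
})

test_that("an unassignable library yields an unevaluable profile", {
  m <- make_community(n_species = 2, overlap_fraction = 1,
                      genome_length = 6000, seed = 89)
  db <- make_marker_db(m, markers_per_species = 2, marker_length = 100,
                       kmer_length = 21)
  noise <- make_lib(random_reads(50, read_len = 60), "NOISE")
  p <- profile_abundance(noise, db)
  expect_false(p$evaluable)
  expect_equal(p$n_assigned, 0)
  expect_error(shannon_index(p), "no assigned reads")
})

test_that("Shannon index matches closed forms", {
  expect_equal(shannon_index(c(a = 100)), 0)
  expect_equal(shannon_index(rep(25, 4)), log(4))
  expect_equal(shannon_index(c(50, 25, 25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon_index(c(50, 25, 25)), 1.0397, tolerance = 1e-4)
  # base conversion and the uniform maximum
  expect_equal(shannon_index(rep(12.5, 8), base = 2), 3)
  expect_lt(shannon_index(c(90, rep(10 / 7, 7))), log(8))
  expect_error(shannon_index(numeric(0)), "empty")
})

test_that("the transplanted-species rule applies its thresholds", {
  donor <- as_profile(c(A = 3, B = 20, C = 77), "D")
  baseline <- as_profile(c(B = 30, C = 70), "BL")
  post_hi <- as_profile(c(A = 0.5, B = 30, C = 69.5), "WK1")
  post_lo <- as_profile(c(A = 0.1, B = 30, C = 69.9), "WK1")
  calls <- detect_transplanted_species(
    list(BL1 = baseline, BL2 = baseline, WK1 = post_hi), donor)
  a <- calls[calls$species == "A", ]
  expect_true(a$qualifies)
  expect_equal(a$call, "transient")
  expect_false(any(calls$qualifies[calls$species != "A"]))

  below <- detect_transplanted_species(
    list(BL1 = baseline, BL2 = baseline, WK1 = post_lo), donor)
  expect_false(below$qualifies[below$species == "A"])

  # detectable in one baseline disqualifies
  seen_once <- detect_transplanted_species(
    list(BL1 = as_profile(c(A = 1, B = 29, C = 70)), BL2 = baseline,
         WK1 = post_hi), donor)
  expect_false(seen_once$qualifies[seen_once$species == "A"])
  expect_error(detect_transplanted_species(list(BL2 = baseline), donor),
               "BL1")
})

test_that("transplanted-species subtypes follow the timing of appearance", {
  donor <- as_profile(c(A = 10, B = 10, C = 10, D = 70), "D")
  bl <- as_profile(c(D = 100), "BL")
  prof <- function(a, b, c) as_profile(c(A = a, B = b, C = c,
                                         D = 100 - a - b - c))
  calls <- detect_transplanted_species(
    list(BL1 = bl, BL2 = bl,
         WK1 = prof(1, 0, 1), MO1 = prof(0, 1, 1), MO2_3 = prof(0, 1, 1)),
    donor)
  expect_equal(calls$call[calls$species == "A"], "transient")
  expect_equal(calls$call[calls$species == "B"], "late")
  expect_equal(calls$call[calls$species == "C"], "persistent")
})

test_that("large-change flags separate absolute and log-scale changes", {
  cfg <- taxonomy_config()
  pre <- c(X = 0.01, Y = 5, Z = 94.99)
  post <- c(X = 1, Y = 80, Z = 19)
  out <- detect_large_changes(pre, post, cfg)
  x <- out[out$species == "X", ]
  expect_equal(x$log_change, 2)
  expect_equal(x$abs_change, 0.99)
  expect_true(x$log_flag)
  expect_false(x$large_abs)
  y <- out[out$species == "Y", ]
  expect_equal(y$abs_change, 75)
  expect_true(y$large_abs)
  expect_true(y$log_flag)  # log10(80/5) = 1.204
  # identical profiles flag nothing
  expect_equal(nrow(detect_large_changes(pre, pre, cfg)), 0)
  # appearance from zero is flagged, not pseudocounted
  app <- detect_large_changes(c(W = 100), c(W = 99, V = 1), cfg)
  v <- app[app$species == "V", ]
  expect_true(v$from_zero)
  expect_true(is.na(v$log_change))
})

test_that("BH correction matches the brute-force oracle", {
  set.seed(97)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("the paired species test flags enriched species and handles edge cases", {
  set.seed(101)
  n_pairs <- 8
  mk_pair <- function(shift) {
    base <- rlnorm(10)
    d <- base
    d[1:2] <- d[1:2] * shift  # species 1 and 2 donor-enriched
    list(d = as_profile(setNames(d, paste0("s", 1:10))),
         r = as_profile(setNames(base, paste0("s", 1:10))))
  }
  pairs <- lapply(1:n_pairs, function(i) mk_pair(6))
  res <- donor_recipient_species_test(lapply(pairs, `[[`, "d"),
                                      lapply(pairs, `[[`, "r"))
  expect_equal(attr(res, "status"), "ok")
  ranked <- res$species[order(res$p)]
  expect_true(all(c("s1", "s2") %in% ranked[1:3]))

  # fewer than 2 pairs: skipped with explicit status
  skipped <- donor_recipient_species_test(list(pairs[[1]]$d),
                                          list(pairs[[1]]$r))
  expect_match(attr(skipped, "status"), "skipped")

  # identical donor/recipient profiles: constant differences, NA p
  same <- as_profile(c(a = 60, b = 40))
  const <- donor_recipient_species_test(list(same, same), list(same, same))
  expect_true(all(const$status == "constant"))
  expect_true(all(is.na(const$p)))
  expect_false(any(const$significant))
})
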