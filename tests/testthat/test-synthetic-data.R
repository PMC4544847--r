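test_that("community abundance vectors are normalized and respect overlap", {
  full <- make_community(n_species = 10, overlap_fraction = 1, seed = 7)
  expect_equal(sum(full$donor_abundance), 100, tolerance = 1e-12)
  expect_equal(sum(full$recipient_abundance), 100, tolerance = 1e-12)
  expect_true(all(full$donor_abundance > 0))
  expect_true(all(full$recipient_abundance > 0))
  expect_false(isTRUE(all.equal(full$donor_abundance,
                                full$recipient_abundance)))

  disjoint <- make_community(n_species = 10, overlap_fraction = 0, seed = 7)
  expect_length(
    intersect(names(which(disjoint$donor_abundance > 0)),
              names(which(disjoint$recipient_abundance > 0))), 0)

  half <- make_community(n_species = 50, overlap_fraction = 0.5, seed = 1)
  shared <- intersect(names(which(half$donor_abundance > 0)),
                      names(which(half$recipient_abundance > 0)))
  expect_length(shared, 25)
})

test_that("community generation is deterministic in the seed", {
  a <- make_community(n_species = 50, overlap_fraction = 0.5, seed = 1)
  b <- make_community(n_species = 50, overlap_fraction = 0.5, seed = 1)
  c <- make_community(n_species = 50, overlap_fraction = 0.5, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$donor_abundance, c$donor_abundance))
})

test_that("invalid community parameters are rejected", {
  expect_error(make_community(n_species = 1), "n_species")
  expect_error(make_community(overlap_fraction = 1.5), "overlap_fraction")
  expect_error(community_model(c("a", "b"), c("ACGT", "ACGT"),
                               c(60, 30), c(50, 50)), "sum to 100")
})

test_that("mixing is a convex combination with exact endpoints", {
  m <- community_model(
    c("a", "b"), random_dna(c(500, 500)),
    donor_abundance = c(100, 0), recipient_abundance = c(0, 100),
    engraftment_schedule = c(WK1 = 0.5, MO1 = 0, MO2_3 = 1))
  expect_equal(unname(mix_communities(m, "MO1")), c(0, 100))
  expect_equal(unname(mix_communities(m, "MO2_3")), c(100, 0))
  expect_equal(unname(mix_communities(m, "WK1")), c(50, 50))
  expect_error(mix_communities(m, "WK9"), "not in the engraftment schedule")

  r <- make_community(n_species = 9, overlap_fraction = 0.4,
                      engraftment_schedule = c(WK1 = 0.37), seed = 3)
  mixed <- mix_communities(r, "WK1")
  expect_equal(mixed, 0.63 * r$recipient_abundance +
                 0.37 * r$donor_abundance)
  expect_equal(sum(mixed), 100, tolerance = 1e-9)
})

test_that("noise-free reads are exact genome substrings", {
  m <- make_community(n_species = 3, overlap_fraction = 1,
                      genome_length = 2000, seed = 11)
  lib <- generate_reads(m, m$donor_abundance, n_reads = 200,
                        read_length = 70, sample_id = "S1")
  hay <- paste(c(m$genomes, oracle_revcomp(m$genomes)), collapse = "|")
  hits <- vapply(lib$reads$sequence, function(s) grepl(s, hay, fixed = TRUE),
                 logical(1))
  expect_true(all(hits))
  expect_true(all(lib$reads$quality == strrep("G", 70)))
})

test_that("generated FASTQ is byte-identical for a fixed seed", {
  m <- make_community(n_species = 4, overlap_fraction = 0.5,
                      genome_length = 1500, error_rate = 0.01,
                      duplicate_fraction = 0.1, host_fraction = 0.1,
                      seed = 5)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_sample_fastq(generate_reads(m, m$donor_abundance, 300,
                                    sample_id = "S1"), f1)
  write_sample_fastq(generate_reads(m, m$donor_abundance, 300,
                                    sample_id = "S1"), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different sample id gives a different stream
  other <- generate_reads(m, m$donor_abundance, 300, sample_id = "S2")
  lib1 <- read_sample_fastq(f1, "S1")
  expect_false(identical(other$reads$sequence, lib1$reads$sequence))
  # round-trip preserves sequences and qualities
  orig <- generate_reads(m, m$donor_abundance, 300, sample_id = "S1")
  expect_equal(lib1$reads$sequence, orig$reads$sequence)
  expect_equal(lib1$reads$quality, orig$reads$quality)
})

test_that("duplicate and host injections match their ground-truth logs", {
  m <- make_community(n_species = 3, overlap_fraction = 1,
                      genome_length = 5000, duplicate_fraction = 0.1,
                      host_fraction = 0.2, seed = 13)
  lib <- generate_reads(m, m$donor_abundance, n_reads = 1000,
                        sample_id = "S1")
  # ~100 duplicate copies appended; library without them is ~1000
  expect_equal(length(lib$truth$duplicate_ids), 100)
  expect_equal(nrow(lib$reads) - length(lib$truth$duplicate_ids), 1000)
  for (id in head(lib$truth$duplicate_ids, 5)) {
    src <- lib$truth$duplicate_of[[id]]
    expect_identical(
      lib$reads$sequence[lib$reads$read_id == id],
      lib$reads$sequence[lib$reads$read_id == src])
  }
  # host fraction within binomial sampling error of 0.2 (4 sd)
  big <- generate_reads(
    make_community(n_species = 3, overlap_fraction = 1,
                   genome_length = 5000, host_fraction = 0.2, seed = 13),
    m$donor_abundance, n_reads = 10000, sample_id = "H1")
  frac <- length(big$truth$host_ids) / nrow(big$reads)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / 10000))
})

test_that("paired-end mode emits mates from opposite fragment ends", {
  m <- make_community(n_species = 2, overlap_fraction = 1,
                      genome_length = 2000, seed = 17)
  lib <- generate_reads(m, m$donor_abundance, n_reads = 100,
                        read_length = 50, sample_id = "P1", paired = TRUE,
                        insert_size = 200)
  expect_true(all(lib$reads$mate %in% c(1L, 2L)))
  expect_equal(sum(lib$reads$mate == 1), sum(lib$reads$mate == 2))
  hay <- paste(c(m$genomes, oracle_revcomp(m$genomes)), collapse = "|")
  expect_true(all(vapply(lib$reads$sequence,
                         function(s) grepl(s, hay, fixed = TRUE),
                         logical(1))))
})

test_that("marker databases are species-unique and deterministic", {
  m <- make_community(n_species = 5, overlap_fraction = 1,
                      genome_length = 3000, seed = 19)
  db1 <- make_marker_db(m, markers_per_species = 3, marker_length = 120,
                        kmer_length = 21)
  db2 <- make_marker_db(m, markers_per_species = 3, marker_length = 120,
                        kmer_length = 21)
  expect_identical(db1, db2)
  expect_equal(nrow(db1$markers), 15)
  # no profiling k-mer shared between species (checked with the oracle)
  per_species <- lapply(split(db1$markers$sequence, db1$markers$species),
                        function(s) unique(unlist(lapply(s, oracle_kmers,
                                                         k = 21))))
  for (i in seq_along(per_species)) {
    for (j in seq_along(per_species)) {
      if (i < j) {
        expect_length(intersect(per_species[[i]], per_species[[j]]), 0)
      }
    }
  }
  expect_error(make_marker_db(m, marker_length = 20, kmer_length = 21),
               "must exceed")
})

test_that("marker FASTA round-trips", {
  m <- make_community(n_species = 3, overlap_fraction = 1,
                      genome_length = 2000, seed = 23)
  db <- make_marker_db(m, markers_per_species = 2, marker_length = 100,
                       kmer_length = 21)
  f <- tempfile(fileext = ".fasta")
  write_marker_fasta(db, f)
  back <- read_marker_fasta(f, kmer_length = 21)
  expect_equal(back$markers$sequence, db$markers$sequence)
  expect_equal(back$markers$species, db$markers$species)
})
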