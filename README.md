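# fmtdsi

Quantifying engraftment of donor microbiota after fecal microbiota
transplantation (FMT) from shotgun metagenomic reads.

After an FMT, the central microbiological question is whether the donor's
community actually took hold in the recipient's gut, and for how long.
`fmtdsi` answers this without any alignment or taxonomic database, by
comparing read sets directly, and complements that with a marker-based
taxonomic view. It is aimed at microbiome researchers analyzing
longitudinal donor/recipient stool metagenomes (FMT trials in ulcerative
colitis, *C. difficile* infection, and similar settings), and at method
developers who need a fully simulated, ground-truthed test bed for
engraftment metrics.

## The method

**Shared-read similarity.** A read of sample *A* is *shared* with sample
*B* if it contains at least *t* k-mers that occur anywhere in *B*'s reads
(defaults *t* = 2, *k* = 30; k-mers are canonicalized so strand never
matters). The similarity of *A* to *B* is the percentage of *A*'s reads
shared with *B*. This is an exact-membership reimplementation of the
classic Compareads-style read-set comparison.

**Donor Similarity Index.** With *S₀* the recipient-to-donor similarity at
the pre-transplant baseline (the BL2 sample, taken immediately before
transplant) and *Sₜ* the similarity at a post-transplant timepoint,

    DSI = 100 · (Sₜ − S₀) / (100 − S₀)

i.e. the percent of the headroom between baseline and perfect donor
similarity that has been closed at time *t*: 0 means no change from
baseline, 100 means perfect engraftment, negative values mean the
recipient drifted away from the donor. Recipient trajectories are
classified into the two empirically observed patterns (a moderate 1-week
rise followed by decline, versus a low 1-week value with a gradual rise),
and an endpoint rule (DSI > 50 % at 1 month by default) is evaluated per
recipient.

Around this core the package provides:

- a QC cascade mirroring standard shotgun practice: host-read k-mer
  screen, exact-duplicate removal, ambiguous-end trimming, prefix-quality
  and length filters, and a sequencing-depth gate that marks samples CNBP
  ("could not be performed", carried as missing — never zero);
- marker-based species profiling with Shannon diversity, the
  transplanted-species rule (undetectable at both baselines, present in
  the donor, ≥ 0.2 % post-transplant), large-change flags (> 5 absolute
  percentage points, ≥ 1 log₁₀), and a paired donor-versus-recipient
  species test with Benjamini–Hochberg FDR correction;
- a synthetic cohort generator with complete ground truth (true mixing
  fraction π per timepoint, injected host/duplicate/low-quality reads),
  so the whole pipeline is testable without external data.

## Worked example

Simulate three donor/recipient pairs whose post-transplant samples are
donor/recipient mixtures with true engraftment fractions π = 0.6 (week 1),
0.4 (1 month) and 0.1 (2–3 months), then estimate engraftment:

```r
library(fmtdsi)

cohort <- simulate_cohort(n_pairs = 3, n_reads = 5000, seed = 1)
fit <- engraft(cohort, qc = qc_config(min_reads_after_filtering = 500))
fit
#> Engraftment analysis: 18 samples, 3 recipients (k = 30, t = 2)
#>
#> DSI (%) by post-transplant timepoint (NA = CNBP):
#>     WK1  MO1 MO2_3
#> R1 53.8 35.5   8.4
#> R2 53.5 37.9  10.9
#> R3 51.0 36.0   7.8
```

The estimated DSI tracks the simulated schedule: it rises toward ~60 % at
week 1 and decays toward ~10 % by 2–3 months (donor and recipient share
part of their community here, so baseline similarity S₀ ≈ 43–57 % and the
week-1 estimate sits slightly below 100·π). All three trajectories are
classified `moderate_rise_then_decline`, no recipient exceeds the DSI > 50
endpoint at 1 month, and every recipient is more similar to their own
donor than to any other donor at week 1:

```r
fit$patterns
#>                           R1                           R2                           R3
#> "moderate_rise_then_decline" "moderate_rise_then_decline" "moderate_rise_then_decline"
summary(fit)   # adds S0, endpoint counts, donor specificity, per-stage QC table
coef(fit)      # the DSI matrix above
plot(fit)      # trajectory plot
```

File-based runs work the same way: `make_demo(seed, out_dir)` writes a
complete FASTQ + metadata + marker-database bundle and `run_pipeline()`
turns it into TSV/JSON result tables (see also the thin CLI wrapper in
`inst/scripts/fmtdsi`).

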