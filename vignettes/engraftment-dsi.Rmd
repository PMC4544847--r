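---
title: "Measuring FMT engraftment with the Donor Similarity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring FMT engraftment with the Donor Similarity Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtdsi)
```

## The problem

After a fecal microbiota transplant (FMT), clinical response is thought to
depend on whether donor microbes *engraft* — take up residence in the
recipient's gut and persist. Taxonomic profiles answer this only
indirectly: two unrelated people share most abundant gut species, so
species lists barely move even when the underlying strains are replaced
wholesale. `fmtdsi` therefore measures engraftment at the read level,
alignment-free, and uses taxonomy only as a complementary view.

## The similarity kernel

The primitive is a shared-read criterion between two read sets. Sample
*A*'s read is **shared** with sample *B* when the read contains at least
*t* distinct k-mers that occur anywhere in *B*'s reads. The similarity of
*A* to *B* is the percentage of *A*'s reads that are shared. Defaults are
*t* = 2 and *k* = 30: a 30-mer is long enough that chance matches between
unrelated gut genomes are vanishingly rare, and requiring two distinct
matching k-mers suppresses single spurious hits. K-mers are
*canonical* — each is identified with its reverse complement — so strand
orientation never affects matching, and windows containing `N` are skipped
entirely.

Two implementation choices matter:

* **Exact membership, not Bloom filters.** The original tool in this
  family used probabilistic filters for scale; at the library sizes this
  package targets, exact hash sets fit easily in memory, and exactness
  buys a strong guarantee: the indexed kernel is *equal*, not
  approximately equal, to a brute-force per-read set intersection. The
  test suite asserts this equality on dozens of random library pairs.
* **Distinct-k-mer counting.** A k-mer occurring twice in a read counts
  once toward *t*. A read of length exactly *k* contributes one k-mer and
  can therefore never reach *t* = 2; this boundary is documented rather
  than treated as an error.

Directionality is a genuine open choice: shared-read similarity is not
symmetric. The package computes both directions plus a symmetric pooled
score, and uses the **recipient-to-donor** direction (percent of recipient
reads shared with the donor sample) for the DSI, because the quantity of
interest is how much of the recipient's community is donor-like. A flag
switches to the symmetric score.

## The Donor Similarity Index

Let $S_0$ be the recipient-to-donor similarity between the recipient's
second baseline (BL2, collected immediately before transplant) and the
donor's BL2 sample, and $S_t$ the same similarity for a post-transplant
sample. Then

$$\mathrm{DSI} = 100\,\frac{S_t - S_0}{100 - S_0}.$$

DSI rescales similarity so that the baseline maps to 0 and perfect donor
similarity maps to 100: it is the percent of available headroom closed at
time $t$. It is deliberately **not clamped**: values below zero are
meaningful (the recipient drifted further from the donor than at
baseline) and occur in real cohorts. $S_0 = 100$ leaves no headroom and
raises an explicit degenerate-baseline error. The first baseline BL1 is
never used for $S_0$; it serves as a drift control — the BL1-versus-BL2
similarity shows how much the community moves between two pre-transplant
collections, which is the natural yardstick for post-transplant changes.

Two empirical trajectory patterns are distinguished: a *moderate rise then
decline* (week-1 DSI at or above a threshold, default 40, followed by a
lower final value) and a *low then gradual rise* (week-1 DSI below the
threshold with a higher final value). The published description of these
patterns is narrative, not algorithmic; the classifier here is an explicit
formalization with the threshold exposed as a parameter, and anything
fitting neither shape — including trajectories with fewer than two usable
post-transplant values — is reported `indeterminate` with a reason. The
endpoint rule (engraftment = DSI strictly greater than 50 at 1 month, both
configurable) is evaluated per recipient; timepoints whose samples failed
QC are *not evaluable*, never failures.

## Quality control and CNBP

The read-filtering cascade runs in this order: host-read removal, exact
duplicate removal, ambiguous-end trimming, then a combined quality/length
filter. The order is load-bearing — because host removal runs first, a
duplicated host read is accounted as host, never as a duplicate — and the
report reconciles exactly: input reads equal per-stage removals plus
survivors.

* **Host screen.** Reads sharing at least 2 canonical 31-mers with the
  host reference are removed — the same shared-k-mer logic as the
  similarity kernel, reapplied as a classifier against one reference
  sequence.
* **Duplicates.** Byte-identical raw sequences, first occurrence kept.
  Mates of a pair are treated as independent reads; alignment-based
  pair-coordinate semantics are out of scope.
* **Quality rule.** Reads whose *mean* Phred score over the first 80
  bases (120 for 150 bp MiSeq-like reads) falls below 6 are removed, as
  are reads shorter than 80 (120) bases after trimming. The published
  wording ("quality below 6 over the first 80 bases") does not say
  whether the rule is per-base or aggregate; a per-base rule at Phred 6
  would discard nearly every real library due to isolated bad cycles,
  which is inconsistent with the depths those studies retained, so the
  mean was chosen and is stated here as a design decision.
* **Depth gate / CNBP.** Samples with fewer than
  `min_reads_after_filtering` surviving reads (production default 10⁷)
  are flagged CNBP — *could not be performed* — and excluded from
  similarity analysis. A second, optional trigger flags samples whose
  host-removed fraction exceeds `max_host_fraction`, since excess host
  DNA with few bacterial reads is the typical cause in practice. CNBP
  propagates as missing everywhere: a CNBP timepoint leaves a gap in the
  trajectory, a CNBP recipient or donor baseline blanks the whole
  trajectory, and CNBP values never enter summaries as zeros.

## Taxonomic module

Species abundance is profiled by a deliberately simple marker-gene
assigner: the synthetic marker database guarantees (by rejection sampling
at construction) that no marker k-mer is shared between species, so each
read maps to at most one species; relative abundance is the share of
assigned reads. This is a stand-in for clade-specific-marker profilers in
spirit, not in catalogue. On top of the profiles:

* **Shannon diversity** $H = -\sum p_i \ln p_i$, natural log by default
  (the classical index is sometimes reported in other bases, so the base
  is an argument).
* **Transplanted species**: undetectable in *both* baselines (the
  conservative reading; a flagged option relaxes this to BL2 only),
  present in the donor at any non-zero level, and reaching ≥ 0.2 %
  post-transplant; qualifying species are subtyped transient / persistent
  / late / intermittent by when they appear. "Undetectable" is abundance
  at or below a detection floor, default exactly 0, exposed because real
  profilers have detection limits.
* **Large changes**: absolute changes above 5 percentage points and
  log-scale changes of one log₁₀ or more are flagged separately (a 2-log
  rise from 0.01 % to 1 % is biologically loud but absolutely tiny; the
  dual flag keeps both views). Appearances from zero are flagged rather
  than pseudocounted — a pseudocount would manufacture a fold change out
  of a detection limit.
* **Donor-versus-recipient test**: paired two-tailed t test per species
  on relative abundances (matching the simple spreadsheet-style analysis
  this mirrors; an arcsine-square-root transform was considered and left
  out to keep the published behaviour), Benjamini–Hochberg FDR. Species
  with all-zero paired differences have no defined t statistic and are
  reported with status `constant` and `NA` p, outside the FDR step.
  Species nominally significant (p < 0.05) but not surviving correction
  are flagged `nominal_only`, mirroring how such results are typically
  reported.

## The synthetic cohort generator

Every estimator above is validated against simulated data with known
truth, generated by the package itself:

* **Communities.** Per-species genomes are uniform random sequences
  (default 20 kb). Abundances are log-normal (σ = 1) renormalized to
  100 % — the long-tailed shape typical of gut profiles — with a
  configurable fraction of species shared between donor and recipient.
* **Engraftment ground truth.** A post-transplant community at timepoint
  $t$ is the convex mixture $(1-\pi_t)\,\mathrm{recipient} +
  \pi_t\,\mathrm{donor}$. The schedule π(WK1) = 0.6, π(MO1) = 0.4,
  π(MO2_3) = 0.1 is the default study condition: a strong initial
  engraftment that decays over months, the dominant observed pattern.
  π is exactly the quantity DSI estimates, which is what makes parameter
  recovery a meaningful end-to-end check.
* **Reads.** Uniform fragment positions, uniform strand (minus-strand
  reads reverse-complemented), 93 bp by default (HiSeq-like; 150 for
  MiSeq-like runs). Substitution errors at a configurable rate with a
  two-level quality model (Phred 38 for clean bases, 8 for substituted
  ones); an optional fraction of uniformly Phred-2 "bad" reads exercises
  the quality filter; a configurable fraction of reads is drawn from a
  synthetic 100 kb host reference; a configurable fraction is re-emitted
  verbatim as duplicates. The generator logs everything (read origins,
  host/duplicate/bad ids, true abundances) in a sidecar used by the
  tests, and `expected_qc_counts()` replays the QC cascade as pure
  bookkeeping on that sidecar — exact at error rate 0.
* **Determinism.** One master seed; each sample's stream is derived by
  hashing (sample id, seed), so adding a sample never perturbs another,
  and a regenerated FASTQ is byte-identical.

What the generator does **not** emulate: real genome content (no GC bias,
no repeats beyond chance, no indels), quality-by-cycle decay, strain-level
variation within a species, or any ecological response to the bowel
preparation itself. Consequently, passing tests demonstrate that the
estimators are correct *given their model* — e.g. that DSI recovers π on
mixture data — not that real FMT cohorts satisfy that model; on real data
the donor and recipient share genomic content, which inflates $S_0$ and
compresses the DSI scale, exactly why the index normalizes by the
baseline.

## Numerical and design choices

* k-mers are 2-bit encoded into 64-bit words (k ≤ 31) in a small C++
  core; membership structures are exact hash sets.
* Distinct-k-mer counting per read; ties and boundary reads (length = k)
  documented above.
* The DSI denominator check rejects $S_0 = 100$ explicitly; inputs
  outside [0, 100] are parameter errors, `NA` (CNBP) propagates.
* Pattern thresholds and endpoint threshold/timepoint are explicit
  arguments with the narrative defaults (40; 50 at MO1).
* Marker profiling requires marker length > profiler k (24 by default)
  and fails construction, not assignment, on any cross-species k-mer
  collision.
* Sizes used in the shipped tests and acceptance script are desk-scale
  choices made once: 20 000 reads per sample for parameter recovery
  (binomial error on a shared-read percentage at that depth is ≈ 0.35
  points, far inside the 5-point tolerance), 2 000 reads for QC
  ground-truth recovery, 50 random pairs of ≤ 200 reads for oracle
  equivalence, 1 000 random p-vectors and 40 null cohorts for the
  statistics checks.

## Known limitations

* Similarity is computed on full surviving libraries; there is no
  subsampling to equal depth, so strongly unequal library sizes can bias
  directional percentages (the symmetric score is less sensitive).
* The marker profiler is only as good as its database; with real marker
  catalogues, cross-species k-mer uniqueness must be curated rather than
  guaranteed by construction.
* The paired t test on relative abundances inherits the compositional
  caveats of its spreadsheet-era original; it is provided for
  comparability, not as the state of the art.
* CNBP is a binary gate; partially degraded samples pass or fail wholesale.
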