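---
title: "Mining completely captured gene clusters from a simulated fosmid library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining completely captured gene clusters from a simulated fosmid library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snrcm)
```

## The problem

Large-insert metagenomic libraries (fosmids, ~30-45 kb inserts) are a
practical route from soil DNA to heterologously expressible biosynthetic
gene clusters (BGCs). Three computational questions recur in that
workflow, and this package implements all three against a fully synthetic,
seeded test bed:

1. **Is a candidate BGC completely captured on one clone?** A cluster
   called on an assembled contig is only recoverable from the library if a
   single insert carries all of it. Long reads sequenced from the pooled
   clones answer this directly: if one read contains the whole candidate
   region, some clone does too. We call this check *single-read
   containment mining*.
2. **Which clone in a pool of 2000 carries it?** The library is stored as
   pools; recovering the one positive clone uses rounds of serial dilution
   with PCR screening, and the expected success odds of each round are
   simple binomial arithmetic worth planning in advance.
3. **What if the cluster is bigger than any insert?** A cluster too large
   for one fosmid can still be captured piecewise by overlapping clones
   and reassembled into one construct (transformation-associated
   recombination, TAR); that needs a tiling path, a restriction-digest
   prediction for verification, and a read-based check of the final
   construct.

The package also includes a rule-based annotator for one cluster family —
lasso peptides — because their hallmark is an unusually small precursor
gene that generic gene callers miss.

## Synthetic community, library and reads

Everything runs on simulated data so that every claim has ground truth.
`generate_community()` builds random DNA fragments (stand-ins for
assembled contigs) and plants one cluster per plan row. Lasso clusters
get real gene content — a 1.9 kb asparagine-synthetase-like B/C gene, a
~0.4 kb B2 gene, a ~0.3 kb B1 chaperone gene, a genuine precursor open
reading frame, and optionally an ABC-transporter gene — so the annotator
can rediscover them from sequence. Other classes get generic open reading
frames of the configured total length.

`build_fosmid_library()` ligates inserts into a circular synthetic vector
backbone (8,139 bp, shipped as a fixture). One designed clone per
single-insert cluster guarantees capture; a cluster larger than any insert
gets three designed clones laid out so that *no two* of them cover it —
the minimal tiling answer is forced to be exactly three, which gives the
planner a non-trivial target. The remaining clones are placed uniformly at
random, and clones fill storage pools of `pool_size` in index order.

`simulate_long_reads()` draws log-normal read lengths (truncated to
[1 kb, molecule length]), uniform start positions on the circular
molecule (reads may wrap the vector/insert junction), random strands, and
applies per-base Bernoulli substitutions, insertions and deletions —
substitutions first, then indels. With all rates zero, every read is an
exact substring of its (doubled) molecule, which the tests exploit. The
error model is deliberately simple: no homopolymer bias, no quality
strings, no chimeras. Defaults (5% substitutions, 1.5% insertions, 1.5%
deletions, ~20 kb median length, 20x coverage) are explicit conventions,
not measured values, and sit in `sim_config()` where they can be changed.

Reproducibility contract: one configuration seed fans out to per-stage
seeds by fixed offsets (community `seed`, library `seed+1`, long reads
`seed+2`, short reads `seed+3`, dilution simulation `seed+4`, TAR stage
`seed+5`), so identical config plus identical seed gives byte-identical
stage outputs, and stages are individually reproducible.

## Single-read containment mining

`mine_single_read_containment()` decides, per candidate region, whether at
least one read completely contains it:

1. **Seeding and chaining.** Exact k-mers (default k = 15) shared between
   the region and a read (both strands) are chained colinearly with a
   bounded gap (default 2 kb). Chains never mix strands, so a region is
   never declared complete from mixed-strand fragments of one read.
2. **Refinement.** A chain whose *span* could plausibly reach the
   completeness threshold (span ≥ 0.9 x the coverage threshold) is
   refined by a band-limited Smith-Waterman alignment in a window around
   the chain. The spanned fraction of the region and the alignment
   identity come from the traceback. Chains that cannot reach the
   threshold keep their chain statistics — exact k-mer anchors cannot
   span more of the region than the chain does, so skipping refinement
   cannot miss a complete call.
3. **Verdict.** `complete_on_single_read` when covered fraction ≥ 0.95
   and identity ≥ 0.80 on one read; `absent` when the best covered
   fraction is below 0.05; `partial` otherwise. Ties among supporting
   reads break by (higher coverage, higher identity, lexicographic read
   id).

Two numerical choices deserve comment because they are easy to get wrong:

* **Alignment scoring regime.** The default scores are match +1,
  mismatch −2, gap −2 (linear). With cheaper penalties (e.g. gap −1)
  the expected score of aligning *unrelated* random DNA is positive, so a
  local alignment sprawls across the entire region and every region looks
  at least "partial" on every read. The chosen scores keep random
  alignments in the logarithmic regime where they stay short.
* **Minimum evidence score.** A refined alignment scoring below 50 is
  treated as no evidence (covered fraction 0). Under the default scoring
  the chance of a random alignment reaching 50 is negligible, while any
  genuine containment of a few hundred bases scores far above it; the
  floor only discards junk alignments that survive seeding by accident.

The thresholds (0.95 coverage, 0.80 identity, 0.05 absence floor) are
package conventions, exposed in `containment_params()` and as CLI flags.
The test suite holds the miner to a full (unbanded) dynamic-programming
local-alignment oracle with identical thresholds on randomized
contained/partial/absent pairs and requires 100% verdict agreement.

Upstream of mining, `filter_contigs()` drops contigs shorter than 40 kb
(inclusive boundary) — shorter contigs cannot witness a fosmid-sized
cluster — and `import_regions()` validates candidate regions against
contig bounds and flags regions on a contig edge, which may be truncated
cluster calls.

## Rule-based lasso annotation

The classifier is a small rule table (`inst/extdata/lasso_rules.tsv`)
mapping gene evidence — size in bp, free-text description, domain tag —
to the lasso roles:

```{r rules}
lasso_rules()
```

A rule fires when the size window holds and a regex matches; on multiple
labels the precedence B2 > B1 > C > D > A decides, and all fired rule ids
are reported as the rationale (no silent selection). A B1-type and
B2-type rationale on one gene marks a fused B gene.

```{r classify}
classify_gene(423, "Lasso peptide biosynthesis B2 protein", "PF13471")
classify_gene(294, "PqqD family peptide modification chaperone", "PF05402")
```

Precursor genes are too small for description-based evidence, so the
`A_size_scan` rule fires only for genes ≤ 210 bp whose translation passes
`scan_precursors()`: an open reading frame of 20-70 aa (ATG/GTG/TTG
starts, both strands) with a leader/core split where the core starts with
a ring-donor glycine (optionally Ala/Ser/Cys when relaxed), an Asp/Glu
ring acceptor sits at core position 7-9, at least 3 tail residues follow,
the leader is at least 8 aa, and the residue two positions before the
core is threonine-like ({T, S, L, A, C, V, I}). One candidate is reported
per (ORF, split, acceptor position) and candidates are ranked (Gly donor,
Asp over Glu, Thr at −2, shorter tail). The residue sets and distances
are explicit conventions; each sub-rule is individually falsifiable, and
the tests knock each one out against a brute-force enumeration oracle.

`assess_completeness()` applies the minimal biosynthetic set: A + C + B,
where B is either both B1 and B2 or one fused B gene; an ABC-transporter
D gene is flagged but not required. `annotate_lasso_region()` chains the
pieces and, for small unlabelled genes, rescues precursors by scanning
the gene's own neighbourhood.

## Serial-dilution recovery arithmetic

With the default conversion of 8x10^8 cells/ml per OD600 unit, an OD of
0.25x10^-5 is 2000 cells/ml, so a 100 ul inoculum holds ~200 cells; one
further tenfold dilution and 200 ul gives ~40 cells. For a target clone
at frequency f in the pool and c cells per tube, a tube is positive with
probability 1 − (1 − f)^round(c), and a round of n tubes succeeds with
probability 1 − (1 − p_tube)^n:

```{r dilution}
plans <- standard_dilution_plan(n_tubes = 16)
plans[[1]]
plans[[2]]
```

`simulate_recovery()` is the stochastic twin: it distributes cells
per tube binomially (optionally Poisson cell counts), carries the most
enriched positive tube forward, and plates colonies at the end. The tests
require its Monte-Carlo round-success frequency to sit within 3 standard
errors of the analytic value.

## TAR planning for oversized clusters

`find_tiling_path()` solves minimum interval covering by greedy furthest
reach — provably minimum-cardinality — with the extra constraint that
consecutive fosmids overlap by at least `min_overlap_bp` (default 500 bp;
recombination needs homologous overlap). A coverage gap raises a typed
`tiling_gap` error carrying the uncovered interval.
`assemble_construct()` concatenates the covered reference interval with a
vector stub and plants exactly two copies of a verification site
(default `ATTTAAAT`, an 8-bp blunt cutter), removing incidental
occurrences. `predict_digest_fragments()` predicts the restriction
fragments (circular: arcs between cuts, lengths summing to the molecule
length; linear: ends add one fragment). `size_filter_reads()` assigns
reads to expected fragment sizes within a relative tolerance, and
`verify_assembly()` requires every predicted fragment to be completely
contained in at least one read of its size group — the same single-read
containment machinery used for mining.

## The pipeline and the demo configuration

`run_pipeline()` chains simulate → mine → annotate → dilution → tar,
writing per-stage files and a checksum manifest. The shipped
`demo_config()` plants six clusters — two lasso (one with a
transporter), a bacteriocin, a terpene, a lanthipeptide, and one ~58 kb
NRPS-like cluster that cannot fit any insert — into ~500 clones at 20x
long-read coverage and 8% total read error. At these study conditions the
pipeline calls all five single-insert clusters complete on single reads,
calls the 58 kb cluster partial, tiles it with exactly three clones,
and the digest-plus-read verification of the reassembled construct
passes.

```{r pipeline, eval = FALSE}
run <- run_pipeline(demo_config(), out_dir = "demo_out")
run$mine$verdicts
run$tar$bgc76.1$verification
```

A thin command-line interface wraps the same functions
(`system.file("cli", "snrcm.R", package = "snrcm")`) with subcommands
`simulate`, `mine`, `annotate-lasso`, `plan-dilution`, `plan-tar`,
`verify` and `run`; it logs to stderr, writes results to files only, and
exits 0 on success, 2 on usage errors, 3 on stage failures.

## Limitations

* The read simulator has no homopolymer or quality model; error rates are
  conventions, not fits to basecaller output.
* Hybrid assembly and antiSMASH-style region calling are consumed as
  inputs (the simulator writes truth regions), not reimplemented.
* The lasso rule table encodes keyword evidence, not HMM domain searches;
  domain tags are input evidence.
* The dilution model ignores growth competition between clones and PCR
  false positives (false negatives are supported via
  `dilution_params()`).
* TAR recombination chemistry is out of scope; only its planning and
  verification arithmetic is implemented.
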