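---
title: "Insertion-site sequencing analysis for group II intron retrotransposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-site sequencing analysis for group II intron retrotransposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rigseq)
library(dplyr)
```

## The assay and the analysis problem

Group II introns are retroelements that normally re-insert ("retrohome")
into a single cognate site, but at low frequency they also invade ectopic
genomic sites — retrotransposition. RIG-Seq is a targeted amplicon assay
that captures these events: after selecting retrotransposition-positive
colonies via a retromobility indicator gene, nested PCR amplifies the
junction between the intron 3′ end and the invaded locus, so each sequenced
read carries

```
[6-nt library index][6 random nt][intron 3′-end tag][genomic 3′ flank]
```

with a low-quality tail on the flank end. The analysis questions are
tabular ones: which replicon (chromosome vs intron donor plasmid) each read
comes from, which unique boundaries were invaded and at what relative
frequency, how site diversity compares across libraries of different depth,
and what the sequence context around the boundary looks like — in
particular C at position −6 (the most conserved residue) and T at +5 (the
signature of the endonuclease-dependent double-strand pathway; its absence
marks single-strand DNA invasion).

This package implements the full computational pipeline —
demultiplex/trim, exact-match mapping, event collapsing, subsampling
normalization, and site profiling — together with a ground-truth simulator
that generates RIG-Seq libraries with the published structure, and sequence
utilities for the relaxase nick-site biochemistry that accompanies the
assay (in-silico PCR, primer-extension arithmetic, oriT-similarity
scanning).

## The simulator defines the study conditions

`sim_config()` encodes the library design as data: one row per library with
its barcode, relaxase status, number of chromosomal insertion sites,
chromosomal read fraction, frequency-spectrum concentration, and depth. The
defaults are the published study conditions:

* three libraries — relaxase absent (`D-C`), relaxase from the conjugative
  element (`D-pRS01`), relaxase expressed alone (`D-pLtrB`) — with 154, 461
  and 912 chromosomal insertion sites and chromosomal read fractions of
  5.2%, 30.4% and 86.9% respectively;
* `p_C6 = 0.90` and `p_T5 = 0.25`: each planted site's event-strand base at
  −6 is C with probability 0.90 (otherwise uniform over A/G/T) and at +5 is
  T with probability 0.25, reproducing the ~90% C−6 / ~25% T+5 composition
  of the real libraries;
* 20–21-nt genomic flanks with a 5-nt Q2 tail (so 15–16 nt survive
  trimming), constant Q37 elsewhere, Phred+33;
* 50,000 reads per library on a synthetic 100-kb circular chromosome and a
  12-kb circular donor plasmid.

Choices the assay description leaves open were fixed once, on realism
grounds, and are not tuned:

* **Frequency spectra.** Per-site relative frequencies are symmetric
  Dirichlet draws; relaxase-positive libraries use a higher concentration
  (4 vs 2) because relaxase flattens the event spectrum. Concentration 2–4
  gives skewed-but-not-dominated spectra: a 154-site library then spans
  roughly two orders of magnitude in per-site frequency, which is what
  selection-based insertion assays typically show.
* **Replicon sizes.** The chromosome is scaled to 100 kb (the real one is
  2.4 Mb) while keeping the published site counts, so tests and the
  acceptance script run at desk scale; all coordinate arithmetic is
  length-independent. The donor plasmid gets 50 insertion sites per library
  (plasmid events are a nuisance variable here — only their read share
  matters).
* **Site spacing.** Planted boundaries are kept ≥ 30 nt apart (across all
  libraries) so that −6/+5 edits and −12..+6 profile windows of different
  sites never collide. Placement walks a random permutation of positions,
  blocking each accepted site's neighbourhood; it errors explicitly if the
  replicon jams before all sites are placed.
* **The intron 3′-end tag.** The real tag fragment is construct-specific,
  so a fixed synthetic 20-nt tag ships as the default; all trimming logic
  is sequence-agnostic and requires only ≥ 8 nt.
* **No sequencing-error model.** The downstream mapper is exact-match, so
  read errors would only reduce yield without changing any estimand; the
  only "quality" feature simulated is the fixed low-quality tail.

Every stage derives its stream from the single config seed, so whole runs
are bit-reproducible.

What passing tests on these libraries do *not* show: robustness to real
base-calling errors, chimeric PCR artefacts, index hopping, or mappability
structure of a real 2.4-Mb genome (repeats, prophages). The simulator is a
correctness harness for the pipeline arithmetic, not an error-model
benchmark.

## Trimming and mapping

`run_trim()` assigns each read by exact, case-insensitive match of its
first six bases (6-nt indices leave no safe 1-mismatch margin), finds the
tag by exact substring search anywhere in the read (the random hexamer is
skipped implicitly, and overlapping tag occurrences count as ambiguous),
drops everything through the tag plus the fixed 5-nt tail, and accepts
flanks of 15–16 nt. Reads whose retained flank contains `N` are rejected at
trim time — an `N` can never exact-match, and counting such reads as
"unmapped" would blur trimming QC into mapping QC. The report partitions
the input exactly: category counts always sum to the read count.

`map_flanks()` is the zero-mismatch limit of short-read alignment: with a
15–16-nt read, an aligner's seed spans the whole read, so "0 mismatches in
the seed, try hard, report best" reduces to exact full-length matching on
both strands. The index stores every plus-strand window (length L per
circular replicon, wrapping the origin); minus-strand hits come from
querying the flank's reverse complement, which is equivalent to indexing
both strands. A single genomic occurrence is `unique`; several are
`ambiguous` — excluded from event counting by default (`unique-only`),
because the headline statistic is *unique* insertion points. A
`best-first` mode instead assigns the lexicographically smallest
(replicon, strand, start) occurrence, emulating a single-report best-hit
aligner deterministically; which behaviour the original analysis used is
not recoverable, so both are provided and the default is documented.

Replicon preference is reported over uniquely mapped flanks (the
denominator behind "X% of reads were chromosomal"), with the
unmapped/ambiguous share reported separately over all demultiplexed reads.

## Events, frequencies, subsampling

The sequenced flank is the 3′-exon side of the insertion, so a plus-strand
flank starting at *s* places the boundary at *s* (the intron sits between
*s*−1 and *s*), and a minus-strand flank over plus-interval [*s*, *e*)
places it at *e* on the − strand. Opposite-strand events at the same
boundary are distinct — reverse-splicing orientation matters biologically.
Relative retrotransposition frequency divides an event's read count by the
library's uniquely mapped chromosomal reads (donor-plasmid events are
normalized separately and flagged); whether the original denominator
included unmapped reads is unstated, so the choice is documented here
rather than guessed.

Libraries of different depth cannot be compared by raw unique-site counts,
so `subsample_unique_counts()` draws K equal-size read subsets without
replacement — each an independent Algorithm-R reservoir pass seeded as
`seed + subset_index` — and averages the unique-site count. The published
analysis used K = 1000 subsets of S = 250,000 reads; the package defaults
to desk-scale K = 100 and S = min(pool, 10,000), with the configuration
carrying whatever full-scale values a real run needs and all parameters
recorded in the result object. Exactness is tested against exhaustive
subset enumeration on toy libraries, and the mean is checked to be
non-decreasing in S.

## Insertion-site profiles

Windows span −12..+6 around the boundary (no position 0), covering the
intron-binding sites IBS2/IBS1 upstream and the δ′/+5 region downstream.
Upstream sequence is taken from the reference, not from reads — reads
carry only the 3′ flank, so the reference is the only possible source of
−6 composition. Minus-strand events mirror by reverse complement;
flipping every event strand together with the reference is a no-op on the
profile (tested).

Two standard modes are emitted, matching the two published analyses:
an *unweighted* profile over the whole site set irrespective of
frequencies, and a *frequency-weighted* profile restricted to events with
relative frequency ≥ 5×10⁻³ (the published cutoff). Note the cutoff
interacts with library size: a flat 912-site library has mean frequency
1.1×10⁻³, so at the published cutoff only its high-frequency tail enters
the weighted profile — exactly as in the original analysis. Key-position
recovery in the tests and acceptance script therefore uses the
whole-site-set mode. Columns are normalized to sum to 1; an empty
post-cutoff profile is an explicit error.

`consensus()` calls a base at ≥ 0.5 column frequency, otherwise the
minimal IUPAC code over bases at ≥ 0.25 (the secondary threshold is a
documented choice — the original grid-profile procedure is not
algorithmically specified). `compare_to_homing()` reports, per position,
the modal base, agreement with a homing-site model string, and Shannon
information 2 − H in bits — the logo-ready export. The default model
string is an illustrative synthetic stand-in with the key residues (C−6,
T+5) in place; the exact construct sequence is user-suppliable and all
scoring is model-relative.

## Nick-site utilities

The relaxase (the conjugation-initiating enzyme that nicks oriT
site- and strand-specifically) is probed with oligo-scale experiments whose
arithmetic this module reproduces:

* `insilico_pcr()` — exact-match primer location in all orientations, with
  origin-spanning products on circular templates; amplicon length includes
  both primer footprints (the convention under which the cloned glnP
  fragment is 1323 bp).
* `primer_extension_product()` — extension terminates at a template nick;
  the product covers all positions strictly 5′ of the nick on the
  synthesized strand, which is how a 96-nt nicked substrate yields a 61-nt
  band when the nick sits 61 nt from the primer start.
* `orit_similarity_scan()` — ungapped both-strand sliding comparison
  against a user-supplied nic window, reporting windows at or above an
  identity floor (default 9 of 15, the similarity of the published glnP
  off-target site to the cognate oriT nic site). The cognate nic 15-mer is
  configuration, not a shipped constant — it is construct-specific and not
  machine-readably published.

## A worked run

```{r pipeline, message = FALSE}
libs <- default_libraries() |>
  mutate(n_sites = c(30L, 60L, 120L), reads = 5000L)
cfg <- sim_config(seed = 7, chrom_length = 30000, libraries = libs)

sim <- simulate_rigseq(cfg)
trimmed <- run_trim(sim$reads, cfg$libraries, cfg$tag)
index <- index_reference(sim$reference)
mapped <- map_flanks(trimmed$flanks, index)
replicon_summary(mapped)
```

```{r events}
events <- collapse_events(mapped, index) |> relative_frequencies()
ks <- events |>
  filter(role == "chromosome") |>
  group_by(library) |>
  group_modify(~ key_position_stats(build_profile(
    extract_windows(.x |> mutate(library = .y$library), sim$reference),
    cutoff = 0, weighted = FALSE
  )))
ks
```

The same stages, with outputs and a manifest written to disk, run as
`run_pipeline(rigseq_config(simulate = cfg), outdir)`.

## Numerical choices and limitations

* Coordinates are 0-based half-open internally and in BED output; the
  human-readable mapping TSV documents its convention. Circular
  coordinates reduce modulo the replicon length.
* Ambiguity tie-breaks (multi-hit placements, consensus code selection)
  are deterministic, never random.
* Subsample standard deviation is reported across subsets; with K = 1 it
  is `NA` by construction.
* The package does not model conjugal transfer, retrohoming into the
  cognate site (the donor construct is designed to exclude it), peak
  calling or hotspot statistics near oriC/Ter, primer thermodynamics, or
  relaxase kinetics.
* Headline wet-lab percentages (retrotransposition frequencies per
  colony-forming unit) are outside the computational scope; the read-level
  percentages above are recovered from simulation because the original
  raw libraries were not deposited.

## Problem sizes used by the tests and acceptance script

The test suite exercises references of 0.3–100 kb, libraries of 10²–10⁵
reads, mapper cross-checks of 1,000 flanks against a brute-force
both-strand scan on 10-kb references, and subsampling at K = 10⁴ on
enumerable toy libraries. The acceptance script runs the full default
conditions (3 × 50,000 reads, 100-kb chromosome, all 1,527 chromosomal
sites) and reports recovered read fractions, site counts, recovery rate,
key-position percentages and subsampled unique-site means.
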