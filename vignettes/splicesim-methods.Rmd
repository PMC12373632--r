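---
title: "splicesim: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicesim: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `splicesim`, the
assumptions it rests on, and the design decisions taken where the
protocol leaves room for interpretation. It states no empirical result;
the numbers the package produces are computed by its test suite and by
`scripts/acceptance.R`.

## The simulation model

`splicesim` treats a Smart-seq3 experiment as a three-layer generative
process.

**Layer 1 — empirical protocol characteristics.** Library preparation
leaves fingerprints in the data that depend on wet-lab specifics
(tagmentation time shortens fragments; nuclei input raises the
unspliced fraction; sequencing depth shapes reads per UMI). Rather than
parametrise these mechanistically, `characterize_data()` measures them
as weighted empirical distributions from a user-supplied tagged BAM and
the simulator resamples from them. Sampling can therefore only produce
values observed (or explicitly declared) in the characterised data —
deliberately so: the goal is to mimic *a particular dataset's*
conditions, not a population model.

Fragment lengths are measured as the number of *exonic* positions
between the outermost aligned positions of a pair, and only on
estimation genes: genes on chromosomes 1–22/X/Y (with or without a
`chr` prefix, to cover both Ensembl and UCSC naming), with a single
annotated transcript, whose genomic span overlaps no other gene. Span
overlap is tested strand-agnostically on the full gene extent rather
than exon by exon — the conservative reading, which minimises
ambiguity about which gene a pair belongs to. Pairs with zero exonic
overlap (e.g. purely intronic) are dropped from the length
distributions but still contribute to intronic-coverage statistics.
Multi-mapped reads are handled by excluding non-primary alignments;
pairs lacking a `BC` tag are counted and skipped rather than fatal,
because real demultiplexed output contains unassigned reads. Quality
profiles use aligned-read quality strings at the modal read length;
shorter reads contribute to their positions only. The barcode-segment
quality profile slot exists in the bundle but is empty by default: BAM
`BC` tags carry no quality string, and the read-position profile is
applied to the whole read during simulation.

**Layer 2 — ground truth.** The experiment design is p populations × c
cells. The transcript UMI count matrix is built by the cascade
described in the README; the choices worth recording:

* *Minimum gene count n.* A gene's count is floored at its simulated
  transcript count, so every isoform can receive at least one UMI in
  expectation and the PSI apportionment is well posed. The floor is
  user-adjustable (`n_min` / `--min-umis`).
* *Cell size factor.* Drawn log2-uniformly on [2⁻², 2²]: the range is
  stated in powers of two, and log-uniform sampling makes halving and
  doubling equally likely, which is how capture-efficiency variation is
  usually conceived. Counts scale as `round(base × s)` with
  round-half-even, then are re-floored at n.
* *PSI law.* "Randomly distributing 100%" is realised as a flat
  Dirichlet (uniform on the simplex) — the least-informative choice.
  It does not reproduce the dominant-isoform bias of real
  transcriptomes; users wanting realistic isoform-usage priors should
  supply their own matrices. Novel transcripts participate in the PSI
  draw as ordinary isoforms of their gene.
* *Rounding.* Unspliced counts use round-half-even; spliced counts are
  apportioned by largest-remainder rounding (ties broken by transcript
  order), so per-gene per-cell totals are conserved *exactly* — a
  property the test suite asserts on thousands of random cascades.
* *Unspliced species.* One intron-retaining pre-mRNA per gene (the full
  exon-span sequence), matching the gene-level granularity of the
  unspliced matrix. Per-intron partial retention is out of scope.

Novel events: `add_new_junction()` joins two existing, ordered,
non-overlapping exons of the gene across a junction no annotated
transcript uses, grafted onto a randomly chosen annotated backbone.
`add_new_exon()` places a new exon strictly inside an intron; with
`canonical = TRUE` (default) the 2 nt preceding the exon on the sense
strand must read AG and the 2 nt following it GT, i.e. both newly
created introns keep canonical acceptor/donor motifs (on the minus
strand this is checked as genomic CT/AC). The admissible-placement scan
is exhaustive over motif positions, and an independent verifier
(`verify_canonical_exon()`, which reads the genome directly and shares
no code with the search) re-checks every emitted placement in the
tests.

**Layer 3 — reads.** Eight steps, mirroring the protocol:

1. Tagging: each molecule becomes `ATTGCGCAATG` + UMI + `GGG` +
   transcript sequence. UMI length defaults to 8 nt and barcode length
   to 16 nt (protocol-conventional values, both configurable). UMIs
   are unique within (cell, gene) — collisions across genes are
   allowed, matching how UMI counting is keyed — so ground-truth
   molecule counts stay identifiable.
2. PCR: the molecule's target read count r is drawn from the empirical
   reads-per-UMI distribution; `max(1, round(r × paf))` copies are
   created. The PCR amplification factor (default 5) models the fact
   that not all amplified fragments are sequenced: it inflates
   temporarily and subsampling later restores r, without simulating
   cycle-by-cycle doubling. Any `paf ≥ 1` satisfies the contract; the
   tests exercise several values.
3. UMI fragments: a 5′ prefix per copy, length drawn empirically and
   *clamped* (never resampled) to the molecule length. Clamping is
   unbiased for transcripts longer than typical fragments and
   deterministic for short ones; it is the main known source of
   distributional deviation for very short transcripts.
4. Internal fragments: per molecule, `round(ratio × copies)` fragments
   at uniformly random offsets in the remainders (Tn5 insertion-site
   bias is not modelled), lengths drawn empirically and clamped. An
   empty remainder yields none.
5. Reads: read 1 = first `read_len` bases, read 2 = reverse complement
   of the last `read_len` bases (FR geometry). Internal fragments are
   reverse-complemented with probability 0.5 first; UMI fragments
   always keep transcript sense.
6. Errors: independent per-base substitution at P (default 0.005),
   uniform over the three alternative bases; no indels, no PCR-error
   inheritance (duplicates differ only by sequencing error, because
   errors are injected on final reads).
7. Subsampling: per molecule, `min(r, copies)` UMI pairs are kept
   uniformly; internal pairs are thinned by the same *global* retention
   fraction, preserving the internal-to-UMI balance set in step 4.
   Whether the original protocol ties internal subsampling to UMI
   subsampling per molecule is not observable from the outputs; the
   global coupling keeps the step-4 ratio exact in expectation.
8. Qualities: position i of each read draws from the empirical profile
   at position i; reads beyond the profile reuse its last position.

All randomness flows through one seeded RNG; stage seeds derive from
the global seed by a fixed splitting rule (`child_seed()`), so a stage
is reproducible regardless of what ran before it and identical seeds
give byte-identical FASTQ.

## What the synthetic fixtures emulate — and what they do not

`make_toy_reference()` builds contigs of ~9 kb carrying, each, one
single-transcript gene (a clean estimation target) and three
multi-transcript genes, one on the minus strand, with planted canonical
AG/GT slots at recorded intron positions. `make_toy_bam()` draws
exonic fragment lengths from a discretised log-normal (median 400 nt,
σ = 0.25 on the log scale), reads per UMI from a truncated geometric
(mean ≈ 2), and plants intronic pairs, a BC-less pair and a secondary
alignment to exercise the skip rules. `make_default_characteristics()`
is fully parametric (log-normal fragment lengths with medians 350/200
nt for UMI/internal fragments, geometric reads per UMI, 80% of genes
fully spliced, negative-binomial UMIs per gene with mean 12, Phred
profile decaying gently from Q37) — values at typical Smart-seq3
scale, chosen once as defaults, not copied from any real dataset.

Passing tests on these fixtures demonstrates that the machinery is
correct — coordinates, conservation, strand rules, distribution
round-trips — not that simulated data matches any particular real
experiment. Real data adds features the fixtures do not model: GC
bias (not modelled at all, by design — simulation output inherits only
whatever composition the reference has), positional Tn5 bias, adapter
read-through, indels, overlapping genes and ragged read lengths beyond
the modal-length rule.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GTF I/O
  converts at the boundary (1-based inclusive). Round trips preserve
  every printed integer.
* Distribution round-trip tests use a two-sample Kolmogorov–Smirnov
  statistic against the weighted reference CDF, with the pass
  threshold *calibrated by resampling the reference against itself* at
  the observed sample size (upper 0.5–1% quantile of the null), rather
  than a fixed critical value — this accounts for the discreteness of
  the supports.
* Degenerate inputs are defined, not fatal: empty count matrices give
  valid empty FASTQs; empty remainders give zero internal fragments;
  an empty transcript tags to tag + UMI + GGG; genes with zero
  UMI-containing reads are omitted from the ratio distribution
  (division undefined, logged).
* Error paths are explicit: fewer eligible genes than requested,
  overfull barcode spaces, UMIs-per-gene support below the minimum
  count, no admissible novel junction/exon, schema-version mismatches.

## Problem sizes

The test-suite and acceptance-script simulations use 9 genes over 3
contigs with 2 populations × 25 cells (≈6,000 molecules, ≈30,000 read
pairs, ≈10⁷ bases), which gives the statistical checks comfortable
resolution (3σ binomial intervals of ±0.0002 on the error rate, ±0.012
on the antisense fraction); the end-to-end scaled design uses 20 genes
× 2 populations × 10 cells. These sizes were chosen to make the checks
sharp while keeping the default developer loop fast; all scale
parameters are plain arguments.

## Known limitations

* Fragment-length clamping biases lengths downward for transcripts
  shorter than typical fragments.
* The flat-Dirichlet PSI prior and the single pre-mRNA species per
  gene are simplifications (see above).
* No GC bias, Tn5 sequence bias, indels, adapter read-through, PCR
  error inheritance, or direct BAM output.
* `read_alignment_pairs()` loads pairs into memory per file/region
  rather than streaming record by record; characterisation of very
  large BAMs should pass `region` to work chromosome by chromosome.
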