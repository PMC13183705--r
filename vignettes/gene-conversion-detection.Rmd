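---
title: "Detecting gene conversion in IGHV repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene conversion in IGHV repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igconvert)
```

## The problem

In species whose antibody repertoires rely on few functional V genes,
diversity can be generated by *gene conversion*: non-reciprocal transfer of a
sequence tract from a donor — typically a pseudogene — into a homologous
rearranged acceptor V gene. The observable footprint of such an event in a
sequenced repertoire is a contiguous run of mismatches between a repertoire
sequence and its assigned functional germline gene that is, at the same time,
similar or identical to a pseudogene elsewhere in the locus.

`igconvert` implements this detection logic end to end for immunoglobulin
heavy-chain V (IGHV) repertoires: mismatch-block extraction, donor
attribution by edit distance, a genomic gene-order filter, event
characterization (flanking identity, expanded extents, AID-motif context,
non-B DNA motifs), repertoire-level summaries, and a simulator that
generates repertoires with implanted tracts and ground truth so that every
stage is testable without external data.

## Detection model

### Mismatch blocks

A repertoire sequence and its assigned functional germline are compared in
shared IMGT-gapped coordinates. A *mismatch block* is a maximal run of
consecutive columns at which both sequences carry a base and the bases
differ. Two conventions matter and are explicit parameters:

* `min_block_len` (default **3 nt**) — the smallest block retained. Three
  consecutive mismatches is the conventional floor below which a cluster
  cannot be distinguished from coincident point mutations.
* `merge_gap` (default **0**) — runs separated by at most this many
  non-mismatching columns are merged into one block. The default treats
  blocks as pure consecutive-mismatch runs; merging lets long, interrupted
  conversion tracts surface as single events when desired.

Columns where either sequence has an IMGT gap (`.`) or an ambiguous base
(`N`) are *neutral*: they never count as mismatches, never count as matches,
and terminate a run unless `merge_gap` absorbs them. This prevents ambiguous
base calls from fabricating events.

### Donor attribution

Each block's read sequence is scanned against the ungapped sequence of every
pseudogene for the segment minimizing the Levenshtein (unit-cost edit)
distance. A donor hit is accepted when that minimum is at most `max_lev`
(default **1**): most genuine donor segments match exactly and a small cap
bounds false attribution, while remaining configurable for noisier data.
Ties between minimal-distance segments are broken deterministically:

1. greater combined 5′+3′ flanking identity between the donor context and
   the read context (window `flank_w = 6` nt per side) — the biologically
   meaningful criterion, since conversion initiates in flanking homology;
2. smaller absolute difference between the donor offset and the block's
   (ungapped) start — positional conservatism;
3. lexicographically smaller donor name, then offset and length — pure
   determinism.

For blocks of ≥ 18 nt the scan uses k-mer seeds (`seed_len = 8`) with the
pigeonhole guarantee that any segment within `max_lev` edits contains at
least one exact seed; candidates around seed hits are verified with the full
edit distance, so the seeded path returns exactly the exhaustive result
(this equality is asserted in the test suite against an independent
`utils::adist` oracle). Distances are computed on the block alone; flanking
identity is recorded separately rather than folded into the distance.

Donors are drawn only from the pseudogene set, so self-donation is excluded
by construction. Block coordinates are reported in IMGT-gapped acceptor
columns, donor offsets in donor-ungapped coordinates; both conventions are
fixed in the output schema.

### Gene-order filter

Gene conversion uses donors located 5′ (upstream) of the acceptor, so
events whose attributed pseudogene lies 3′ of the acceptor functional gene
are excluded. Locus order is read **only** from an explicit gene-order
table — never inferred from IMGT gene-name numbering, which does not encode
physical order reliably. Internally, ranks increase strictly 5′→3′ and the
filter keeps exactly the events with `rank(donor) < rank(acceptor)`; the
loader normalizes whatever position convention the input table uses.
Orientation flags are stored but deliberately unused: the filter is purely
positional, and inverted genes are handled by their rank alone, since no
orientation-specific rule is established for this filter.

## Event characterization

* **Flanking identity** — walking outward from the block in the
  donor-anchored alignment, the number of consecutive positions at which
  acceptor and donor are identical, separately 5′ and 3′. These homology
  flanks are where conversion is thought to initiate, and they bound the
  true extent of the event.
* **Expanded event** — the block extended by its identical flanks, clamped
  to the sequence; the inferred minimal extent of the conversion tract. A
  3-nt block with (6, 1) flanks expands to 10 nt.
* **AID motif context** — the coding strand is scanned for the AID target
  motifs WRCY, RGYW, TW and WA (IUPAC: W = A/T, R = A/G, Y = C/T), with
  overlapping occurrences all reported and `N` never matching.
  Reverse-strand scanning is available behind a flag; the default mirrors
  coding-strand hotspot annotation practice. Distance from a block to the
  nearest motif is 0 on overlap and 1 for an immediately adjacent motif
  (each intervening nucleotide adds 1). This "adjacent = 1" convention is
  the package default because events cluster next to, rather than within,
  AID motifs; a `convention = "gap"` switch counts only intervening
  nucleotides.
* **Hotspot overlap** — each event is `full` (contained in a motif),
  `partial` (intersecting one) or `none`; the three categories partition
  all events by construction. Overlap counts are tallied over motif
  instances, not nucleotide columns.
* **Positional profile** — over the range from the minimum event start to
  the maximum event end, the percentage of events covering each position.
  The denominator is the number of events by default; a flag switches to
  the number of sequences. The choice is recorded in the output metadata
  because either normalization is defensible and they differ by a constant
  factor.

## Non-B DNA motifs

Seven classes of structure-forming motifs are scanned with per-class
thresholds (all configurable via `nonb_params()` and recorded with each
result): direct repeats (arm ≥ 10 nt, spacer ≤ 10), inverted repeats
(arm ≥ 6, spacer ≤ 100), mirror repeats (arm ≥ 10, spacer ≤ 100), short
tandem repeats (unit 1–9 nt, ≥ 3 copies, ≥ 12 nt), G-quadruplex runs
(`G{3,}(N{1,7}G{3,}){3}`), Z-DNA tracts (alternating purine–pyrimidine of
GC/GT/AC steps, ≥ 10 nt) and A-phased repeats (≥ 3 A-tracts of 3–9 nt at
~10 nt periodicity). The defaults follow the conventions of the standard
non-B motif search tools. Occurrences are maximal in a precisely stated
sense — one occurrence per maximal agreement run and repeat period — and
this normative definition is what the exhaustive-scan oracle in the test
suite checks for direct repeats.

## Repertoire summaries

Per-sample accounting reports the pipeline counts and
`%GC = 100 × n_filtered / n_unique`, i.e. the share of unique sequences
carrying at least one order-filtered event — the numerator counts GC+
sequences, not raw events, matching how the percentage is tied to unique
sequence counts; a flag switches to event counts. Percentages are rounded
half-up to two decimals; the summary mean is the arithmetic mean of the
per-sample values. Family/gene usage, the donor–acceptor matrix (long
format, chord-diagram-ready) and 10-nt flank-window FASTA export for
external motif discovery complete the reporting layer. Windows truncated at
sequence boundaries are flagged, and events whose expanded extent starts at
the first nucleotide have no 5′ window at all.

## The simulator

The generator emulates exactly the structure the detector assumes, with
defaults chosen once as the package's study conditions:

* 5 functional genes and 10 pseudogenes of 300 nt; each pseudogene derives
  from one functional gene and is mutated until its realized global-alignment
  identity to the source lies within 2 points of `pseudo_identity`
  (default **0.65**, the middle of the 60–68% identity range typical of
  donor/acceptor pairs). Identity is measured with the package's own
  aligner, so gap-mediated match recovery is accounted for.
* Each pseudogene carries 3 *implant sites*: windows whose 5′ and 3′
  anchors (defaults **6** and **1** nt, the dominant flank lengths around
  short conversion events) stay identical to the source gene while the
  enclosed core — its length drawn from `tract_len_range`, default 3–30 nt —
  is fully mutated. A fully mutated core guarantees every implant is
  non-silent and carries a contiguous mismatch run at least as long as the
  tract, which is what makes exact recovery a meaningful target. With
  `pseudo_identity = 1` nothing is mutated and all conversions are silent;
  silent conversions are recorded in the ground truth and excluded from
  sensitivity denominators, mirroring the fact that a conversion without
  mismatches is unobservable.
* Reads copy a uniformly chosen acceptor, implant one tract with
  probability `implant_fraction` (default **0.1**), then undergo
  AID-biased SHM: per-base substitution at `shm_rate` (default **0.005**),
  multiplied by `hotspot_multiplier` (default **3**) inside WRCY/RGYW
  occurrences. A single integer seed drives one generator stream through
  all stages; identical (config, seed) gives byte-identical output, and the
  caller's RNG state is never disturbed.
* First-wave pseudogenes are placed upstream of all functional genes,
  second-wave ones downstream, so `downstream_donor_fraction` can exercise
  the order filter (1.0 must empty the post-filter event set).

What the simulator does **not** model — V(D)J junctions, clonal lineages,
indel SHM, non-uniform sequencing error — bounds what passing tests show:
they demonstrate correctness of the detection logic under its own
assumptions, not performance on real repertoires, where annotation error
and junctional diversity add failure modes the synthetic data cannot
exhibit.

## Numerical choices

* Pairwise identity uses global affine-gap alignment over ungapped
  sequences with match +1, mismatch 0, gap open 2, gap extend 1 and
  identity = matches / alignment columns; the traceback prefers the
  diagonal state, then a gap in the second sequence, at equal scores, which
  fixes the reported identity among co-optimal alignments. The alignment
  score is cross-checked against `Biostrings::pairwiseAlignment` and the
  identity against a full DP-with-traceback oracle in the tests.
* Alleles of one gene collapse to the gene-level name for locus-rank
  purposes; all alleles remain available as alignment targets.
* Degenerate inputs: empty sequences are errors for identity; empty event
  sets flow through every summary as empty results, not errors; reads with
  malformed quality strings are rejected individually, never aborting a
  stream.
* Quality filtering applies Phred ≥ 30 inside the merged-overlap interval
  and ≥ 20 elsewhere (the read ends). When merger metadata is absent the
  overlap interval defaults to the central region `[trim, len − trim)` with
  `trim = 50` nt — a declared default, not an inference; it is configurable
  because merger conventions vary.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, the package's chosen verification sizes: 1,000-read
repertoires for recovery and rate checks, 1,000 random pairs for the edit
distance oracle, 200 block/donor cases for the donor-scan oracle, 1,000
350-nt sequences for the AID-motif oracle and 100 300-nt sequences for the
direct-repeat oracle. Reproducing a full multi-animal accounting table from
raw reads additionally requires the deposited sequencing runs and an
external V-annotation service; that workflow is documented in the README as
optional and is not part of the verification surface.

## Known limitations

* Donor attribution reports one best donor per block; genuinely ambiguous
  blocks (segments shared by several pseudogenes) are resolved by the tie
  chain rather than reported as multi-donor events.
* The order filter drops events whose donor lacks an order-table entry;
  such donors are counted separately but never rescued.
* Overlap categories and positional profiles assume one shared coordinate
  system; sequences with indels relative to the germline are outside the
  current model.
* Light-chain and D/J conversion are not precluded by the design but are
  untested.
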