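# igconvert

Detection and characterization of gene-conversion events in immunoglobulin
heavy-chain V (IGHV) repertoires.

In species with restricted V-gene usage, antibody diversity can come not
from V(D)J combinatorics but from **gene conversion**: non-reciprocal
transfer of a sequence tract from a donor pseudogene into a homologous
rearranged functional V gene. `igconvert` is for immunogenetics and
repertoire-analysis groups who want to find and quantify these events in
annotated B-cell receptor repertoires — and to validate the whole pipeline
on synthetic data with known ground truth.

## What it computes

Given a germline set (functional genes + pseudogenes, IMGT-gapped FASTA), a
locus gene-order table, and an AIRR-style table of annotated productive
sequences, the pipeline:

1. **Mismatch blocks** — maximal runs of ≥ `min_block_len` (default 3)
   consecutive mismatching columns between each sequence *r* and its
   assigned functional germline *g*, in shared IMGT-gapped coordinates
   (gap and `N` columns are neutral).
2. **Donor attribution** — for each block *b*, the pseudogene segment *s*
   minimizing the Levenshtein distance `d(b, s)`, accepted when
   `d ≤ max_lev` (default 1); ties break on 5′+3′ flanking identity to the
   read context, then position, then name. Long blocks use a seeded scan
   that provably equals the exhaustive one.
3. **Gene-order filter** — events are kept only when
   `rank(donor) < rank(acceptor)` in the locus (donor 5′ of acceptor).
4. **Characterization** — identical-flank lengths 5′/3′ of each block
   against the donor, the *expanded event*
   `[start − five_len, end + three_len)`, distance to the nearest AID
   hotspot motif (WRCY/RGYW/TW/WA; adjacent = 1), full/partial/no hotspot
   overlap, positional event percentages, and non-B DNA motif context
   (direct/inverted/mirror repeats, STR, G4, Z-DNA, A-phased repeats).
5. **Summaries** — per-sample accounting with
   `%GC = 100 · n_filtered / n_unique`, family and gene usage, the
   donor–acceptor count matrix, and 10-nt flank-window FASTA export for
   motif discovery.

A simulator (`sim_config()`, `simulate_repertoire()`) generates toy loci
and repertoires with implanted tracts, AID-biased SHM and ground truth, and
`evaluate_recovery()` scores sensitivity, precision and donor accuracy.

## Worked example

```r
library(igconvert)

cfg <- sim_config(n_reads = 300, shm_rate = 0,
                  tract_len_range = c(10L, 25L), seed = 17)
sim <- simulate_repertoire(cfg)
sim$locus$set
#> germline_set: 15 records; 5 functional genes, 10 pseudogenes; 0 gene(s) missing from the order table

events <- gene_order_filter(detect_repertoire(sim$reads, sim$locus$set),
                            sim$locus$set)
events <- annotate_events(events, sim$locus$set, sim$reads)
events[1:3, c("sequence_id", "gc_acceptor", "gc_donor", "gc_block_start",
              "gc_block_end", "gc_lev_distance",
              "gc_five_prime_identical_len", "gc_expanded_length")]
#>   sequence_id gc_acceptor gc_donor gc_block_start gc_block_end gc_lev_distance
#> 1  read000007    IGHV1-24 IGHV1-44            215          225               0
#> 2  read000029    IGHV1-21 IGHV1-41             70           93               0
#> 3  read000045    IGHV1-21 IGHV1-41            161          183               0
#>   gc_five_prime_identical_len gc_expanded_length
#> 1                           6                 29
#> 2                          24                 49
#> 3                           9                 34

rec <- evaluate_recovery(sim$truth, events)
sprintf("sensitivity %.2f  precision %.2f  donor accuracy %.2f",
        rec$sensitivity, rec$precision, rec$donor_accuracy)
#> [1] "sensitivity 1.00  precision 1.00  donor accuracy 1.00"

head(donor_acceptor_matrix(events), 3)
#>      donor acceptor count
#> 1 IGHV1-44 IGHV1-24    10
#> 2 IGHV1-41 IGHV1-21     7
#> 3 IGHV2-42 IGHV2-22     4
```

Each event row reads: in `read000007` (assigned to functional gene
IGHV1-24) the columns [215, 225) mismatch the germline but exactly match a
segment of pseudogene IGHV1-44 (edit distance 0); 6 identical nucleotides
flank it 5′, so the inferred conversion tract (the expanded event) spans
29 nt. Recovery of 1.00/1.00/1.00 means every implanted tract was found,
no spurious event was called, and every donor was attributed correctly.

A thin CLI wraps the same functions:

```sh
Rscript exec/igconvert simulate --seed 5 --out-dir sim/
Rscript exec/igconvert detect --germline sim/germline.fasta \
    --order sim/order.tsv --repertoire sim/repertoire.tsv --out events.tsv
# sequences: 1000  detected events: 113  after order filter: 112  GC+ sequences: 109  %GC: 10.90
```

## Layout

* `R/`, `src/` — implementation (Rcpp for the alignment primitives)
* `exec/igconvert` — command-line front end
* `vignettes/gene-conversion-detection.Rmd` — methods: model, parameters,
  simulator design, numerical conventions, limitations
* `tests/testthat/` — unit, property and oracle-equivalence tests
* `scripts/acceptance.R` — end-to-end reproduction script
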