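Package: igconvert
Title: Detection and Characterization of Gene Conversion in
    Immunoglobulin Heavy-Chain V Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate gene-conversion events in annotated
    immunoglobulin heavy-chain V (IGHV) repertoires by locating contiguous
    mismatch blocks between repertoire sequences and their assigned
    functional germline genes, attributing each block to a candidate
    pseudogene donor by edit distance, and filtering attributions with a
    genomic gene-order constraint (donor pseudogene 5' of the acceptor).
    Events are characterized by flanking identity to the donor, expanded
    extents, proximity to and overlap with AID hotspot motifs (WRCY, RGYW,
    TW, WA), and non-B DNA motif context (direct/inverted/mirror repeats,
    short tandem repeats, G-quadruplex, Z-DNA, A-phased repeats).
    Repertoire-level summaries include per-sample pipeline accounting with
    percent converted sequences, family and gene usage, donor-acceptor
    matrices, and flank-window export for motif discovery. A synthetic-data
    module simulates germline loci and repertoires with implanted
    conversion tracts, AID-biased somatic hypermutation and ground truth,
    and scores detection recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
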