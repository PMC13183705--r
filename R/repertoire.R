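#' Read a FASTQ file into a quality-read table
#'
#' Loads Sanger Phred+33 FASTQ into the data.frame layout consumed by
#' [quality_filter()]: one row per read with `read_id`, `seq` and `qual`
#' (the raw quality string). Merged-overlap coordinates, when known, can be
#' attached afterwards as `overlap_start` / `overlap_end` (0-based,
#' half-open).
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq_reads <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE, row.names = NULL)
}

phred_scores <- function(qual) as.integer(charToRaw(qual)) - 33L

#' Phred quality filter with separate overlap and end thresholds
#'
#' A read passes when every base inside its merged-overlap interval has
#' quality >= `overlap_min` and every base outside it has quality >=
#' `end_min`. Reads without `overlap_start`/`overlap_end` columns (or with
#' `NA` there) use a default central interval `[trim, len - trim)`; when
#' `2 * trim >= len` the interval is empty and only `end_min` applies.
#' Reads whose quality string length differs from the sequence length are
#' rejected individually (reason `"length_mismatch"`), never aborting the
#' stream. Filtering is order-preserving and idempotent.
#'
#' @param reads data.frame from [read_fastq_reads()], optionally with
#'   `overlap_start`/`overlap_end` (0-based half-open).
#' @param overlap_min,end_min Phred thresholds (defaults 30 and 20).
#' @param trim Default end width defining the central overlap interval when
#'   none is supplied (default 50 nt).
#' @return The passing rows, in input order, with attribute `counts`
#'   (named vector: `pass`, `fail`) and attribute `fail_reasons` (character
#'   vector naming why each failing read was dropped).
#' @export
quality_filter <- function(reads, overlap_min = 30, end_min = 20, trim = 50) {
    stopifnot(overlap_min >= end_min, end_min >= 0)
    n <- nrow(reads)
    pass <- logical(n)
    reason <- character(n)
    has_iv <- all(c("overlap_start", "overlap_end") %in% names(reads))
    for (i in seq_len(n)) {
        sq <- reads$seq[i]
        ql <- reads$qual[i]
        if (nchar(ql) != nchar(sq)) {
            reason[i] <- "length_mismatch"
            next
        }
        q <- phred_scores(ql)
        len <- length(q)
        if (has_iv && !is.na(reads$overlap_start[i]) && !is.na(reads$overlap_end[i])) {
            s <- reads$overlap_start[i]; e <- reads$overlap_end[i]
        } else {
            s <- min(trim, len); e <- max(len - trim, s)
        }
        inside <- seq_len(len) > s & seq_len(len) <= e
        ok <- all(q[inside] >= overlap_min) && all(q[!inside] >= end_min)
        if (ok) pass[i] <- TRUE else reason[i] <- "low_quality"
    }
    out <- reads[pass, , drop = FALSE]
    row.names(out) <- NULL
    attr(out, "counts") <- c(pass = sum(pass), fail = sum(!pass))
    attr(out, "fail_reasons") <- reason[!pass]
    out
}

#' Collapse annotated reads to unique productive sequences
#'
#' Drops non-productive records, then keeps one record per distinct
#' (`sample_id`, `sequence`) pair with `duplicate_count` set to the number
#' of reads collapsed into it. Uniqueness is on the exact gapped sequence
#' string, per sample. The sum of `duplicate_count` over the output equals
#' the number of productive input records in each sample.
#'
#' @param reads data.frame with columns `sequence_id`, `sample_id`,
#'   `sequence`, `v_call`, `productive` (logical or "T"/"F"/"TRUE"/"FALSE").
#' @return data.frame of unique productive records (first-seen
#'   representative per group) with `duplicate_count`; attribute
#'   `unique_per_sample` holds the per-sample output counts.
#' @export
collapse_unique <- function(reads) {
    prod <- reads$productive
    if (!is.logical(prod)) prod <- toupper(as.character(prod)) %in% c("T", "TRUE")
    reads <- reads[prod, , drop = FALSE]
    if (nrow(reads) == 0L) {
        out <- reads
        out$duplicate_count <- integer(0)
        attr(out, "unique_per_sample") <- integer(0)
        return(out)
    }
    key <- paste(reads$sample_id, reads$sequence, sep = "\r")
    first <- !duplicated(key)
    out <- reads[first, , drop = FALSE]
    out$duplicate_count <- as.integer(table(key)[key[first]])
    row.names(out) <- NULL
    attr(out, "unique_per_sample") <- table(out$sample_id)
    out
}

#' Assign the closest functional germline gene to a read
#'
#' Plumbing stand-in for a full V-annotation tool, used to annotate
#' synthetic reads: returns the functional gene/allele with maximal
#' [pairwise_identity()] to the read. Ties are broken deterministically by
#' lexicographically smaller name (then allele).
#'
#' @param read_seq Nucleotide string (IMGT gaps allowed; they are removed
#'   before alignment).
#' @param set A `germline_set`.
#' @return list with `v_call` (name + allele when present) and `identity`.
#' @export
assign_functional_gene <- function(read_seq, set) {
    g <- set$genes[set$genes$functionality == "F", , drop = FALSE]
    if (nrow(g) == 0L) stop("empty functional gene set")
    ids <- vapply(g$ungapped_seq, function(s) pairwise_identity(read_seq, s),
                  numeric(1), USE.NAMES = FALSE)
    lab <- paste0(g$name, ifelse(is.na(g$allele), "", g$allele))
    ord <- order(-ids, lab)
    list(v_call = lab[ord[1L]], identity = ids[ord[1L]])
}

# ---- event table I/O --------------------------------------------------------

EVENT_MANDATORY_COLS <- c("sequence_id", "gc_acceptor", "gc_donor",
                          "gc_block_start", "gc_block_end", "gc_lev_distance")

EVENT_INT_COLS <- c("gc_block_start", "gc_block_end", "gc_block_start_ungapped",
                    "gc_block_length", "gc_donor_offset", "gc_donor_length",
                    "gc_lev_distance", "gc_five_prime_identical_len",
                    "gc_three_prime_identical_len", "gc_expanded_start",
                    "gc_expanded_end", "gc_expanded_length", "gc_aid_distance")

EVENT_LGL_COLS <- c("gc_passed_order_filter")

#' Write / read gene-conversion event tables
#'
#' Events are stored as AIRR-style tab-separated text: standard columns
#' (`sequence_id`, `sample_id`, `v_call`) plus tool-specific columns
#' prefixed `gc_`. Coordinates are 0-based half-open; block coordinates
#' live in IMGT-gapped acceptor columns, `gc_donor_offset` in the donor's
#' ungapped sequence. The round trip `write_events()` then `read_events()`
#' reproduces all fields exactly; unknown columns are preserved.
#'
#' @param events data.frame of events (one row per event).
#' @param path Output/input TSV path.
#' @return `read_events()` returns the event data.frame; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
    utils::write.table(events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
    ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    missing <- setdiff(EVENT_MANDATORY_COLS, names(ev))
    if (length(missing) > 0L)
        stop("event table is missing mandatory column(s): ",
             paste(missing, collapse = ", "))
    for (cl in intersect(EVENT_INT_COLS, names(ev)))
        ev[[cl]] <- as.integer(ev[[cl]])
    for (cl in intersect(EVENT_LGL_COLS, names(ev)))
        ev[[cl]] <- as.logical(ev[[cl]])
    ev
}
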