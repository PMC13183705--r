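#' Levenshtein (unit-cost edit) distance
#'
#' Standard edit distance with unit costs for substitution, insertion and
#' deletion; symmetric, and 0 exactly when the strings are equal.
#'
#' @param a,b Character scalars.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) cpp_levenshtein(a, b)

#' Detection parameters
#'
#' @param min_block_len Minimum mismatch-block length in nucleotides
#'   (default 3, the smallest event size considered).
#' @param merge_gap Runs of mismatches separated by at most this many
#'   non-mismatching columns are merged into one block (default 0: pure
#'   consecutive-mismatch runs).
#' @param max_lev Maximum edit distance between a block and its donor
#'   segment for a donor attribution to be accepted (default 1).
#' @param flank_w Flank width (nt) used in the donor tie-break (default 6).
#' @param seed_len k-mer seed length for the seeded donor scan (default 8);
#'   seeding is used only for blocks long enough that the pigeonhole
#'   guarantee holds, and always returns the same result as the exhaustive
#'   scan.
#' @return list of class `detect_config`.
#' @export
detect_config <- function(min_block_len = 3L, merge_gap = 0L, max_lev = 1L,
                          flank_w = 6L, seed_len = 8L) {
    stopifnot(min_block_len >= 1, merge_gap >= 0, max_lev >= 0, flank_w >= 0,
              seed_len >= 1)
    structure(list(min_block_len = as.integer(min_block_len),
                   merge_gap = as.integer(merge_gap),
                   max_lev = as.integer(max_lev),
                   flank_w = as.integer(flank_w),
                   seed_len = as.integer(seed_len)),
              class = "detect_config")
}

#' Extract maximal mismatch blocks between a read and its germline
#'
#' Compares a repertoire sequence with its assigned functional germline in
#' shared IMGT-gapped coordinates and returns maximal runs of consecutive
#' mismatching columns. Columns where either sequence carries `.` (IMGT
#' gap) or `N` are neutral: they never mismatch, and they terminate runs
#' unless `merge_gap` absorbs them. Runs separated by at most `merge_gap`
#' non-mismatching columns are merged; blocks shorter than `min_block_len`
#' (counted over columns where both sequences have a base) are discarded.
#'
#' @param read_gapped,germ_gapped Equal-length IMGT-gapped sequences.
#' @param min_block_len,merge_gap See [detect_config()].
#' @param read_id Used in error messages.
#' @return data.frame with 0-based half-open gapped coordinates `start`,
#'   `end`, ungapped read coordinates `start_ungapped`, `end_ungapped`,
#'   `length` (non-gap columns) and `read_subseq` (the read's bases in the
#'   block).
#' @export
extract_mismatch_blocks <- function(read_gapped, germ_gapped,
                                    min_block_len = 3L, merge_gap = 0L,
                                    read_id = NULL) {
    r <- seq_chars(toupper(read_gapped))
    g <- seq_chars(toupper(germ_gapped))
    if (length(r) != length(g))
        stop("read", if (!is.null(read_id)) paste0(" '", read_id, "'"),
             " and germline differ in gapped length (", length(r), " vs ",
             length(g), ")")
    neutral <- r == "." | g == "." | r == "N" | g == "N"
    mism <- !neutral & r != g
    non_gap <- r != "." & g != "."
    read_base <- r != "."

    empty <- data.frame(start = integer(0), end = integer(0),
                        start_ungapped = integer(0), end_ungapped = integer(0),
                        length = integer(0), read_subseq = character(0),
                        stringsAsFactors = FALSE)
    if (!any(mism)) return(empty)

    rl <- rle(mism)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    runs <- data.frame(start = starts[rl$values], end = ends[rl$values])
    # merge runs separated by <= merge_gap non-mismatching columns
    if (nrow(runs) > 1L && merge_gap > 0L) {
        keep_start <- runs$start[1L]
        merged <- list()
        cur_end <- runs$end[1L]
        for (k in 2L:nrow(runs)) {
            if (runs$start[k] - cur_end - 1L <= merge_gap) {
                cur_end <- runs$end[k]
            } else {
                merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
                keep_start <- runs$start[k]
                cur_end <- runs$end[k]
            }
        }
        merged[[length(merged) + 1L]] <- c(keep_start, cur_end)
        runs <- data.frame(start = vapply(merged, `[`, 0, 1L),
                           end = vapply(merged, `[`, 0, 2L))
    }

    ung_before <- c(0L, cumsum(read_base))  # ungapped read pos before column i
    out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
        s <- runs$start[k]; e <- runs$end[k]   # 1-based inclusive columns
        len <- sum(non_gap[s:e])
        data.frame(start = s - 1L, end = e,
                   start_ungapped = ung_before[s],
                   end_ungapped = ung_before[e + 1L],
                   length = len,
                   read_subseq = paste(r[s:e][read_base[s:e]], collapse = ""),
                   stringsAsFactors = FALSE)
    }))
    out <- out[out$length >= min_block_len, , drop = FALSE]
    row.names(out) <- NULL
    if (nrow(out) == 0L) empty else out
}

# flank identity of a donor segment against the read context:
# consecutive identical nt immediately outside the block/segment, walking
# outward, capped at `w` per side
donor_flank_score <- function(read_ungapped, block_s, block_e,
                              donor_seq, off, seg_len, w) {
    rch <- seq_chars(read_ungapped)
    dch <- seq_chars(donor_seq)
    five <- 0L
    while (five < w && block_s - five >= 1L && off - five >= 1L &&
           rch[block_s - five] == dch[off - five] &&
           rch[block_s - five] != "N") five <- five + 1L
    three <- 0L
    while (three < w && block_e + 1L + three <= length(rch) &&
           off + seg_len + 1L + three <= length(dch) &&
           rch[block_e + 1L + three] == dch[off + seg_len + 1L + three] &&
           rch[block_e + 1L + three] != "N") three <- three + 1L
    five + three
}

#' Attribute a mismatch block to a candidate pseudogene donor
#'
#' Scans every pseudogene's ungapped sequence for the segment minimizing
#' the edit distance to the block's read sequence and returns the best hit
#' when that distance is at most `max_lev`, otherwise `NULL`. Ties between
#' minimal-distance segments are broken by (1) greater combined 5'+3'
#' flanking identity against the read context (width `flank_w` per side),
#' (2) smaller absolute difference between the donor offset and the block's
#' ungapped start, (3) lexicographically smaller donor name, then donor
#' offset and segment length. For blocks of at least 18 nt (and long enough
#' for the pigeonhole bound `len >= seed_len * (max_lev + 1)`), a
#' seed-and-extend search is used; its result equals the exhaustive scan.
#'
#' @param block One row from [extract_mismatch_blocks()].
#' @param read_ungapped The read sequence with gaps removed.
#' @param set A `germline_set` (donors are its pseudogenes).
#' @param config A [detect_config()].
#' @return list(`donor_name`, `donor_offset` (0-based, donor-ungapped),
#'   `donor_length`, `lev_distance`) or `NULL` when no segment is within
#'   `max_lev`.
#' @export
search_donor <- function(block, read_ungapped, set, config = detect_config()) {
    pseudos <- set$genes[set$genes$name %in% set$pseudogene_names, , drop = FALSE]
    if (nrow(pseudos) == 0L) stop("empty pseudogene set")
    subseq <- block$read_subseq
    m <- nchar(subseq)
    use_seed <- m >= 18L && m >= config$seed_len * (config$max_lev + 1L)
    cand <- list()
    for (i in seq_len(nrow(pseudos))) {
        dseq <- pseudos$ungapped_seq[i]
        hits <- if (use_seed)
            cpp_scan_segments_seeded(subseq, dseq, config$max_lev, config$seed_len)
        else cpp_scan_segments(subseq, dseq, config$max_lev)
        if (nrow(hits) > 0L)
            cand[[length(cand) + 1L]] <-
                data.frame(donor_name = pseudos$name[i],
                           offset = hits[, "offset"], length = hits[, "length"],
                           dist = hits[, "dist"], stringsAsFactors = FALSE)
    }
    if (length(cand) == 0L) return(NULL)
    cand <- do.call(rbind, cand)
    cand <- cand[cand$dist == min(cand$dist), , drop = FALSE]
    bs <- block$start_ungapped  # 0-based
    # flank score per candidate (donor records of one gene share the name;
    # use the first record of that gene for context, matching the scan above)
    cand$flank <- vapply(seq_len(nrow(cand)), function(k) {
        dseq <- pseudos$ungapped_seq[match(cand$donor_name[k], pseudos$name)]
        donor_flank_score(read_ungapped, bs, bs + (block$end_ungapped - block$start_ungapped),
                          dseq, cand$offset[k], cand$length[k], config$flank_w)
    }, integer(1))
    ord <- order(-cand$flank, abs(cand$offset - bs), cand$donor_name,
                 cand$offset, cand$length)
    best <- cand[ord[1L], ]
    list(donor_name = best$donor_name, donor_offset = best$offset,
         donor_length = best$length, lev_distance = best$dist)
}

#' Detect candidate gene-conversion events in one read
#'
#' Composition of [extract_mismatch_blocks()] and [search_donor()]: every
#' maximal mismatch block against the assigned functional germline is
#' scanned against all pseudogenes, blocks without a donor hit within
#' `max_lev` are dropped, and one event is emitted per (block, best donor).
#' A read is GC+ when at least one of its events survives all filters.
#' Detection depends only on the sequence, never on `duplicate_count`.
#'
#' @param read One-row data.frame (or list) with `sequence_id`, `sequence`
#'   (IMGT-gapped), `v_call` and optionally `sample_id`.
#' @param set A `germline_set`.
#' @param config A [detect_config()].
#' @return Event data.frame (possibly 0-row); see [write_events()] for the
#'   column conventions.
#' @export
detect_events <- function(read, set, config = detect_config()) {
    v_call <- as.character(read$v_call)
    acceptor <- sub("\\*.*$", "", v_call)
    allele <- if (grepl("*", v_call, fixed = TRUE))
        sub("^[^*]*", "", v_call) else NULL
    g <- set$genes
    hit <- if (!is.null(allele)) {
        h <- which(g$name == acceptor & !is.na(g$allele) & g$allele == allele)
        if (length(h) == 0L) which(g$name == acceptor) else h
    } else which(g$name == acceptor)
    if (length(hit) == 0L)
        stop("v_call '", v_call, "' not in germline set; known genes: ",
             paste(unique(g$name), collapse = ", "))
    germ <- g[hit[1L], ]
    read_gapped <- toupper(as.character(read$sequence))
    blocks <- extract_mismatch_blocks(read_gapped, germ$gapped_seq,
                                      config$min_block_len, config$merge_gap,
                                      read_id = read$sequence_id)
    events <- empty_events()
    if (nrow(blocks) == 0L) return(events)
    read_ungapped <- gsub(".", "", read_gapped, fixed = TRUE)
    rows <- lapply(seq_len(nrow(blocks)), function(k) {
        b <- blocks[k, ]
        hit <- search_donor(b, read_ungapped, set, config)
        if (is.null(hit)) return(NULL)
        data.frame(sequence_id = as.character(read$sequence_id),
                   sample_id = if (!is.null(read$sample_id))
                       as.character(read$sample_id) else NA_character_,
                   v_call = v_call,
                   gc_acceptor = acceptor,
                   gc_donor = hit$donor_name,
                   gc_block_start = b$start, gc_block_end = b$end,
                   gc_block_start_ungapped = b$start_ungapped,
                   gc_block_length = b$length,
                   gc_read_subseq = b$read_subseq,
                   gc_donor_offset = hit$donor_offset,
                   gc_donor_length = hit$donor_length,
                   gc_lev_distance = hit$lev_distance,
                   gc_passed_order_filter = NA,
                   gc_five_prime_identical_len = NA_integer_,
                   gc_three_prime_identical_len = NA_integer_,
                   gc_expanded_start = NA_integer_,
                   gc_expanded_end = NA_integer_,
                   gc_expanded_length = NA_integer_,
                   gc_aid_distance = NA_integer_,
                   gc_hotspot_overlap = NA_character_,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(events)
    out <- do.call(rbind, rows)
    row.names(out) <- NULL
    out
}

empty_events <- function() {
    data.frame(sequence_id = character(0), sample_id = character(0),
               v_call = character(0), gc_acceptor = character(0),
               gc_donor = character(0), gc_block_start = integer(0),
               gc_block_end = integer(0), gc_block_start_ungapped = integer(0),
               gc_block_length = integer(0), gc_read_subseq = character(0),
               gc_donor_offset = integer(0), gc_donor_length = integer(0),
               gc_lev_distance = integer(0), gc_passed_order_filter = logical(0),
               gc_five_prime_identical_len = integer(0),
               gc_three_prime_identical_len = integer(0),
               gc_expanded_start = integer(0), gc_expanded_end = integer(0),
               gc_expanded_length = integer(0), gc_aid_distance = integer(0),
               gc_hotspot_overlap = character(0), stringsAsFactors = FALSE)
}

#' Detect events across a repertoire table
#'
#' Applies [detect_events()] to every row of an annotated-read table and
#' binds the results.
#'
#' @param reads data.frame with `sequence_id`, `sequence`, `v_call`,
#'   optional `sample_id`.
#' @inheritParams detect_events
#' @return Combined event data.frame.
#' @export
detect_repertoire <- function(reads, set, config = detect_config()) {
    out <- lapply(seq_len(nrow(reads)), function(i)
        detect_events(reads[i, , drop = FALSE], set, config))
    out <- do.call(rbind, out)
    if (is.null(out)) empty_events() else out
}

#' Genomic gene-order filter
#'
#' Keeps exactly the events whose donor pseudogene lies 5' (strictly
#' smaller locus rank) of the acceptor functional gene; events with a donor
#' located 3' of the acceptor are excluded, as are events whose donor or
#' acceptor has no order-table entry (counted separately). Idempotent.
#'
#' @param events Event data.frame.
#' @param set A `germline_set` (its `order` table supplies the ranks).
#' @return The retained events with `gc_passed_order_filter = TRUE`;
#'   attribute `removed` holds the counts of excluded events
#'   (`downstream_donor`, `unresolved_rank`).
#' @export
gene_order_filter <- function(events, set) {
    if (nrow(events) == 0L) {
        attr(events, "removed") <- c(downstream_donor = 0L, unresolved_rank = 0L)
        return(events)
    }
    dr <- gene_rank(set, events$gc_donor)
    ar <- gene_rank(set, events$gc_acceptor)
    unresolved <- is.na(dr) | is.na(ar)
    keep <- !unresolved & dr < ar
    out <- events[keep, , drop = FALSE]
    if (nrow(out) > 0L) out$gc_passed_order_filter <- TRUE
    row.names(out) <- NULL
    attr(out, "removed") <- c(downstream_donor = sum(!keep & !unresolved),
                              unresolved_rank = sum(unresolved))
    out
}
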