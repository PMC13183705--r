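#' Flanking identity between acceptor and donor around an event
#'
#' Walks outward from the mismatch block in the donor-anchored alignment
#' implied by `gc_donor_offset`: `five_len` is the number of consecutive
#' positions immediately 5' of the block where the acceptor and donor
#' nucleotides are identical, `three_len` the same at the 3' side. Both are
#' capped only by the available sequence. These identical flanks are the
#' sequence-homology tracts over which a conversion event may extend beyond
#' its observable mismatches.
#'
#' @param event One event row (needs `gc_block_start_ungapped`,
#'   `gc_read_subseq`, `gc_donor_offset`, `gc_donor_length`).
#' @param acceptor,donor Gene records (rows of `germline_set$genes`).
#' @return list(`five_len`, `three_len`), both integers >= 0.
#' @export
flanking_identity <- function(event, acceptor, donor) {
    a <- seq_chars(acceptor$ungapped_seq[[1L]])
    d <- seq_chars(donor$ungapped_seq[[1L]])
    off <- event$gc_donor_offset       # 0-based
    seg_len <- event$gc_donor_length
    if (is.na(off) || off < 0L || off + seg_len > length(d))
        stop("donor offset out of donor bounds (offset ", off,
             ", segment length ", seg_len, ", donor length ", length(d), ")")
    bs <- event$gc_block_start_ungapped
    be <- bs + nchar(event$gc_read_subseq)
    five <- 0L
    while (bs - five >= 1L && off - five >= 1L &&
           a[bs - five] == d[off - five] && a[bs - five] != "N")
        five <- five + 1L
    three <- 0L
    while (be + 1L + three <= length(a) &&
           off + seg_len + 1L + three <= length(d) &&
           a[be + 1L + three] == d[off + seg_len + 1L + three] &&
           a[be + 1L + three] != "N")
        three <- three + 1L
    list(five_len = five, three_len = three)
}

#' Expanded extent of an event
#'
#' Extends the mismatch block by its identical 5' and 3' flanks: the
#' expanded interval is the inferred minimal extent of the conversion
#' tract. Lengths are counted over non-gap columns, and the interval is
#' clamped to the sequence bounds, so `expanded_len >= block length`
#' always holds.
#'
#' @param event One event row with `gc_five_prime_identical_len` and
#'   `gc_three_prime_identical_len` filled (see [flanking_identity()]).
#' @param acceptor Acceptor gene record (maps ungapped positions back to
#'   IMGT-gapped columns).
#' @return list(`expanded_start`, `expanded_end` (gapped columns, 0-based
#'   half-open), `expanded_start_ungapped`, `expanded_end_ungapped`,
#'   `expanded_len`).
#' @export
expanded_event <- function(event, acceptor) {
    five <- event$gc_five_prime_identical_len
    three <- event$gc_three_prime_identical_len
    if (is.na(five) || is.na(three))
        stop("flanking identity must be computed before expanded_event()")
    g <- seq_chars(acceptor$gapped_seq[[1L]])
    base_cols <- which(g != ".")
    n_u <- length(base_cols)
    bs <- event$gc_block_start_ungapped
    be <- bs + nchar(event$gc_read_subseq)
    es <- max(0L, bs - five)
    ee <- min(n_u, be + three)
    gs <- if (n_u == 0L) 0L else base_cols[es + 1L] - 1L
    ge <- if (ee == 0L) 0L else base_cols[ee]
    list(expanded_start = gs, expanded_end = ge,
         expanded_start_ungapped = es, expanded_end_ungapped = ee,
         expanded_len = ee - es)
}

AID_PATTERNS <- c(WRCY = "[AT][AG]C[CT]", RGYW = "[AG]G[CT][AT]",
                  TW = "T[AT]", WA = "[AT]A")

revcomp <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(seq_chars(x)), collapse = ""))
}

#' Scan a sequence for AID hotspot motifs
#'
#' Finds every occurrence (overlapping occurrences included) of the AID
#' target motifs WRCY `[AT][AG]C[CT]`, RGYW `[AG]G[CT][AT]`, TW `T[AT]` and
#' WA `[AT]A` on the coding strand. Gap columns (`.`) are skipped during
#' matching but coordinates are reported in the gapped frame, so motif and
#' event coordinates share one system. `N` never matches. Reverse-strand
#' scanning is available behind `both_strands`.
#'
#' @param seq Nucleotide string over A,C,G,T,N,`.`.
#' @param classes Which motif classes to scan (default all four).
#' @param both_strands Also scan the reverse complement and report
#'   occurrences in plus-strand coordinates (default `FALSE`).
#' @return data.frame with `motif_class`, `start`, `end` (0-based
#'   half-open, gapped coordinates) and `strand`.
#' @export
scan_aid_motifs <- function(seq, classes = names(AID_PATTERNS),
                            both_strands = FALSE) {
    seq <- toupper(seq)
    ch <- seq_chars(seq)
    base_cols <- which(ch != ".")
    ung <- paste(ch[base_cols], collapse = "")
    out <- scan_iupac(ung, classes, base_cols, "+")
    if (both_strands) {
        rc <- revcomp(ung)
        hits <- scan_iupac(rc, classes, seq_along(seq_chars(rc)), "-")
        if (nrow(hits) > 0L) {
            n <- nchar(rc)
            s <- n - hits$end      # map back to plus-strand ungapped 0-based
            e <- n - hits$start
            hits$start <- base_cols[s + 1L] - 1L
            hits$end <- base_cols[e]
            out <- rbind(out, hits)
        }
    }
    out <- out[order(out$start, out$end, out$motif_class), , drop = FALSE]
    row.names(out) <- NULL
    out
}

scan_iupac <- function(ungapped, classes, base_cols, strand) {
    res <- lapply(classes, function(cl) {
        pat <- AID_PATTERNS[[cl]]
        w <- nchar(gsub("\\[[^]]*\\]", "x", pat))
        m <- gregexpr(paste0("(?=", pat, ")"), ungapped, perl = TRUE)[[1L]]
        if (m[1L] == -1L) return(NULL)
        s <- as.integer(m)                 # 1-based ungapped starts
        data.frame(motif_class = cl,
                   start = base_cols[s] - 1L,
                   end = base_cols[s + w - 1L],
                   strand = strand, stringsAsFactors = FALSE)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res) == 0L)
        return(data.frame(motif_class = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, res)
}

#' Distance from an event to the nearest AID motif
#'
#' 0 when any motif interval intersects the block. Otherwise, under the
#' default `"adjacent1"` convention, an immediately adjacent motif is 1
#' nucleotide away and the distance is one plus the number of nucleotides
#' strictly between the nearest boundaries. `convention = "gap"` counts
#' only the intervening nucleotides (touching motifs give 0). Returns `NA`
#' when no motif exists.
#'
#' @param event One event row (gapped block coordinates).
#' @param motifs data.frame from [scan_aid_motifs()] on the same sequence.
#' @param convention `"adjacent1"` (default) or `"gap"`.
#' @return Integer distance in nucleotides, or `NA_integer_`.
#' @export
nearest_aid_distance <- function(event, motifs,
                                 convention = c("adjacent1", "gap")) {
    convention <- match.arg(convention)
    if (nrow(motifs) == 0L) return(NA_integer_)
    s <- event$gc_block_start
    e <- event$gc_block_end
    gap <- ifelse(motifs$end <= s, s - motifs$end,
                  ifelse(motifs$start >= e, motifs$start - e, -1L))
    d <- ifelse(gap < 0L, 0L, gap + if (convention == "adjacent1") 1L else 0L)
    as.integer(min(d))
}

#' Overlap category between an event and AID hotspot motifs
#'
#' `"full"` when the event is entirely contained within some hotspot
#' motif, `"partial"` when some hotspot intersects the block without
#' containing it, `"none"` otherwise. The three categories partition all
#' events.
#'
#' @inheritParams nearest_aid_distance
#' @param hotspots data.frame of motif occurrences (`start`, `end`).
#' @return One of `"full"`, `"partial"`, `"none"`.
#' @export
hotspot_overlap_category <- function(event, hotspots) {
    s <- event$gc_block_start
    e <- event$gc_block_end
    if (nrow(hotspots) > 0L) {
        if (any(hotspots$start <= s & e <= hotspots$end)) return("full")
        if (any(hotspots$start < e & hotspots$end > s)) return("partial")
    }
    "none"
}

#' Positional event-inclusion profile
#'
#' Over the range from the minimum event start to the maximum event end,
#' counts at each position how many events contain it and converts the
#' count to a percentage. The denominator is the number of events by
#' default; `denominator = "sequences"` divides by `n_sequences` instead
#' (the choice is recorded in the result's attributes).
#'
#' @param events Event data.frame (gapped block coordinates).
#' @param denominator `"events"` (default) or `"sequences"`.
#' @param n_sequences Number of sequences, required for
#'   `denominator = "sequences"`.
#' @return data.frame with `position` (0-based) and `percentage` in
#'   \[0, 100\]; empty when no events. Attribute `denominator` records the
#'   choice and value.
#' @export
positional_event_percentage <- function(events,
                                        denominator = c("events", "sequences"),
                                        n_sequences = NULL) {
    denominator <- match.arg(denominator)
    if (nrow(events) == 0L) {
        out <- data.frame(position = integer(0), percentage = numeric(0))
        attr(out, "denominator") <- c(kind = denominator, value = 0)
        return(out)
    }
    denom <- if (denominator == "events") nrow(events) else {
        stopifnot(!is.null(n_sequences), n_sequences >= 1)
        n_sequences
    }
    lo <- min(events$gc_block_start)
    hi <- max(events$gc_block_end) - 1L
    pos <- lo:hi
    cnt <- vapply(pos, function(p)
        sum(events$gc_block_start <= p & p < events$gc_block_end), integer(1))
    out <- data.frame(position = pos, percentage = 100 * cnt / denom)
    attr(out, "denominator") <- c(kind = denominator, value = denom)
    out
}

#' Signed offsets of motifs relative to events
#'
#' For every (event, motif occurrence) pair on the same sequence, the
#' offset `motif start - block start`, suitable for histogramming motif
#' positions relative to conversion events.
#'
#' @param events Event data.frame (`sequence_id`, gapped block start).
#' @param motifs Motif data.frame with `sequence_id`, `motif_class`,
#'   `start`.
#' @return data.frame with `sequence_id`, `motif_class`, `offset`.
#' @export
motif_offsets <- function(events, motifs) {
    out <- merge(events[, c("sequence_id", "gc_block_start")],
                 motifs[, c("sequence_id", "motif_class", "start")],
                 by = "sequence_id")
    data.frame(sequence_id = out$sequence_id,
               motif_class = out$motif_class,
               offset = out$start - out$gc_block_start,
               stringsAsFactors = FALSE)
}

#' Annotate events with flanks, expanded extents and AID context
#'
#' Fills the characterization columns of an event table: flanking identity
#' against the attributed donor, expanded interval and length, distance to
#' the nearest AID motif and the hotspot-overlap category. AID motifs are
#' scanned on the read sequence when `reads` is supplied (matched by
#' `sequence_id`), otherwise on the acceptor germline.
#'
#' @param events Event data.frame from [detect_repertoire()].
#' @param set A `germline_set`.
#' @param reads Optional read table (`sequence_id`, `sequence`).
#' @param aid_classes Motif classes used for the AID annotations.
#' @return The event data.frame with `gc_five_prime_identical_len`,
#'   `gc_three_prime_identical_len`, `gc_expanded_*`, `gc_aid_distance`
#'   and `gc_hotspot_overlap` filled.
#' @export
annotate_events <- function(events, set, reads = NULL,
                            aid_classes = names(AID_PATTERNS)) {
    if (nrow(events) == 0L) return(events)
    seq_for <- function(ev) {
        if (!is.null(reads)) {
            i <- match(ev$sequence_id, reads$sequence_id)
            if (!is.na(i)) return(toupper(reads$sequence[i]))
        }
        get_gene(set, ev$gc_acceptor)$gapped_seq[[1L]]
    }
    motif_cache <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(events))) {
        ev <- events[k, , drop = FALSE]
        acc <- get_gene(set, ev$gc_acceptor)
        don <- get_gene(set, ev$gc_donor)
        fl <- flanking_identity(ev, acc, don)
        events$gc_five_prime_identical_len[k] <- fl$five_len
        events$gc_three_prime_identical_len[k] <- fl$three_len
        ev$gc_five_prime_identical_len <- fl$five_len
        ev$gc_three_prime_identical_len <- fl$three_len
        ex <- expanded_event(ev, acc)
        events$gc_expanded_start[k] <- ex$expanded_start
        events$gc_expanded_end[k] <- ex$expanded_end
        events$gc_expanded_length[k] <- ex$expanded_len
        sq <- seq_for(ev)
        key <- ev$sequence_id
        motifs <- get0(key, envir = motif_cache)
        if (is.null(motifs)) {
            motifs <- scan_aid_motifs(sq, aid_classes)
            assign(key, motifs, envir = motif_cache)
        }
        events$gc_aid_distance[k] <- nearest_aid_distance(ev, motifs)
        events$gc_hotspot_overlap[k] <- hotspot_overlap_category(ev, motifs)
    }
    events
}
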