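#' Per-sample pipeline accounting with percent converted sequences
#'
#' Builds the repertoire-level accounting table: one row per sample with
#' the pipeline stage counts and `pct_gc = 100 x n_filtered / n_unique`
#' rounded half-up to 2 decimals, plus a `mean` row (arithmetic mean of the
#' per-sample values) and a `total` row (column sums; its `pct_gc` is left
#' `NA` since the headline percentage is the mean of the per-sample
#' values). By default `n_filtered` counts GC+ unique sequences, i.e. the
#' percentage is the share of unique sequences carrying at least one
#' filtered event.
#'
#' @param counts data.frame with `sample_id`, `n_unique`, `n_filtered` and
#'   optionally `n_raw`, `n_preproc`, `n_quality`, `n_annotated`,
#'   `n_detected`.
#' @return data.frame of class `gc_accounting` with the per-sample rows
#'   followed by `mean` and `total` rows.
#' @export
gc_percentage_table <- function(counts) {
    req <- c("sample_id", "n_unique", "n_filtered")
    if (!all(req %in% names(counts)))
        stop("counts must have columns: ", paste(req, collapse = ", "))
    if (any(counts$n_unique == 0))
        stop("n_unique is 0 for sample '",
             counts$sample_id[counts$n_unique == 0][1],
             "': percentage undefined")
    num_cols <- intersect(c("n_raw", "n_preproc", "n_quality", "n_annotated",
                            "n_unique", "n_detected", "n_filtered"),
                          names(counts))
    out <- counts[, c("sample_id", num_cols), drop = FALSE]
    pct_raw <- 100 * out$n_filtered / out$n_unique
    out$pct_gc <- round_half_up(pct_raw, 2)
    mean_row <- c(list(sample_id = "mean"),
                  lapply(out[num_cols], mean),
                  list(pct_gc = round_half_up(mean(pct_raw), 2)))
    total_row <- c(list(sample_id = "total"),
                   lapply(out[num_cols], sum),
                   list(pct_gc = NA_real_))
    out <- rbind(out, as.data.frame(mean_row, stringsAsFactors = FALSE),
                 as.data.frame(total_row, stringsAsFactors = FALSE))
    row.names(out) <- NULL
    attr(out, "pct_gc_raw") <- pct_raw
    class(out) <- c("gc_accounting", "data.frame")
    out
}

#' @export
print.gc_accounting <- function(x, ...) {
    print.data.frame(x, row.names = FALSE, ...)
    invisible(x)
}

gene_family <- function(name) {
    if (any(!grepl("-", name)))
        stop("unparseable gene name (no family-localizer hyphen): '",
             name[!grepl("-", name)][1], "'")
    sub("-.*$", "", name)
}

#' Family and gene usage among conversion events
#'
#' Tabulates how often each gene family and each individual gene appears
#' among the events, separately for acceptors (functional genes) and
#' donors (pseudogenes). Percentages within each table sum to 100 up to
#' rounding.
#'
#' @param events Event data.frame with `gc_acceptor` and `gc_donor`.
#' @return list with data.frames `acceptor_family`, `acceptor_gene`,
#'   `donor_family`, `donor_gene`, each with `name`, `count`, `percent`.
#' @export
family_usage <- function(events) {
    tab <- function(x, by_family) {
        if (length(x) == 0L)
            return(data.frame(name = character(0), count = integer(0),
                              percent = numeric(0), stringsAsFactors = FALSE))
        if (by_family) x <- gene_family(x)
        t <- sort(table(x), decreasing = TRUE)
        data.frame(name = names(t), count = as.integer(t),
                   percent = 100 * as.integer(t) / length(x),
                   stringsAsFactors = FALSE)
    }
    list(acceptor_family = tab(events$gc_acceptor, TRUE),
         acceptor_gene = tab(events$gc_acceptor, FALSE),
         donor_family = tab(events$gc_donor, TRUE),
         donor_gene = tab(events$gc_donor, FALSE))
}

#' Donor-acceptor event matrix
#'
#' Counts events per ordered (donor pseudogene, acceptor functional gene)
#' pair, in the long format consumed by chord-diagram tools. The counts
#' sum to the number of events.
#'
#' @param events Event data.frame (normally after [gene_order_filter()]).
#' @return data.frame of class `donor_acceptor_matrix` with `donor`,
#'   `acceptor`, `count` (all counts >= 1).
#' @export
donor_acceptor_matrix <- function(events) {
    if (nrow(events) == 0L) {
        out <- data.frame(donor = character(0), acceptor = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
    } else {
        t <- as.data.frame(table(donor = events$gc_donor,
                                 acceptor = events$gc_acceptor),
                           stringsAsFactors = FALSE)
        t <- t[t$Freq > 0L, , drop = FALSE]
        out <- data.frame(donor = t$donor, acceptor = t$acceptor,
                          count = as.integer(t$Freq), stringsAsFactors = FALSE)
        out <- out[order(-out$count, out$donor, out$acceptor), , drop = FALSE]
        row.names(out) <- NULL
    }
    class(out) <- c("donor_acceptor_matrix", "data.frame")
    out
}

#' Extract flank windows around expanded events
#'
#' For each event, the `w` nucleotides of the read immediately 5' of the
#' expanded start and immediately 3' of the expanded end, as input for
#' external motif discovery. Windows truncated at a sequence boundary are
#' flagged; events whose expanded region begins at the first nucleotide
#' have no 5' window at all.
#'
#' @param events Annotated event data.frame (expanded coordinates filled).
#' @param reads Read table (`sequence_id`, `sequence`).
#' @param w Window width in nucleotides (default 10).
#' @param fasta_5p,fasta_3p Optional output FASTA paths; windows are
#'   written with headers `<sequence_id>|event<k>[|truncated]`.
#' @return data.frame with `sequence_id`, `five_window`, `five_truncated`,
#'   `three_window`, `three_truncated` (`NA` window when absent).
#' @export
extract_flank_windows <- function(events, reads, w = 10L,
                                  fasta_5p = NULL, fasta_3p = NULL) {
    stopifnot(w >= 1L)
    n <- nrow(events)
    five <- character(n); three <- character(n)
    five_tr <- logical(n); three_tr <- logical(n)
    for (k in seq_len(n)) {
        i <- match(events$sequence_id[k], reads$sequence_id)
        if (is.na(i)) stop("read not found for event sequence_id '",
                           events$sequence_id[k], "'")
        sq <- gsub(".", "", toupper(reads$sequence[i]), fixed = TRUE)
        ch <- seq_chars(sq)
        es <- events$gc_expanded_start[k]   # gapped == ungapped for gapless
        ee <- events$gc_expanded_end[k]
        gp <- grepl(".", reads$sequence[i], fixed = TRUE)
        if (gp) {
            cols <- which(seq_chars(toupper(reads$sequence[i])) != ".")
            es <- sum(cols <= es)
            ee <- sum(cols <= ee)
        }
        s5 <- max(0L, es - w)
        if (es <= 0L) {
            five[k] <- NA_character_; five_tr[k] <- TRUE
        } else {
            five[k] <- paste(ch[(s5 + 1L):es], collapse = "")
            five_tr[k] <- (es - s5) < w
        }
        e3 <- min(length(ch), ee + w)
        if (ee >= length(ch)) {
            three[k] <- NA_character_; three_tr[k] <- TRUE
        } else {
            three[k] <- paste(ch[(ee + 1L):e3], collapse = "")
            three_tr[k] <- (e3 - ee) < w
        }
    }
    out <- data.frame(sequence_id = events$sequence_id,
                      five_window = five, five_truncated = five_tr,
                      three_window = three, three_truncated = three_tr,
                      stringsAsFactors = FALSE)
    write_windows <- function(path, win, tr) {
        keep <- !is.na(win)
        hdr <- paste0(out$sequence_id[keep], "|event", which(keep),
                      ifelse(tr[keep], "|truncated", ""))
        x <- Biostrings::BStringSet(win[keep])
        names(x) <- hdr
        Biostrings::writeXStringSet(x, path)
    }
    if (!is.null(fasta_5p)) write_windows(fasta_5p, five, five_tr)
    if (!is.null(fasta_3p)) write_windows(fasta_3p, three, three_tr)
    out
}
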