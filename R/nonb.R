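#' Non-B DNA motif scan parameters
#'
#' Per-class thresholds for [scan_nonb_motifs()], modeled on the
#' conventions of standard non-B motif search tools. All lengths are in
#' nucleotides.
#'
#' @param dr_arm_min,dr_spacer_max Direct repeats: minimum arm length
#'   (default 10) and maximum spacer (default 10).
#' @param ir_arm_min,ir_spacer_max Inverted repeats: defaults 6 and 100.
#' @param mr_arm_min,mr_spacer_max Mirror repeats: defaults 10 and 100.
#' @param str_unit_max,str_min_copies,str_min_len Short tandem repeats:
#'   unit 1..9 nt, at least 3 copies, total tract at least 12 nt.
#' @param z_min Minimum length of an alternating purine-pyrimidine tract
#'   of GC/GT/AC steps (default 10).
#' @param apr_tract_min,apr_tract_max,apr_min_tracts,apr_period,apr_period_tol
#'   A-phased repeats: >= 3 A (or T) tracts of 3-9 nt whose centers repeat
#'   with ~10 nt periodicity (tolerance +/- 1).
#' @return list of class `nonb_params`.
#' @export
nonb_params <- function(dr_arm_min = 10L, dr_spacer_max = 10L,
                        ir_arm_min = 6L, ir_spacer_max = 100L,
                        mr_arm_min = 10L, mr_spacer_max = 100L,
                        str_unit_max = 9L, str_min_copies = 3L,
                        str_min_len = 12L,
                        z_min = 10L,
                        apr_tract_min = 3L, apr_tract_max = 9L,
                        apr_min_tracts = 3L, apr_period = 10L,
                        apr_period_tol = 1L) {
    if (dr_arm_min < 3L || ir_arm_min < 3L || mr_arm_min < 3L)
        stop("repeat arm_min must be >= 3")
    structure(as.list(environment()), class = "nonb_params")
}

#' Scan a sequence for non-B DNA-forming motifs
#'
#' Identifies occurrences of seven motif classes capable of non-canonical
#' DNA structures: direct repeats (`DR`, two identical arms with a short
#' spacer), inverted repeats (`IR`, reverse-complement arms), mirror
#' repeats (`MR`, reversed arms), short tandem repeats (`STR`),
#' G-quadruplex-forming runs (`GQ`, `G{3,}(N{1,7}G{3,}){3}`), Z-DNA tracts
#' (`Z`, alternating purine-pyrimidine of GC/GT/AC steps) and A-phased
#' repeats (`APR`, >= 3 A-tracts at ~10 nt periodicity). All occurrences
#' are maximal; overlaps within and across classes are allowed. `N` never
#' participates in a motif. Coordinates are 0-based half-open on the given
#' (ungapped) sequence.
#'
#' @param seq Nucleotide string over A,C,G,T,N.
#' @param params A [nonb_params()] list.
#' @param classes Subset of `c("DR","IR","MR","STR","GQ","Z","APR")`.
#' @return data.frame with `motif_class`, `start`, `end`; attribute
#'   `params` records the thresholds used.
#' @export
scan_nonb_motifs <- function(seq, params = nonb_params(),
                             classes = c("DR", "IR", "MR", "STR", "GQ",
                                         "Z", "APR")) {
    if (!inherits(params, "nonb_params")) stop("params must come from nonb_params()")
    seq <- toupper(seq)
    if (grepl(".", seq, fixed = TRUE))
        seq <- gsub(".", "", seq, fixed = TRUE)
    res <- list()
    add <- function(cl, s, e) {
        if (length(s) > 0L)
            res[[length(res) + 1L]] <<- data.frame(
                motif_class = cl, start = as.integer(s), end = as.integer(e),
                stringsAsFactors = FALSE)
    }
    rep_scan <- function(mode, arm_min, spacer_max) {
        m <- cpp_scan_repeats(seq, mode, arm_min, spacer_max)
        m[!duplicated(m[, c("start", "end"), drop = FALSE]), , drop = FALSE]
    }
    if ("DR" %in% classes) {
        m <- rep_scan(0L, params$dr_arm_min, params$dr_spacer_max)
        add("DR", m[, "start"], m[, "end"])
    }
    if ("IR" %in% classes) {
        m <- rep_scan(1L, params$ir_arm_min, params$ir_spacer_max)
        add("IR", m[, "start"], m[, "end"])
    }
    if ("MR" %in% classes) {
        m <- rep_scan(2L, params$mr_arm_min, params$mr_spacer_max)
        add("MR", m[, "start"], m[, "end"])
    }
    if ("STR" %in% classes) {
        m <- scan_str(seq, params$str_unit_max, params$str_min_copies,
                      params$str_min_len)
        add("STR", m$start, m$end)
    }
    if ("GQ" %in% classes) {
        m <- gregexpr("G{3,}(?:[ACGT]{1,7}?G{3,}){3}", seq, perl = TRUE)[[1L]]
        if (m[1L] != -1L)
            add("GQ", as.integer(m) - 1L,
                as.integer(m) - 1L + attr(m, "match.length"))
    }
    if ("Z" %in% classes) {
        m <- scan_z(seq, params$z_min)
        add("Z", m$start, m$end)
    }
    if ("APR" %in% classes) {
        m <- scan_apr(seq, params$apr_tract_min, params$apr_tract_max,
                      params$apr_min_tracts, params$apr_period,
                      params$apr_period_tol)
        add("APR", m$start, m$end)
    }
    out <- if (length(res) == 0L)
        data.frame(motif_class = character(0), start = integer(0),
                   end = integer(0), stringsAsFactors = FALSE)
    else do.call(rbind, res)
    out <- out[order(out$start, out$end, out$motif_class), , drop = FALSE]
    row.names(out) <- NULL
    attr(out, "params") <- params
    out
}

# maximal short-tandem-repeat tracts: for each unit length u, runs where
# seq[i] == seq[i+u] give tracts of length run + u; a tract qualifies when
# it holds >= min_copies full copies and >= min_len nt. Identical intervals
# found at several unit lengths are reported once (smallest unit).
scan_str <- function(seq, unit_max, min_copies, min_len) {
    ch <- seq_chars(seq)
    n <- length(ch)
    out <- list()
    for (u in seq_len(min(unit_max, max(0L, n - 1L)))) {
        agree <- ch[seq_len(n - u)] == ch[seq_len(n - u) + u] &
                 ch[seq_len(n - u)] != "N"
        if (!any(agree)) next
        r <- rle(agree)
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        for (k in which(r$values)) {
            tract <- r$lengths[k] + u
            if (tract >= min_len && tract %/% u >= min_copies)
                out[[length(out) + 1L]] <-
                    c(start = s[k] - 1L, end = s[k] - 1L + tract, unit = u)
        }
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), end = integer(0)))
    m <- do.call(rbind, out)
    m <- m[order(m[, "start"], m[, "end"], m[, "unit"]), , drop = FALSE]
    m <- m[!duplicated(m[, c("start", "end"), drop = FALSE]), , drop = FALSE]
    data.frame(start = m[, "start"], end = m[, "end"])
}

# maximal alternating purine-pyrimidine tracts whose dinucleotide steps are
# all GC, CG, GT, TG, AC or CA (AT/TA steps excluded)
scan_z <- function(seq, z_min) {
    ch <- seq_chars(seq)
    n <- length(ch)
    if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
    pair_ok <- vapply(seq_len(n - 1L), function(i) {
        x <- ch[i]; y <- ch[i + 1L]
        if (x == "N" || y == "N") return(FALSE)
        pur <- c("A", "G")
        alt <- (x %in% pur) != (y %in% pur)
        alt && !(x %in% c("A", "T") && y %in% c("A", "T"))
    }, logical(1))
    r <- rle(pair_ok)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- which(r$values & r$lengths + 1L >= z_min)
    data.frame(start = s[keep] - 1L, end = s[keep] + r$lengths[keep])
}

# A-phased repeats: runs of A (or runs of T) of tract_min..tract_max nt
# whose centers recur with period +/- tol; an occurrence spans the first
# through last tract of a maximal phased chain of >= min_tracts tracts
scan_apr <- function(seq, tract_min, tract_max, min_tracts, period, tol) {
    ch <- seq_chars(seq)
    tracts <- list()
    for (base in c("A", "T")) {
        r <- rle(ch == base)
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        for (k in which(r$values & r$lengths >= tract_min & r$lengths <= tract_max))
            tracts[[length(tracts) + 1L]] <-
                c(start = s[k] - 1L, end = e[k], center = (s[k] - 1L + e[k]) / 2)
    }
    if (length(tracts) < min_tracts)
        return(data.frame(start = integer(0), end = integer(0)))
    tr <- do.call(rbind, tracts)
    tr <- tr[order(tr[, "center"]), , drop = FALSE]
    out <- list()
    i <- 1L
    nt <- nrow(tr)
    while (i <= nt) {
        j <- i
        while (j < nt &&
               abs(tr[j + 1L, "center"] - tr[j, "center"] - period) <= tol)
            j <- j + 1L
        if (j - i + 1L >= min_tracts)
            out[[length(out) + 1L]] <- c(tr[i, "start"], tr[j, "end"])
        i <- j + 1L
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), end = integer(0)))
    m <- do.call(rbind, out)
    data.frame(start = m[, 1L], end = m[, 2L])
}
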