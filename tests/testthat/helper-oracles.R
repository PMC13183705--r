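# Independent oracles used to validate the package's alignment and
# scanning primitives. These deliberately re-derive each quantity by the
# most literal route available (full DP matrices, all-window enumeration,
# utils::adist), sharing no code with the implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# full-matrix unit-cost edit distance
r_levenshtein <- function(a, b) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    D <- matrix(0L, n + 1, m + 1)
    D[, 1] <- 0:n
    D[1, ] <- 0:m
    for (i in seq_len(n)) for (j in seq_len(m))
        D[i + 1, j + 1] <- min(D[i, j] + (A[i] != B[j]),
                               D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    D[n + 1, m + 1]
}

# full Gotoh DP with explicit traceback; identical scoring convention to
# the package (gap of length L costs open + L * ext; ties prefer the
# diagonal state, then a gap consuming `a`, then a gap consuming `b`)
r_global_identity <- function(a, b, open = 2, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e18
    M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
    tM <- matrix(NA_integer_, n + 1, m + 1); tX <- tM; tY <- tM
    M[1, 1] <- 0
    if (n > 0) { X[2:(n + 1), 1] <- -(open + (1:n) * ext); tX[2:(n + 1), 1] <- c(1L, rep(2L, n - 1L)) }
    if (m > 0) { Y[1, 2:(m + 1)] <- -(open + (1:m) * ext); tY[1, 2:(m + 1)] <- c(1L, rep(3L, m - 1L)) }
    pick <- function(v) {  # max with preference M > X > Y
        w <- which(v == max(v))[1]
        c(v[w], w)
    }
    for (i in seq_len(n)) for (j in seq_len(m)) {
        s <- if (A[i] == B[j] && A[i] != "N") 1 else 0
        p <- pick(c(M[i, j], X[i, j], Y[i, j]))
        if (p[1] > NEG / 2) { M[i + 1, j + 1] <- p[1] + s; tM[i + 1, j + 1] <- p[2] }
        p <- pick(c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                    Y[i, j + 1] - open - ext))
        if (p[1] > NEG / 2) { X[i + 1, j + 1] <- p[1]; tX[i + 1, j + 1] <- p[2] }
        p <- pick(c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                    Y[i + 1, j] - ext))
        if (p[1] > NEG / 2) { Y[i + 1, j + 1] <- p[1]; tY[i + 1, j + 1] <- p[2] }
    }
    st <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
    i <- n; j <- m; n_match <- 0L; len <- 0L
    while (i > 0 || j > 0) {
        len <- len + 1L
        if (st == 1) {
            if (A[i] == B[j] && A[i] != "N") n_match <- n_match + 1L
            st <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
        } else if (st == 2) {
            st <- tX[i + 1, j + 1]; i <- i - 1L
        } else {
            st <- tY[i + 1, j + 1]; j <- j - 1L
        }
    }
    100 * n_match / len
}

# all donor substrings (lengths 1 .. m+max_lev; longer ones provably
# exceed max_lev) minimizing the edit distance to `block`
brute_best_segments <- function(block, donor, max_lev) {
    m <- nchar(block); n <- nchar(donor)
    cand <- do.call(rbind, lapply(seq_len(min(n, m + max_lev)), function(len) {
        s <- 0:(n - len)
        data.frame(offset = s, length = len,
                   dist = as.integer(utils::adist(
                       block, substring(donor, s + 1, s + len))))
    }))
    d <- min(cand$dist)
    if (d > max_lev) return(cand[0, ])
    out <- cand[cand$dist == d, ]
    out[order(out$offset, out$length), ]
}

# naive all-window IUPAC scan on an ungapped sequence (0-based half-open)
naive_aid_scan <- function(seq) {
    pats <- list(WRCY = c("AT", "AG", "C", "CT"), RGYW = c("AG", "G", "CT", "AT"),
                 TW = c("T", "AT"), WA = c("AT", "A"))
    ch <- strsplit(seq, "")[[1]]
    out <- list()
    for (cl in names(pats)) {
        p <- pats[[cl]]
        w <- length(p)
        for (s in seq_len(length(ch) - w + 1)) {
            ok <- all(vapply(seq_len(w), function(k)
                grepl(ch[s + k - 1], p[k], fixed = TRUE), logical(1)))
            if (ok)
                out[[length(out) + 1]] <- data.frame(
                    motif_class = cl, start = s - 1L, end = s - 1L + w,
                    stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0)
        return(data.frame(motif_class = character(0), start = integer(0),
                          end = integer(0)))
    o <- do.call(rbind, out)
    o <- o[order(o$start, o$end, o$motif_class), ]
    row.names(o) <- NULL
    o
}

# quadratic direct-repeat scan by literal substring comparison: for every
# (leftmost agreement-run start, arm-start distance d) pair, extend the
# agreement character by character and apply the arm/spacer thresholds
brute_dr_scan <- function(seq, arm_min, spacer_max) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    eq <- function(i, j) ch[i] == ch[j] && ch[i] != "N"
    out <- list()
    for (d in arm_min:(n - 1)) {
        i <- 1
        while (i <= n - d) {
            if (eq(i, i + d) && (i == 1 || !eq(i - 1, i - 1 + d))) {
                R <- 0
                while (i + R <= n - d && eq(i + R, i + R + d)) R <- R + 1
                L <- min(R, d); g <- d - L
                if (L >= arm_min && g <= spacer_max)
                    out[[length(out) + 1]] <- c(start = i - 1L,
                                                end = i - 1L + d + L)
                i <- i + R
            } else i <- i + 1
        }
    }
    if (length(out) == 0)
        return(data.frame(start = integer(0), end = integer(0)))
    m <- unique(do.call(rbind, out))
    m <- m[order(m[, "start"], m[, "end"]), , drop = FALSE]
    data.frame(start = m[, "start"], end = m[, "end"], row.names = NULL)
}
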