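# acceptor/donor pair with exactly 6 identical nt 5' of a 3-nt core and
# exactly 1 identical nt 3' of it (the 7th upstream / 2nd downstream differ)
flank_pair <- function() {
    acc <- "TGCATGCAGGTCAAGCTTGCATGCA"
    don <- "AGCATACAGGTCTTTCATGCATGCA"
    #            ^ 7th nt 5' of the core differs   core: positions 13..15
    #            (and the 2nd nt 3' of it)
    list(acc = data.frame(ungapped_seq = acc, gapped_seq = acc,
                          stringsAsFactors = FALSE),
         don = data.frame(ungapped_seq = don, gapped_seq = don,
                          stringsAsFactors = FALSE),
         event = make_event(gc_block_start = 12L, gc_block_end = 15L,
                            gc_block_start_ungapped = 12L,
                            gc_read_subseq = "TTT", gc_donor_offset = 12L,
                            gc_donor_length = 3L, gc_block_length = 3L))
}

test_that("flanking identity walks outward from the block", {
    fp <- flank_pair()
    fl <- flanking_identity(fp$event, fp$acc, fp$don)
    expect_equal(fl, list(five_len = 6L, three_len = 1L))

    # block at the first position has no 5' flank
    ev0 <- make_event(gc_block_start = 0L, gc_block_end = 3L,
                      gc_block_start_ungapped = 0L, gc_read_subseq = "TTT",
                      gc_donor_offset = 0L, gc_donor_length = 3L)
    fl0 <- flanking_identity(ev0, fp$acc, fp$don)
    expect_equal(fl0$five_len, 0L)

    bad <- fp$event; bad$gc_donor_offset <- 1000L
    expect_error(flanking_identity(bad, fp$acc, fp$don), "donor offset")
})

test_that("flanking identity equals a position-by-position walk oracle", {
    set.seed(9)
    for (k in 1:25) {
        n <- 60
        acc <- rand_dna(n)
        don <- rand_dna(n)
        s <- sample(5:(n - 10), 1)
        len <- sample(3:6, 1)
        ev <- make_event(gc_block_start = s, gc_block_end = s + len,
                         gc_block_start_ungapped = s,
                         gc_read_subseq = strrep("T", len),
                         gc_donor_offset = s, gc_donor_length = len)
        a <- strsplit(acc, "")[[1]]; d <- strsplit(don, "")[[1]]
        five <- 0; i <- s
        while (i >= 1 && a[i] == d[i]) { five <- five + 1; i <- i - 1 }
        three <- 0; i <- s + len + 1
        while (i <= n && a[i] == d[i]) { three <- three + 1; i <- i + 1 }
        got <- flanking_identity(
            ev, data.frame(ungapped_seq = acc, stringsAsFactors = FALSE),
            data.frame(ungapped_seq = don, stringsAsFactors = FALSE))
        expect_equal(got, list(five_len = as.integer(five),
                               three_len = as.integer(three)))
    }
})

test_that("expanded events add the identical flanks to the block", {
    fp <- flank_pair()
    ev <- fp$event
    ev$gc_five_prime_identical_len <- 6L
    ev$gc_three_prime_identical_len <- 1L
    ex <- expanded_event(ev, fp$acc)
    # 3-nt block with (6, 1) flanks expands to 10 nt
    expect_equal(ex$expanded_len, 10L)
    expect_equal(c(ex$expanded_start, ex$expanded_end), c(6L, 16L))

    ev$gc_five_prime_identical_len <- 0L
    ev$gc_three_prime_identical_len <- 0L
    ex0 <- expanded_event(ev, fp$acc)
    expect_equal(c(ex0$expanded_start, ex0$expanded_end), c(12L, 15L))

    # flank longer than the available sequence clamps at the boundary
    ev$gc_five_prime_identical_len <- 99L
    exc <- expanded_event(ev, fp$acc)
    expect_equal(exc$expanded_start, 0L)
})

test_that("AID motif scan equals the naive all-window oracle", {
    m <- scan_aid_motifs("AGCT")
    expect_equal(m$motif_class[order(m$motif_class)], c("RGYW", "WRCY"))
    expect_equal(unique(m$start), 0L)
    expect_equal(unique(m$end), 4L)
    expect_equal(nrow(scan_aid_motifs("GGGG")), 0)
    m2 <- scan_aid_motifs("TA")
    expect_setequal(m2$motif_class, c("TW", "WA"))

    set.seed(21)
    for (k in 1:40) {
        sq <- rand_dna(120)
        got <- scan_aid_motifs(sq)[, c("motif_class", "start", "end")]
        row.names(got) <- NULL
        expect_equal(got, naive_aid_scan(sq))
    }
})

test_that("AID motif coordinates are reported in the gapped frame", {
    m <- scan_aid_motifs("..AG.CT")      # AGCT spans columns 2,3,5,6
    expect_true(any(m$motif_class == "WRCY" & m$start == 2 & m$end == 7))
})

test_that("nearest AID distance uses the adjacency-is-1 convention", {
    mot <- function(s, e) data.frame(motif_class = "WRCY", start = s, end = e,
                                     strand = "+", stringsAsFactors = FALSE)
    ev <- function(s, e) make_event(gc_block_start = s, gc_block_end = e)
    expect_equal(nearest_aid_distance(ev(4, 7), mot(2, 6)), 0L)   # overlap
    expect_equal(nearest_aid_distance(ev(4, 7), mot(0, 4)), 1L)   # touching
    expect_equal(nearest_aid_distance(ev(6, 9), mot(0, 4)), 3L)   # 2 nt between
    expect_equal(nearest_aid_distance(ev(4, 7), mot(0, 4), convention = "gap"), 0L)
    expect_true(is.na(nearest_aid_distance(ev(4, 7), mot(0, 4)[0, ])))
})

test_that("hotspot overlap categories partition all events", {
    ev <- make_event(gc_block_start = 2L, gc_block_end = 5L)
    hs <- function(s, e) data.frame(motif_class = "WRCY", start = s, end = e,
                                    strand = "+", stringsAsFactors = FALSE)
    expect_equal(hotspot_overlap_category(ev, hs(0, 8)), "full")
    expect_equal(hotspot_overlap_category(ev, hs(4, 9)), "partial")
    expect_equal(hotspot_overlap_category(ev, hs(10, 20)), "none")
    set.seed(33)
    for (k in 1:50) {
        e <- make_event(gc_block_start = sample(0:20, 1))
        e$gc_block_end <- e$gc_block_start + sample(3:10, 1)
        h <- hs(sample(0:25, 3), 0)
        h$end <- h$start + sample(2:6, 3, replace = TRUE)
        expect_true(hotspot_overlap_category(e, h) %in%
                    c("full", "partial", "none"))
    }
})

test_that("positional percentages count event inclusion per position", {
    ev <- rbind(make_event(gc_block_start = 1L, gc_block_end = 4L),
                make_event(gc_block_start = 2L, gc_block_end = 5L))
    pr <- positional_event_percentage(ev)
    expect_equal(pr$position, 1:4)
    expect_equal(pr$percentage, c(50, 100, 100, 50))
    expect_true(all(pr$percentage >= 0 & pr$percentage <= 100))

    one <- positional_event_percentage(make_event(gc_block_start = 3L,
                                                  gc_block_end = 6L))
    expect_equal(one$position, 3:5)        # exactly the block
    expect_equal(one$percentage, rep(100, 3))

    expect_equal(nrow(positional_event_percentage(make_event()[0, ])), 0)

    seq_denom <- positional_event_percentage(ev, denominator = "sequences",
                                             n_sequences = 10)
    expect_equal(max(seq_denom$percentage), 20)
})

test_that("motif offsets are signed block-relative starts", {
    ev <- make_event(gc_block_start = 10L, gc_block_end = 13L)
    mot <- data.frame(sequence_id = c("r1", "r1", "r2"),
                      motif_class = "DR", start = c(0L, 10L, 5L),
                      stringsAsFactors = FALSE)
    off <- motif_offsets(ev, mot)
    expect_equal(sort(off$offset), c(-10L, 0L))        # r2 motif not paired
    expect_equal(nrow(motif_offsets(ev, mot[0, ])), 0)
})
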