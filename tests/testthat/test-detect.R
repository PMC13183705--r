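test_that("edit distance has metric basics and matches the DP oracle", {
    expect_equal(levenshtein("", ""), 0)
    expect_equal(levenshtein("ACG", "ACG"), 0)
    expect_equal(levenshtein("ACG", ""), 3)
    set.seed(5)
    for (k in 1:60) {
        a <- rand_dna(sample(0:30, 1)); b <- rand_dna(sample(0:30, 1))
        d <- levenshtein(a, b)
        expect_equal(d, r_levenshtein(a, b))
        expect_equal(d, levenshtein(b, a))
        expect_equal(d == 0, a == b)
    }
})

test_that("mismatch blocks are maximal runs with merge and length rules", {
    expect_equal(nrow(extract_mismatch_blocks("AAAAAAAAAA", "AAAAAAAAAA")), 0)
    b <- extract_mismatch_blocks("AAATTTAAAA", "AAAAAAAAAA")
    expect_equal(b$start, 3L); expect_equal(b$end, 6L)
    expect_equal(b$read_subseq, "TTT")
    # single mismatch stays below the 3-nt floor
    expect_equal(nrow(extract_mismatch_blocks("AATAAAAAAA", "AAAAAAAAAA")), 0)
    # runs [3,5) and [6,8) merge across one matching column
    m <- extract_mismatch_blocks("AAATTATTAA", "AAAAAAAAAA", merge_gap = 1)
    expect_equal(c(m$start, m$end), c(3L, 8L))
    expect_equal(nrow(extract_mismatch_blocks("AAATTATTAA", "AAAAAAAAAA",
                                              merge_gap = 0)), 0)
})

test_that("gap and N columns are neutral in block extraction", {
    # '.' in either sequence breaks a run and is excluded from length
    b <- extract_mismatch_blocks("TT.TT", "AA.AA", min_block_len = 2)
    expect_equal(nrow(b), 2)
    expect_equal(b$length, c(2L, 2L))
    # merge_gap can absorb the gap column; length still counts bases only
    b2 <- extract_mismatch_blocks("TT.TT", "AA.AA", min_block_len = 3,
                                  merge_gap = 1)
    expect_equal(nrow(b2), 1)
    expect_equal(b2$length, 4L)
    expect_equal(b2$read_subseq, "TTTT")
    # N never mismatches
    expect_equal(nrow(extract_mismatch_blocks("ANNNA", "AAAAA")), 0)
    expect_error(extract_mismatch_blocks("ACGT", "ACGTA", read_id = "rX"), "rX")
})

test_that("ungapped block coordinates track gap columns", {
    b <- extract_mismatch_blocks("..AATTTA", "..AAAAAA")
    expect_equal(b$start, 4L)            # gapped column
    expect_equal(b$start_ungapped, 2L)   # third read base
})

test_that("donor search finds exact segments and respects the distance cap", {
    set <- toy_set()
    blocks <- data.frame(start = 9L, end = 14L, start_ungapped = 9L,
                         end_ungapped = 14L, length = 5L,
                         read_subseq = "AATTA", stringsAsFactors = FALSE)
    read <- "CAGGTGCAGAATTAGGAGTCTGGGGGAGGC"    # equals the upstream pseudogene
    hit <- search_donor(blocks[1, ], read, set)
    expect_equal(hit$donor_name, "IGHV1-40")
    expect_equal(hit$lev_distance, 0L)
    expect_equal(hit$donor_offset, 9L)
    # nothing within the cap
    far <- blocks; far$read_subseq <- "TGCATGCATGCA"
    expect_null(search_donor(far[1, ], read, set, detect_config(max_lev = 0L)))
})

test_that("a zero distance cap returns only identical segments", {
    set <- toy_set()
    cfg <- detect_config(max_lev = 0L)
    pseudo_seqs <- set$genes$ungapped_seq[set$genes$functionality == "P"]
    set.seed(11)
    for (k in 1:20) {
        # half the draws are guaranteed pseudogene substrings
        sub <- if (k %% 2 == 0) {
            src <- sample(pseudo_seqs, 1)
            s <- sample(nchar(src) - 5L, 1)
            substr(src, s, s + 5L)
        } else rand_dna(6)
        blk <- data.frame(start = 0L, end = 6L, start_ungapped = 0L,
                          end_ungapped = 6L, length = 6L, read_subseq = sub,
                          stringsAsFactors = FALSE)
        hit <- search_donor(blk, sub, set, cfg)
        in_pseudo <- any(vapply(pseudo_seqs, grepl, logical(1),
                                pattern = sub, fixed = TRUE))
        expect_equal(!is.null(hit), in_pseudo)
        if (!is.null(hit)) {
            donor <- set$genes$ungapped_seq[
                set$genes$name == hit$donor_name][1]
            seg <- substr(donor, hit$donor_offset + 1,
                          hit$donor_offset + hit$donor_length)
            expect_identical(seg, sub)
        }
    }
})

test_that("seeded donor scan equals the exhaustive scan on long blocks", {
    set.seed(13)
    for (k in 1:40) {
        block <- rand_dna(sample(18:40, 1))
        donor <- rand_dna(300)
        if (k %% 4 == 0) {   # guarantee some true hits with 0 or 1 edits
            pos <- sample(0:(300 - nchar(block)), 1)
            substr(donor, pos + 1, pos + nchar(block)) <- block
        }
        a <- igconvert:::cpp_scan_segments(block, donor, 1L)
        b <- igconvert:::cpp_scan_segments_seeded(block, donor, 1L, 8L)
        expect_equal(a, b)
    }
})

test_that("donor ties break on flanking identity against the read context", {
    # two pseudogenes both carry the block at distance 0; only IGHV1-9's
    # copy sits in flanks matching the read
    read <- "AAAACCGGGTTTCCAAAA"
    blk <- data.frame(start = 6L, end = 12L, start_ungapped = 6L,
                      end_ungapped = 12L, length = 6L, read_subseq = "GGGTTT",
                      stringsAsFactors = FALSE)
    p <- write_toy_germline(
        list("IGHV1-1*01|F" = "AAAACCAAAAAACCAAAA",
             "IGHV1-8*01|P" = "TGCATGGGGTTTATGCAT",   # mismatching flanks
             "IGHV1-9*01|P" = "CAAACCGGGTTTCCAAAC"),  # matching flanks
        data.frame(gene_name = c("IGHV1-8", "IGHV1-9", "IGHV1-1"),
                   position = 1:3))
    set <- load_germline_set(p$fasta, p$order)
    hit <- search_donor(blk, read, set)
    expect_equal(hit$donor_name, "IGHV1-9")
})

test_that("event detection composes blocks and donors and ignores SHM-like scatter", {
    set <- toy_set()
    germ <- set$genes$ungapped_seq[set$genes$name == "IGHV1-20"]
    mk_read <- function(seq) data.frame(sequence_id = "r1", sample_id = "s1",
                                        sequence = seq, v_call = "IGHV1-20*01",
                                        stringsAsFactors = FALSE)
    expect_equal(nrow(detect_events(mk_read(germ), set)), 0)

    # implanted donor tract (the upstream pseudogene core at columns 9..13)
    conv <- germ
    substr(conv, 10, 14) <- "AATTA"
    ev <- detect_events(mk_read(conv), set)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$gc_donor, "IGHV1-40")
    expect_equal(ev$gc_lev_distance, 0L)
    expect_equal(c(ev$gc_block_start, ev$gc_block_end), c(9L, 14L))

    # five isolated point mutations never reach the 3-nt block floor
    shm <- germ
    for (i in c(2, 8, 15, 21, 27))
        substr(shm, i, i) <- setdiff(c("A", "C", "G", "T"),
                                     substr(shm, i, i))[1]
    expect_equal(nrow(detect_events(mk_read(shm), set)), 0)

    bad <- mk_read(germ); bad$v_call <- "IGHV9-99*01"
    expect_error(detect_events(bad, set), "IGHV1-20")
})

test_that("detection is invariant to duplicate counts", {
    set <- toy_set()
    germ <- set$genes$ungapped_seq[set$genes$name == "IGHV1-20"]
    conv <- germ; substr(conv, 10, 14) <- "AATTA"
    r1 <- data.frame(sequence_id = "r1", sample_id = "s1", sequence = conv,
                     v_call = "IGHV1-20*01", duplicate_count = 1L,
                     stringsAsFactors = FALSE)
    r2 <- r1; r2$duplicate_count <- 500L
    e1 <- detect_events(r1, set); e2 <- detect_events(r2, set)
    expect_identical(e1, e2)
})

test_that("the gene-order filter keeps exactly upstream donors and is idempotent", {
    set <- toy_set()   # ranks: IGHV1-40 (1) < IGHV1-20 (2) < IGHV1-21 (3) < IGHV1-41 (4)
    ev <- rbind(make_event(gc_donor = "IGHV1-40", gc_acceptor = "IGHV1-20"),
                make_event(gc_donor = "IGHV1-41", gc_acceptor = "IGHV1-20"),
                make_event(gc_donor = "IGHV1-40", gc_acceptor = "IGHV1-21"),
                make_event(gc_donor = "IGHV1-99", gc_acceptor = "IGHV1-20"))
    out <- gene_order_filter(ev, set)
    expect_equal(nrow(out), 2)
    expect_true(all(out$gc_passed_order_filter))
    # matches a direct rank comparison
    rk <- setNames(set$order$rank, set$order$gene_name)
    keep <- !is.na(rk[ev$gc_donor]) & rk[ev$gc_donor] < rk[ev$gc_acceptor]
    expect_equal(nrow(out), sum(keep, na.rm = TRUE))
    expect_equal(attr(out, "removed"),
                 c(downstream_donor = 1L, unresolved_rank = 1L))
    # idempotent
    again <- gene_order_filter(out, set)
    expect_equal(again[names(out)], out[names(out)], ignore_attr = TRUE)
    # empty in, empty out
    expect_equal(nrow(gene_order_filter(ev[0, ], set)), 0)
})
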