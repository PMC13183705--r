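test_that("simulation config validates its inputs", {
    expect_error(sim_config(implant_fraction = 1.5), "probabilities")
    expect_error(sim_config(tract_len_range = c(5, 2)), "tract_len_range")
    expect_error(sim_config(downstream_donor_fraction = 0.5,
                            n_pseudo = 5, n_functional = 5), "downstream")
    expect_error(sim_config(v_length = 50, tract_len_range = c(3, 30),
                            n_sites = 3), "unsatisfiable")
})

test_that("the simulated locus hits its identity target and is reproducible", {
    cfg <- sim_config(seed = 99)
    loc1 <- simulate_germline_locus(cfg)
    loc2 <- simulate_germline_locus(cfg)
    expect_identical(loc1$set, loc2$set)
    expect_identical(loc1$sites, loc2$sites)

    g <- loc1$set$genes
    for (j in which(g$functionality == "P")) {
        src <- loc1$sites$source[loc1$sites$donor == g$name[j]][1]
        id <- pairwise_identity(g$ungapped_seq[j],
                                g$ungapped_seq[g$name == src])
        expect_gte(id, 63); expect_lte(id, 67)   # target 65 +/- 2 points
    }

    # identity 1 collapses each pseudogene onto its source gene
    loc_same <- simulate_germline_locus(sim_config(pseudo_identity = 1,
                                                   seed = 99))
    gs <- loc_same$set$genes
    for (j in which(gs$functionality == "P")) {
        src <- loc_same$sites$source[loc_same$sites$donor == gs$name[j]][1]
        expect_identical(gs$ungapped_seq[j], gs$ungapped_seq[gs$name == src])
    }
    expect_true(all(loc_same$sites$is_silent))
})

test_that("implanting replaces exactly the tract and respects anchors", {
    acc <- "AAAAAAGGGCTTTTTT"
    don <- "AAAAAACCCCTTTTTT"   # identical outside positions 7..10
    out <- implant_conversion(acc, acc, don, tract_start = 6L, tract_len = 4L,
                              anchor_5p = 6L, anchor_3p = 1L)
    expect_equal(out, don)
    expect_equal(substr(out, 1, 6), substr(acc, 1, 6))

    # silent conversion: donor tract equals the acceptor tract
    expect_equal(implant_conversion(acc, acc, acc, 6L, 4L, 6L, 1L), acc)

    # anchors not satisfied at the chosen site
    don2 <- don; substr(don2, 3, 3) <- "T"
    expect_error(implant_conversion(acc, acc, don2, 6L, 4L, 6L, 1L), "anchor")
})

test_that("SHM mutation count follows its binomial model", {
    sq <- rand_dna(10000)
    expect_identical(apply_shm(sq, 0, seed = 1), sq)
    all_mut <- apply_shm(sq, 1, hotspot_multiplier = 1, seed = 1)
    expect_equal(sum(strsplit(all_mut, "")[[1]] == strsplit(sq, "")[[1]]), 0)

    mut <- apply_shm(sq, 0.01, hotspot_multiplier = 1, seed = 7)
    n_sub <- sum(strsplit(mut, "")[[1]] != strsplit(sq, "")[[1]])
    bounds <- qbinom(c(0.005, 0.995), 10000, 0.01)
    expect_gte(n_sub, bounds[1]); expect_lte(n_sub, bounds[2])
})

test_that("repertoire simulation is seed-deterministic with faithful truth", {
    cfg <- sim_config(n_reads = 200, seed = 4242)
    s1 <- simulate_repertoire(cfg)
    s2 <- simulate_repertoire(cfg)
    expect_identical(s1$reads, s2$reads)
    expect_identical(s1$truth, s2$truth)

    none <- simulate_repertoire(sim_config(n_reads = 50, implant_fraction = 0,
                                           seed = 1))
    expect_equal(nrow(none$truth), 0)

    many <- simulate_repertoire(sim_config(n_reads = 2000, seed = 31,
                                           shm_rate = 0))
    bounds <- qbinom(c(0.005, 0.995), 2000, 0.1)
    expect_gte(nrow(many$truth), bounds[1])
    expect_lte(nrow(many$truth), bounds[2])
})

test_that("recovery scoring matches a brute-force set comparison", {
    truth <- data.frame(read_id = c("r1", "r2", "r3"),
                        acceptor = "A1-1", donor = c("P1-1", "P1-2", "P1-3"),
                        tract_start = c(10L, 20L, 30L),
                        tract_end = c(15L, 25L, 35L),
                        donor_offset = 0L, is_upstream_donor = TRUE,
                        is_silent = c(FALSE, FALSE, TRUE),
                        segment_unique = TRUE, stringsAsFactors = FALSE)
    # exact recovery of both non-silent tracts
    ev <- rbind(make_event(sequence_id = "r1", gc_block_start = 10L,
                           gc_block_end = 15L, gc_donor = "P1-1"),
                make_event(sequence_id = "r2", gc_block_start = 20L,
                           gc_block_end = 25L, gc_donor = "P1-2"))
    r <- evaluate_recovery(truth, ev)
    expect_equal(r[c("sensitivity", "precision", "donor_accuracy")],
                 list(sensitivity = 1, precision = 1, donor_accuracy = 1))
    expect_equal(r$n_silent, 1L)

    # no detections at all
    r0 <- evaluate_recovery(truth, ev[0, ])
    expect_equal(r0$sensitivity, 0)
    expect_true(is.na(r0$precision))

    # randomized comparison against direct interval arithmetic
    set.seed(55)
    for (k in 1:10) {
        tr <- truth[sample(1:3, 2), ]
        e <- make_event(sequence_id = sample(c("r1", "r2", "r9"), 1),
                        gc_block_start = sample(5:40, 1))
        e$gc_block_end <- e$gc_block_start + 4L
        got <- evaluate_recovery(tr, e)
        hit <- any(tr$read_id == e$sequence_id &
                   tr$tract_start < e$gc_block_end &
                   tr$tract_end > e$gc_block_start)
        expect_equal(got$precision, as.numeric(hit))
    }
})

test_that("donor accuracy never improves as SHM load increases", {
    acc_at <- function(rate, seed) {
        cfg <- sim_config(n_reads = 250, shm_rate = rate,
                          hotspot_multiplier = 3,
                          tract_len_range = c(10L, 25L), seed = seed)
        sim <- simulate_repertoire(cfg)
        ev <- gene_order_filter(detect_repertoire(sim$reads, sim$locus$set),
                                sim$locus$set)
        evaluate_recovery(sim$truth, ev)$donor_accuracy
    }
    rates <- c(0, 0.03, 0.10)
    mean_acc <- sapply(rates, function(r)
        mean(sapply(c(101, 202, 303), function(s) acc_at(r, s))))
    expect_true(all(diff(mean_acc) <= 1e-12))
})
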