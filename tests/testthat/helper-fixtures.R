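# Tiny germline fixtures written to tempfiles at test time.

write_toy_germline <- function(records, order,
                               dir = { d <- tempfile("toy"); dir.create(d); d }) {
    fasta <- file.path(dir, "germline.fasta")
    writeLines(unlist(lapply(names(records), function(h)
        c(paste0(">", h), records[[h]]))), fasta)
    order_path <- file.path(dir, "order.tsv")
    utils::write.table(order, order_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fasta = fasta, order = order_path)
}

# default 2-functional / 2-pseudogene toy locus used across tests;
# IGHV1-40 sits upstream of both functional genes, IGHV1-41 downstream
toy_set <- function() {
    # both pseudogene cores (positions 10-14) differ from f1 at every base,
    # so an implanted core forms one contiguous 5-nt mismatch block
    f1 <- "CAGGTGCAGCTGGTGGAGTCTGGGGGAGGC"
    f2 <- "GAGGTGAAGCTGCTGGAGTCTGGAGGAGGC"
    p_up <- "CAGGTGCAGAATTAGGAGTCTGGGGGAGGC"
    p_dn <- "CAGGTGCAGGCAAGGGAGTCTGGGGGAGGC"
    paths <- write_toy_germline(
        list("IGHV1-20*01|F" = f1, "IGHV1-21*01|F" = f2,
             "IGHV1-40*01|P" = p_up, "IGHV1-41*01|P" = p_dn),
        data.frame(gene_name = c("IGHV1-40", "IGHV1-20", "IGHV1-21",
                                 "IGHV1-41"),
                   position = 1:4))
    load_germline_set(paths$fasta, paths$order)
}

# one-row event data.frame with sensible defaults, overridable by name
make_event <- function(...) {
    ev <- data.frame(sequence_id = "r1", sample_id = "s1", v_call = "IGHV1-20*01",
                     gc_acceptor = "IGHV1-20", gc_donor = "IGHV1-40",
                     gc_block_start = 9L, gc_block_end = 14L,
                     gc_block_start_ungapped = 9L, gc_block_length = 5L,
                     gc_read_subseq = "TTTTT", gc_donor_offset = 9L,
                     gc_donor_length = 5L, gc_lev_distance = 0L,
                     gc_passed_order_filter = NA,
                     gc_five_prime_identical_len = NA_integer_,
                     gc_three_prime_identical_len = NA_integer_,
                     gc_expanded_start = NA_integer_,
                     gc_expanded_end = NA_integer_,
                     gc_expanded_length = NA_integer_,
                     gc_aid_distance = NA_integer_,
                     gc_hotspot_overlap = NA_character_,
                     stringsAsFactors = FALSE)
    over <- list(...)
    for (nm in names(over)) ev[[nm]] <- over[[nm]]
    ev
}

# small fully-characterized simulation shared by invariant tests
shared_sim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- sim_config(n_reads = 150, shm_rate = 0,
                              tract_len_range = c(8L, 20L), seed = 20260927)
            sim <- simulate_repertoire(cfg)
            ev <- gene_order_filter(detect_repertoire(sim$reads, sim$locus$set),
                                    sim$locus$set)
            ann <- annotate_events(ev, sim$locus$set, sim$reads)
            cache <<- list(sim = sim, events = ann)
        }
        cache
    }
})
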