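#' Simulation configuration
#'
#' Parameters of the synthetic germline locus and repertoire generator.
#' The generator emulates the structure the detector is built for: a small
#' set of functional V genes with derived pseudogenes at ~60-68% identity,
#' implanted donor tracts anchored on identical flanks (6 nt at 5', 1 nt
#' at 3'), AID-hotspot-biased point mutation, and a locus order table
#' placing pseudogenes upstream and downstream of their source genes.
#'
#' @param n_functional,n_pseudo Numbers of functional genes and
#'   pseudogenes; each pseudogene is derived from one functional gene
#'   (round-robin), the first wave placed upstream of every functional
#'   gene, the second downstream.
#' @param v_length V-region length in nt (default 300).
#' @param pseudo_identity Target identity fraction of each pseudogene to
#'   its source functional gene (default 0.65); realized identity is held
#'   within 2 percentage points.
#' @param n_reads Number of simulated reads.
#' @param implant_fraction Probability that a read carries one conversion
#'   tract.
#' @param tract_len_range (min, max) implanted tract length in nt.
#' @param anchor_5p,anchor_3p Identical-flank lengths required at the
#'   implant site (defaults 6 and 1, the dominant flank lengths around
#'   short conversion events).
#' @param shm_rate Per-base substitution probability outside hotspots.
#' @param hotspot_multiplier Relative substitution rate inside WRCY/RGYW
#'   occurrences.
#' @param downstream_donor_fraction Fraction of implants drawn from donors
#'   ranked 3' of the acceptor (exercises the gene-order filter); requires
#'   `n_pseudo >= 2 * n_functional` when positive.
#' @param n_sites Implantable sites constructed per pseudogene.
#' @param leader_len Leader-region length simulated per gene (0 disables).
#' @param require_unique_segments Re-draw site cores until each donor
#'   segment occurs in exactly one pseudogene (exact-match check).
#' @param sample_id Sample label on the simulated reads.
#' @param seed Integer seed; identical (config, seed) gives identical
#'   output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_functional = 5L, n_pseudo = 10L, v_length = 300L,
                       pseudo_identity = 0.65, n_reads = 1000L,
                       implant_fraction = 0.1, tract_len_range = c(3L, 30L),
                       anchor_5p = 6L, anchor_3p = 1L,
                       shm_rate = 0.005, hotspot_multiplier = 3,
                       downstream_donor_fraction = 0,
                       n_sites = 3L, leader_len = 60L,
                       require_unique_segments = FALSE,
                       sample_id = "sim1", seed = 42L) {
    cfg <- as.list(environment())
    probs <- c(pseudo_identity, implant_fraction, shm_rate,
               downstream_donor_fraction)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    if (tract_len_range[1] < 1L || tract_len_range[2] < tract_len_range[1])
        stop("invalid tract_len_range")
    if (n_functional < 1L || n_pseudo < 1L)
        stop("need at least one functional gene and one pseudogene")
    if (downstream_donor_fraction > 0 && n_pseudo < 2L * n_functional)
        stop("downstream donors require n_pseudo >= 2 * n_functional")
    site_span <- anchor_5p + tract_len_range[2] + anchor_3p
    if (n_sites * (site_span + 2L) > v_length)
        stop("unsatisfiable identity/anchor combination: ",
             n_sites, " sites of up to ", site_span, " nt do not fit in ",
             v_length, " nt")
    structure(cfg, class = "sim_config")
}

random_seq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

mutate_positions <- function(ch, pos) {
    for (p in pos)
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    ch
}

count_exact_occurrences <- function(needle, haystacks) {
    sum(vapply(haystacks, function(h) {
        m <- gregexpr(needle, h, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) 0L else length(m)
    }, integer(1)))
}

# internal: build the locus inside an already-seeded RNG stream
build_locus <- function(cfg) {
    nf <- cfg$n_functional; np <- cfg$n_pseudo; L <- cfg$v_length
    fam <- function(k) sprintf("IGHV%d", ((k - 1L) %% 3L) + 1L)
    f_names <- sprintf("%s-%d", vapply(seq_len(nf), fam, ""), 20L + seq_len(nf))
    f_seqs <- vapply(seq_len(nf), function(k) random_seq(L), "")
    f_leaders <- if (cfg$leader_len > 0L)
        vapply(seq_len(nf), function(k) random_seq(cfg$leader_len), "")
    else rep(NA_character_, nf)

    src <- ((seq_len(np) - 1L) %% nf) + 1L
    wave <- ((seq_len(np) - 1L) %/% nf)
    upstream <- wave %% 2L == 0L
    p_names <- sprintf("%s-%d", vapply(src, fam, ""), 40L + seq_len(np))

    span_of <- function(core) cfg$anchor_5p + core + cfg$anchor_3p
    sites <- list()
    p_seqs <- character(np)
    p_leaders <- rep(NA_character_, np)
    M <- round((1 - cfg$pseudo_identity) * L)
    for (j in seq_len(np)) {
        source_seq <- f_seqs[src[j]]
        ch <- seq_chars(source_seq)
        core_lens <- sample(seq(cfg$tract_len_range[1], cfg$tract_len_range[2]),
                            cfg$n_sites, replace = TRUE)
        # place non-overlapping site windows left to right with >= 2 nt gaps
        spans <- span_of(core_lens)
        slack <- L - sum(spans) - 2L * (cfg$n_sites - 1L)
        if (slack < 0L) stop("unsatisfiable identity/anchor combination")
        offs <- sort(sample(0:slack, cfg$n_sites, replace = TRUE))
        starts <- offs + c(0L, cumsum(spans[-cfg$n_sites] + 2L))
        core_starts <- starts + cfg$anchor_5p      # 0-based
        protected <- unlist(lapply(seq_len(cfg$n_sites), function(s)
            (starts[s] + 1L):(starts[s] + spans[s])))
        target_pct <- 100 * cfg$pseudo_identity
        for (attempt in seq_len(50L)) {
            ch2 <- ch
            if (M > 0L) {
                # site cores are fully mutated so every implant is non-silent
                # and carries a contiguous mismatch run
                core_pos <- unlist(lapply(seq_len(cfg$n_sites), function(s)
                    (core_starts[s] + 1L):(core_starts[s] + core_lens[s])))
                ch2 <- mutate_positions(ch2, core_pos)
                id <- pairwise_identity(paste(ch2, collapse = ""), source_seq)
                if (id < target_pct - 2)
                    stop("unsatisfiable identity/anchor combination: fully ",
                         "mutated site cores already push identity to ",
                         round(id, 1), "%, below the target ", target_pct, "%")
                # identity is measured by global alignment, which recovers
                # some matches through gaps; add substitutions outside the
                # protected windows until the realized value reaches the
                # target band
                free <- sample(setdiff(seq_len(L), protected))
                while (id > target_pct + 1 && length(free) > 0L) {
                    take <- seq_len(min(3L, length(free)))
                    ch2 <- mutate_positions(ch2, free[take])
                    free <- free[-take]
                    id <- pairwise_identity(paste(ch2, collapse = ""), source_seq)
                }
                if (abs(id - target_pct) > 2)
                    stop("unsatisfiable identity/anchor combination: realized ",
                         "identity ", round(id, 1), "% cannot reach the target ",
                         target_pct, "%")
            }
            if (!cfg$require_unique_segments || M == 0L) break
            segs <- vapply(seq_len(cfg$n_sites), function(s)
                paste(ch2[(core_starts[s] + 1L):(core_starts[s] + core_lens[s])],
                      collapse = ""), "")
            others <- c(p_seqs[seq_len(j - 1L)][nzchar(p_seqs[seq_len(j - 1L)])])
            self <- paste(ch2, collapse = "")
            occ <- vapply(segs, function(sg)
                count_exact_occurrences(sg, c(others, self)), integer(1))
            if (all(occ == 1L)) break
        }
        p_seqs[j] <- paste(ch2, collapse = "")
        if (cfg$leader_len > 0L) {
            keep <- sample(5:min(26L, cfg$leader_len), 1L)
            lch <- seq_chars(f_leaders[src[j]])
            head_len <- cfg$leader_len - keep
            if (head_len > 0L)
                lch[seq_len(head_len)] <- sample(DNA_BASES, head_len, replace = TRUE)
            p_leaders[j] <- paste(lch, collapse = "")
        }
        for (s in seq_len(cfg$n_sites)) {
            seg <- substr(p_seqs[j], core_starts[s] + 1L,
                          core_starts[s] + core_lens[s])
            acc_seg <- substr(source_seq, core_starts[s] + 1L,
                              core_starts[s] + core_lens[s])
            sites[[length(sites) + 1L]] <- data.frame(
                donor = p_names[j], source = f_names[src[j]],
                core_start = core_starts[s], core_len = core_lens[s],
                segment = seg, is_silent = seg == acc_seg,
                is_upstream = upstream[j], stringsAsFactors = FALSE)
        }
    }
    sites <- do.call(rbind, sites)
    # exact-occurrence count of each segment across all pseudogenes
    sites$segment_unique <- vapply(sites$segment, function(sg)
        count_exact_occurrences(sg, p_seqs) == 1L, logical(1), USE.NAMES = FALSE)

    # locus layout: upstream pseudogenes, then functional genes, then
    # downstream pseudogenes
    order_tab <- data.frame(
        gene_name = c(p_names[upstream], f_names, p_names[!upstream]),
        position = seq_len(sum(upstream) + nf + sum(!upstream)),
        strand = "+", stringsAsFactors = FALSE)

    genes <- data.frame(
        name = c(f_names, p_names),
        allele = "*01",
        functionality = c(rep("F", nf), rep("P", np)),
        gapped_seq = c(f_seqs, p_seqs),
        ungapped_seq = c(f_seqs, p_seqs),
        leader_seq = c(f_leaders, p_leaders),
        family = sub("-.*$", "", c(f_names, p_names)),
        in_order = TRUE, stringsAsFactors = FALSE)
    set <- structure(list(genes = genes,
                          order = data.frame(gene_name = order_tab$gene_name,
                                             rank = as.integer(order_tab$position),
                                             strand = order_tab$strand,
                                             stringsAsFactors = FALSE),
                          functional_names = f_names,
                          pseudogene_names = p_names),
                     class = "germline_set")
    list(set = set, sites = sites)
}

#' Simulate a germline locus with implantable pseudogene sites
#'
#' Generates `n_functional` random functional V genes and `n_pseudo`
#' pseudogenes, each derived from one functional gene by point mutation
#' until the realized [pairwise_identity()] to the source lies within 2
#' percentage points of `pseudo_identity`. Per pseudogene,
#' `n_sites` implant sites are reserved: windows whose 5' and 3' anchors
#' stay identical to the source gene while the enclosed core is fully
#' mutated (so an implanted tract is non-silent and contains a contiguous
#' mismatch run). With `pseudo_identity = 1` no position is mutated and the
#' pseudogene equals its source (its sites are silent). The order table
#' places first-wave pseudogenes upstream of all functional genes and
#' second-wave ones downstream.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return list of class `sim_locus`: `set` (a `germline_set`) and `sites`
#'   (data.frame: `donor`, `source`, `core_start` (0-based), `core_len`,
#'   `segment`, `is_silent`, `is_upstream`, `segment_unique`).
#' @export
simulate_germline_locus <- function(config, seed = NULL) {
    stopifnot(inherits(config, "sim_config"))
    if (!is.null(seed)) config$seed <- seed
    out <- with_seed(config$seed, build_locus(config))
    out$config <- config
    class(out) <- "sim_locus"
    out
}

#' Implant a conversion tract into a read
#'
#' Replaces the tract interval of an acceptor-derived read with the
#' corresponding donor segment, after verifying the mechanistic
#' precondition that acceptor and donor are identical over at least
#' `anchor_5p` nt immediately 5' and `anchor_3p` nt immediately 3' of the
#' tract (gene conversion initiates in flanking sequence homology). When
#' the donor segment equals the acceptor segment the read is returned
#' unchanged (a silent conversion).
#'
#' @param read_seq Acceptor-derived read (ungapped).
#' @param acceptor_seq,donor_seq Ungapped germline sequences (equal
#'   coordinates).
#' @param tract_start 0-based tract start; `tract_len` its length.
#' @param anchor_5p,anchor_3p Required identical-flank lengths.
#' @return The read with the tract replaced.
#' @export
implant_conversion <- function(read_seq, acceptor_seq, donor_seq,
                               tract_start, tract_len,
                               anchor_5p = 6L, anchor_3p = 1L) {
    a <- seq_chars(acceptor_seq); d <- seq_chars(donor_seq)
    s <- tract_start; e <- tract_start + tract_len   # 0-based half-open
    if (s - anchor_5p < 0L || e + anchor_3p > length(a))
        stop("no site satisfying the anchor requirement at tract [",
             s, ", ", e, ")")
    ok5 <- anchor_5p == 0L ||
        all(a[(s - anchor_5p + 1L):s] == d[(s - anchor_5p + 1L):s])
    ok3 <- anchor_3p == 0L ||
        all(a[(e + 1L):(e + anchor_3p)] == d[(e + 1L):(e + anchor_3p)])
    if (!ok5 || !ok3)
        stop("no site satisfying the anchor requirement at tract [",
             s, ", ", e, ")")
    r <- seq_chars(read_seq)
    r[(s + 1L):e] <- d[(s + 1L):e]
    paste(r, collapse = "")
}

#' Apply AID-biased somatic hypermutation
#'
#' Independent per-base substitution with probability
#' `shm_rate * hotspot_multiplier` inside WRCY/RGYW occurrences and
#' `shm_rate` elsewhere (capped at 1); the substituted base is chosen
#' uniformly among the three alternatives. Deterministic given the seed;
#' when `seed` is `NULL` the current RNG stream is used (so a repertoire
#' simulation threads one documented generator through all reads).
#'
#' @param read_seq Ungapped nucleotide string.
#' @param shm_rate Per-base substitution probability.
#' @param hotspot_multiplier Relative rate inside AID hotspots.
#' @param seed Optional integer seed.
#' @return Mutated sequence.
#' @export
apply_shm <- function(read_seq, shm_rate, hotspot_multiplier = 1, seed = NULL) {
    run <- function() {
        if (shm_rate == 0) return(read_seq)
        ch <- seq_chars(read_seq)
        rate <- rep(shm_rate, length(ch))
        hs <- scan_aid_motifs(read_seq, classes = c("WRCY", "RGYW"))
        for (k in seq_len(nrow(hs)))
            rate[(hs$start[k] + 1L):hs$end[k]] <- shm_rate * hotspot_multiplier
        rate <- pmin(rate, 1)
        hit <- which(runif(length(ch)) < rate & ch %in% DNA_BASES)
        if (length(hit) > 0L) ch <- mutate_positions(ch, hit)
        paste(ch, collapse = "")
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate an annotated repertoire with ground truth
#'
#' Draws `n_reads` reads: each picks a functional acceptor uniformly,
#' carries one implanted conversion tract with probability
#' `implant_fraction` (donor pseudogene upstream of the acceptor with
#' probability `1 - downstream_donor_fraction`, chosen among the implant
#' sites of pseudogenes derived from that acceptor), then undergoes
#' AID-biased SHM. Fully reproducible from (config, seed).
#'
#' @param config A [sim_config()].
#' @param locus Optional pre-built [simulate_germline_locus()] result; by
#'   default the locus is generated from the same seed.
#' @return list of class `sim_repertoire`: `reads` (AIRR-style data.frame:
#'   `sequence_id`, `sample_id`, `sequence`, `v_call`, `productive`,
#'   `duplicate_count`), `truth` (data.frame: `read_id`, `acceptor`,
#'   `donor`, `tract_start`, `tract_end`, `donor_offset`,
#'   `is_upstream_donor`, `is_silent`, `segment_unique`), `locus`.
#' @export
simulate_repertoire <- function(config, locus = NULL) {
    stopifnot(inherits(config, "sim_config"))
    with_seed(config$seed, {
        if (is.null(locus)) locus <- build_locus(config)
        set <- locus$set
        sites <- locus$sites
        g <- set$genes
        f_names <- set$functional_names
        reads <- vector("list", config$n_reads)
        truth <- vector("list", config$n_reads)
        for (i in seq_len(config$n_reads)) {
            acc <- sample(f_names, 1L)
            acc_seq <- g$ungapped_seq[match(acc, g$name)]
            sq <- acc_seq
            tr <- NULL
            if (runif(1) < config$implant_fraction) {
                want_up <- runif(1) >= config$downstream_donor_fraction
                cand <- which(sites$source == acc & sites$is_upstream == want_up)
                if (length(cand) == 0L)
                    stop("no ", if (want_up) "upstream" else "downstream",
                         " implant site for acceptor ", acc)
                s <- sites[cand[sample.int(length(cand), 1L)], ]
                donor_seq <- g$ungapped_seq[match(s$donor, g$name)]
                sq <- implant_conversion(sq, acc_seq, donor_seq,
                                         s$core_start, s$core_len,
                                         config$anchor_5p, config$anchor_3p)
                tr <- data.frame(read_id = sprintf("read%06d", i),
                                 acceptor = acc, donor = s$donor,
                                 tract_start = s$core_start,
                                 tract_end = s$core_start + s$core_len,
                                 donor_offset = s$core_start,
                                 is_upstream_donor = s$is_upstream,
                                 is_silent = s$is_silent,
                                 segment_unique = s$segment_unique,
                                 stringsAsFactors = FALSE)
            }
            if (config$shm_rate > 0)
                sq <- apply_shm(sq, config$shm_rate, config$hotspot_multiplier)
            reads[[i]] <- data.frame(sequence_id = sprintf("read%06d", i),
                                     sample_id = config$sample_id,
                                     sequence = sq,
                                     v_call = paste0(acc, "*01"),
                                     productive = TRUE,
                                     duplicate_count = 1L,
                                     stringsAsFactors = FALSE)
            truth[[i]] <- tr
        }
        truth <- truth[!vapply(truth, is.null, logical(1))]
        truth <- if (length(truth) == 0L)
            data.frame(read_id = character(0), acceptor = character(0),
                       donor = character(0), tract_start = integer(0),
                       tract_end = integer(0), donor_offset = integer(0),
                       is_upstream_donor = logical(0), is_silent = logical(0),
                       segment_unique = logical(0), stringsAsFactors = FALSE)
        else do.call(rbind, truth)
        structure(list(reads = do.call(rbind, reads), truth = truth,
                       locus = structure(c(locus, list(config = config)),
                                         class = "sim_locus")),
                  class = "sim_repertoire")
    })
}

#' Score detection recovery against simulation ground truth
#'
#' A truth record is recovered when some event on the same read overlaps
#' its tract interval by at least one nucleotide. Silent conversions
#' (donor segment equal to the acceptor segment) cannot be observed and
#' are excluded from the sensitivity denominator, reported separately.
#'
#' @param truth Ground-truth data.frame from [simulate_repertoire()].
#' @param events Event data.frame (normally after [gene_order_filter()]).
#' @return list with `sensitivity` (recovered / non-silent truth),
#'   `precision` (events overlapping some truth tract / all events),
#'   `donor_accuracy` (recovered records whose overlapping events name the
#'   true donor), `n_truth`, `n_silent`, `n_events`. Metrics are `NA` when
#'   their denominator is empty.
#' @export
evaluate_recovery <- function(truth, events) {
    nonsilent <- truth[!truth$is_silent, , drop = FALSE]
    n_t <- nrow(nonsilent)
    rec <- logical(n_t)
    donor_ok <- logical(n_t)
    for (k in seq_len(n_t)) {
        tr <- nonsilent[k, ]
        ev <- events[events$sequence_id == tr$read_id &
                     events$gc_block_start < tr$tract_end &
                     events$gc_block_end > tr$tract_start, , drop = FALSE]
        rec[k] <- nrow(ev) > 0L
        donor_ok[k] <- rec[k] && any(ev$gc_donor == tr$donor)
    }
    n_e <- nrow(events)
    ev_match <- logical(n_e)
    for (k in seq_len(n_e)) {
        e <- events[k, ]
        ev_match[k] <- any(truth$read_id == e$sequence_id &
                           truth$tract_start < e$gc_block_end &
                           truth$tract_end > e$gc_block_start)
    }
    list(sensitivity = if (n_t > 0L) mean(rec) else NA_real_,
         precision = if (n_e > 0L) mean(ev_match) else NA_real_,
         donor_accuracy = if (sum(rec) > 0L) sum(donor_ok) / sum(rec)
                          else NA_real_,
         n_truth = nrow(truth), n_silent = sum(truth$is_silent),
         n_events = n_e)
}

#' Write a simulated locus / repertoire to disk
#'
#' Writes `germline.fasta` (headers `name*allele|functionality`),
#' `order.tsv`, `repertoire.tsv` (AIRR-style) and `truth.tsv` into
#' `out_dir`.
#'
#' @param sim A `sim_repertoire`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    set <- sim$locus$set
    g <- set$genes
    fa <- Biostrings::BStringSet(g$gapped_seq)
    names(fa) <- paste0(g$name, ifelse(is.na(g$allele), "", g$allele),
                        "|", g$functionality)
    Biostrings::writeXStringSet(fa, file.path(out_dir, "germline.fasta"))
    ord <- set$order
    utils::write.table(data.frame(gene_name = ord$gene_name,
                                  position = ord$rank, strand = ord$strand),
                       file.path(out_dir, "order.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$reads, file.path(out_dir, "repertoire.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out_dir)
}
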