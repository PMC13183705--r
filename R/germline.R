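#' Load a germline gene set and locus gene-order table
#'
#' Reads an IMGT-gapped nucleotide FASTA of germline V genes together with a
#' tab-separated locus gene-order table and returns a validated
#' `germline_set` object. FASTA headers must follow
#' `name*allele|functionality` (allele optional), where functionality is one
#' of `F` (functional), `ORF` or `P` (pseudogene). Sequences may contain `.`
#' for IMGT alignment gaps and `N` for ambiguous bases.
#'
#' The order table (columns `gene_name`, `position`, optional `strand`)
#' gives the physical layout of the locus; positions are converted to
#' strictly increasing internal ranks in the 5'->3' direction. Gene order is
#' taken only from this table, never inferred from gene-name numbering.
#' Genes absent from the table are retained but flagged unusable for the
#' gene-order filter. Alleles of one gene share the gene-level rank.
#'
#' @param fasta_path Path to the germline FASTA.
#' @param order_path Path to the gene-order TSV.
#' @param leader_path Optional FASTA of leader (signal peptide) sequences
#'   with headers matching `name*allele`; used by [leader_identity_suffix()].
#' @return A `germline_set`: list with `genes` (data.frame: `name`,
#'   `allele`, `functionality`, `gapped_seq`, `ungapped_seq`, `leader_seq`,
#'   `family`, `in_order`), `order` (data.frame: `gene_name`, `rank`,
#'   `strand`), `functional_names` and `pseudogene_names` (character
#'   vectors of gene-level names, disjoint; `ORF` genes belong to neither).
#' @export
load_germline_set <- function(fasta_path, order_path, leader_path = NULL) {
    fa <- Biostrings::readBStringSet(fasta_path)
    if (length(fa) == 0L) stop("empty germline FASTA: ", fasta_path)
    headers <- names(fa)
    seqs <- toupper(as.character(fa))
    bad <- grepl("[^ACGTN.]", seqs)
    if (any(bad))
        stop("invalid characters in FASTA record '", headers[which(bad)[1]],
             "' (allowed: A,C,G,T,N,.)")

    parts <- strsplit(headers, "|", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        stop("malformed FASTA header (expected 'name*allele|functionality'): '",
             headers[which(lengths(parts) < 2L)[1]], "'")
    name_allele <- vapply(parts, `[[`, "", 1L)
    functionality <- trimws(vapply(parts, `[[`, "", 2L))
    if (!all(functionality %in% c("F", "ORF", "P")))
        stop("functionality label outside {F, ORF, P} in record '",
             headers[which(!functionality %in% c("F", "ORF", "P"))[1]], "'")

    na_parts <- strsplit(name_allele, "*", fixed = TRUE)
    name <- vapply(na_parts, `[[`, "", 1L)
    allele <- vapply(na_parts, function(p) if (length(p) > 1L) paste0("*", p[2L]) else NA_character_, "")
    if (!all(grepl("^[A-Za-z]+[0-9]+-[A-Za-z0-9]+$", name)))
        stop("gene name not parseable as <locus><family>-<localizer>: '",
             name[which(!grepl("^[A-Za-z]+[0-9]+-[A-Za-z0-9]+$", name))[1]], "'")

    key <- paste0(name, ifelse(is.na(allele), "", allele))
    if (anyDuplicated(key))
        stop("duplicate gene+allele record: '", key[duplicated(key)][1], "'")

    leader <- rep(NA_character_, length(name))
    if (!is.null(leader_path)) {
        lf <- Biostrings::readBStringSet(leader_path)
        lmap <- setNames(toupper(as.character(lf)), names(lf))
        hit <- match(key, names(lmap))
        miss <- is.na(hit)
        hit[miss] <- match(name, names(lmap))[miss]
        leader <- unname(lmap[hit])
    }

    genes <- data.frame(
        name = name, allele = allele, functionality = functionality,
        gapped_seq = seqs, ungapped_seq = gsub(".", "", seqs, fixed = TRUE),
        leader_seq = leader, family = sub("-.*$", "", name),
        stringsAsFactors = FALSE, row.names = NULL
    )

    ord <- utils::read.delim(order_path, stringsAsFactors = FALSE)
    if (!all(c("gene_name", "position") %in% names(ord)))
        stop("gene-order table must have columns 'gene_name' and 'position'")
    if (anyDuplicated(ord$gene_name))
        stop("duplicate gene_name in order table: '",
             ord$gene_name[duplicated(ord$gene_name)][1], "'")
    pos <- ord$position
    if (!is.numeric(pos)) pos <- as.numeric(factor(pos, levels = unique(pos)))
    if (anyDuplicated(pos))
        stop("gene-order positions are not unique")
    order_tab <- data.frame(
        gene_name = ord$gene_name,
        rank = as.integer(rank(pos)),
        strand = if ("strand" %in% names(ord)) ord$strand else NA_character_,
        stringsAsFactors = FALSE
    )
    genes$in_order <- genes$name %in% order_tab$gene_name

    functional_names <- unique(genes$name[genes$functionality == "F"])
    pseudogene_names <- unique(genes$name[genes$functionality == "P"])
    if (length(functional_names) == 0L)
        stop("no functional (F) genes in germline set: nothing to detect against")

    structure(list(genes = genes, order = order_tab,
                   functional_names = functional_names,
                   pseudogene_names = pseudogene_names),
              class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
    cat("germline_set:", nrow(x$genes), "records;",
        length(x$functional_names), "functional genes,",
        length(x$pseudogene_names), "pseudogenes;",
        sum(!x$genes$in_order), "gene(s) missing from the order table\n")
    invisible(x)
}

# locus rank of a gene-level name; NA when absent from the order table
gene_rank <- function(set, name) {
    i <- match(name, set$order$gene_name)
    set$order$rank[i]
}

# first matching gene record (optionally a specific allele)
get_gene <- function(set, name, allele = NULL) {
    g <- set$genes
    i <- if (is.null(allele)) which(g$name == name)
         else which(g$name == name & g$allele == allele)
    if (length(i) == 0L) stop("gene not found in germline set: ", name)
    g[i[1L], , drop = FALSE]
}

#' Pseudogenes located 5' (upstream) of a functional gene
#'
#' Returns the pseudogene names whose locus rank is strictly smaller than
#' the rank of `functional_name` (ranks increase 5'->3'). Pseudogenes
#' lacking an order-table entry are never returned. Orientation is stored in
#' the order table but does not alter the result: the filter is purely
#' positional.
#'
#' @param functional_name Gene-level name of a functional gene present in
#'   the order table.
#' @param set A `germline_set`.
#' @return Character vector of pseudogene names (possibly empty).
#' @export
upstream_pseudogenes <- function(functional_name, set) {
    fr <- gene_rank(set, functional_name)
    if (is.na(fr))
        stop("functional gene '", functional_name, "' missing from order table")
    pr <- gene_rank(set, set$pseudogene_names)
    sort(set$pseudogene_names[!is.na(pr) & pr < fr])
}

#' Global-alignment identity between two germline sequences
#'
#' Percent identity from a global affine-gap alignment of the ungapped
#' sequences: matches / alignment columns x 100, with scoring match +1,
#' mismatch 0 and a gap of length L costing `gap_open + L * gap_extend`.
#' Symmetric in its arguments. `N` never counts as a match.
#'
#' @param a,b Nucleotide strings, or one-row gene records carrying an
#'   `ungapped_seq` field.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return Identity percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, gap_open = 2, gap_extend = 1) {
    a <- as_ungapped_seq(a)
    b <- as_ungapped_seq(b)
    if (nchar(a) == 0L || nchar(b) == 0L)
        stop("pairwise_identity: empty sequence")
    al <- cpp_global_align(a, b, 1, 0, gap_open, gap_extend)
    100 * al$n_match / al$aln_len
}

as_ungapped_seq <- function(x) {
    if (is.character(x) && length(x) == 1L)
        return(gsub(".", "", toupper(x), fixed = TRUE))
    if (!is.null(x$ungapped_seq)) return(x$ungapped_seq[[1L]])
    stop("expected a sequence string or a gene record with 'ungapped_seq'")
}

#' Shared leader-region 3' suffix length
#'
#' Length of the longest identical suffix of two leader sequences (their 3'
#' ends, adjacent to the V region); 0 when the final nucleotides differ. A
#' missing leader on either gene is distinguished from 0 and reported as
#' `NA`.
#'
#' @param f,p Leader nucleotide strings or gene records with `leader_seq`.
#' @return Integer suffix length, or `NA_integer_` when a leader is absent.
#' @export
leader_identity_suffix <- function(f, p) {
    lf <- as_leader_seq(f)
    lp <- as_leader_seq(p)
    if (is.na(lf) || is.na(lp)) return(NA_integer_)
    a <- rev(seq_chars(lf))
    b <- rev(seq_chars(lp))
    k <- min(length(a), length(b))
    if (k == 0L) return(0L)
    neq <- which(a[seq_len(k)] != b[seq_len(k)])
    if (length(neq) == 0L) k else neq[1L] - 1L
}

as_leader_seq <- function(x) {
    if (is.character(x) && length(x) == 1L) return(toupper(x))
    if (!is.null(x$leader_seq)) return(x$leader_seq[[1L]])
    NA_character_
}
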