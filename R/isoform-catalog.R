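# From raw 3' ends to polyA sites and a ranked 3'UTR isoform catalog.

#' Merge 3' ends within the precision window into polyA sites
#'
#' Single-linkage clustering: adjacent ends whose gap is strictly less than
#' `window` nt join the same site, transitively. The representative end of a
#' site is its distal-most member. Chained clusters may span more than
#' `window` nt; that is a documented property of single-linkage.
#'
#' @param ends Numeric vector of 3' end positions (nt after stop),
#'   any order.
#' @param window Precision window (nt); merging applies at gaps `< window`
#'   (strict, default 100).
#' @return Tibble of sites ordered by position: `site`, `n_members`,
#'   `members` (list-column), `span_start`, `span_end`,
#'   `representative_end`, `very_short`.
#' @export
merge_ends <- function(ends, window = 100) {
  ends <- sort(as.numeric(ends))
  if (length(ends) == 0) {
    return(tibble::tibble(site = integer(), n_members = integer(),
                          members = list(), span_start = numeric(),
                          span_end = numeric(), representative_end = numeric(),
                          very_short = logical()))
  }
  new_site <- c(TRUE, diff(ends) >= window)
  grp <- cumsum(new_site)
  members <- split(ends, grp)
  tibble::tibble(
    site = seq_along(members),
    n_members = lengths(members),
    members = unname(members),
    span_start = vapply(members, min, numeric(1), USE.NAMES = FALSE),
    span_end = vapply(members, max, numeric(1), USE.NAMES = FALSE),
    representative_end = vapply(members, max, numeric(1), USE.NAMES = FALSE),
    very_short = vapply(members, max, numeric(1), USE.NAMES = FALSE) < 100)
}

#' Merge detected ends per gene
#'
#' @param ends Tibble of detected ends with `gene_id` and `utr_pos` (from
#'   [detect_ends()]).
#' @param window Precision window (nt).
#' @return Tibble of per-gene polyA sites with a `gene_id` column.
#' @export
merge_gene_ends <- function(ends, window = 100) {
  if (nrow(ends) == 0) {
    out <- merge_ends(numeric(0), window)
    out$gene_id <- character(0)
    return(out[, c("gene_id", setdiff(names(out), "gene_id"))])
  }
  out <- dplyr::group_by(ends, .data$gene_id)
  out <- dplyr::reframe(out, merge_ends(.data$utr_pos, window))
  tibble::as_tibble(out)
}

# forbidden genomic interval of a potential fusion partner: CDS for
# non-target genes, 5'UTR plus CDS for target-family genes
.forbidden_span <- function(g) {
  if (g$is_target) {
    if (g$strand == "+") c(g$gene_start, g$cds_end) else c(g$cds_start, g$gene_end)
  } else {
    c(g$cds_start, g$cds_end)
  }
}

#' Discard fusion-transcript isoforms
#'
#' An isoform whose genomic span (stop codon to representative end) runs into
#' another gene — the CDS of any gene, or the 5'UTR/CDS of a neighboring
#' target-family gene — is an ambiguous fusion call and is discarded. With
#' stranded coverage only same-strand genes can be fused; with unstranded
#' coverage opposite-strand overlap is also discarded, because independent
#' transcripts on the two strands superpose in the coverage.
#'
#' @param sites Per-gene polyA site tibble (from [merge_gene_ends()]).
#' @param genes Gene-model tibble (all genes of the region set).
#' @param stranded Whether the underlying coverage was strand-specific.
#' @return List with `kept` (sites tibble) and `discarded` (tibble of
#'   `gene_id`, `site`, `offending_gene`).
#' @export
discard_fusions <- function(sites, genes, stranded = TRUE) {
  if (nrow(sites) == 0) {
    return(list(kept = sites,
                discarded = tibble::tibble(gene_id = character(), site = integer(),
                                           offending_gene = character())))
  }
  discards <- list()
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$gene_id == sites$gene_id[i], ]
    if (nrow(g) == 0) stop("unknown gene in site table: ", sites$gene_id[i],
                           call. = FALSE)
    rep_end <- sites$representative_end[i]
    span <- if (g$strand == "+") {
      c(g$stop_anchor, g$stop_anchor + rep_end)
    } else {
      c(g$stop_anchor - rep_end, g$stop_anchor)
    }
    others <- genes[genes$gene_id != g$gene_id & genes$chrom == g$chrom, ]
    if (stranded) others <- others[others$strand == g$strand, ]
    for (j in seq_len(nrow(others))) {
      f <- .forbidden_span(others[j, ])
      if (span[1] < f[2] && f[1] < span[2]) {
        keep[i] <- FALSE
        discards[[length(discards) + 1L]] <- tibble::tibble(
          gene_id = g$gene_id, site = sites$site[i],
          offending_gene = others$gene_id[j])
        break
      }
    }
  }
  list(kept = sites[keep, , drop = FALSE],
       discarded = if (length(discards) > 0) dplyr::bind_rows(discards) else
         tibble::tibble(gene_id = character(), site = integer(),
                        offending_gene = character()))
}

#' Rank polyA sites into a 3'UTR isoform catalog
#'
#' Isoforms are ranked by length (representative end, nt after stop)
#' ascending. A gene with a single site carries an sUTR; with several, the
#' shortest is the pUTR and the rest are dUTR1, dUTR2, ... in increasing
#' length. Genes with more than `max_stats_isoforms` isoforms stay in the
#' catalog but are flagged out of the summary statistics.
#'
#' @param sites Per-gene polyA site tibble (post-merge, post-fusion-filter).
#' @param max_stats_isoforms Isoform count above which a gene is excluded
#'   from summary statistics (default 5).
#' @return Tibble: `gene_id`, `rank`, `length`, `category`, `n_isoforms`,
#'   `span_start`, `span_end`, `very_short`, `in_stats`.
#' @export
catalog_isoforms <- function(sites, max_stats_isoforms = 5) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(gene_id = character(), rank = integer(),
                          length = numeric(), category = character(),
                          n_isoforms = integer(), span_start = numeric(),
                          span_end = numeric(), very_short = logical(),
                          in_stats = logical()))
  }
  out <- dplyr::group_by(sites, .data$gene_id)
  out <- dplyr::arrange(out, .data$representative_end, .by_group = TRUE)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), n_isoforms = dplyr::n())
  out <- dplyr::ungroup(out)
  out$length <- out$representative_end
  out$category <- utr_category(out$rank, out$n_isoforms)
  out$in_stats <- out$n_isoforms <= max_stats_isoforms
  out[, c("gene_id", "rank", "length", "category", "n_isoforms",
          "span_start", "span_end", "very_short", "in_stats")]
}

#' Isoform category label from rank and isoform count
#'
#' @param rank Length rank (1 = shortest).
#' @param n Number of isoforms of the gene.
#' @return `"sUTR"` when `n == 1`, `"pUTR"` for rank 1 of a multi-isoform
#'   gene, else `"dUTR<rank-1>"`.
#' @export
utr_category <- function(rank, n) {
  k <- max(length(rank), length(n))
  rank <- rep_len(rank, k)
  n <- rep_len(n, k)
  ifelse(n == 1, "sUTR", ifelse(rank == 1, "pUTR", paste0("dUTR", rank - 1)))
}
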