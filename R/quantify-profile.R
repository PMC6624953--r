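# Segment-subtraction quantification of 3'UTR isoforms and the P1-P4
# quantitative profiles.
#
# With nested isoforms, every transcript covering segment i (the region
# between adjacent 3' ends) also covers all segments upstream of it, so the
# mean depth of segment i equals the summed abundance of the isoforms ending
# at or beyond its distal boundary. Differencing adjacent segment depths and
# dividing by the depth of the first segment therefore recovers each
# isoform's share of the gene's mRNA population.

#' Mean depth of the inter-end segments
#'
#' Segments tile the 3'UTR: segment 1 runs from the stop codon to the most
#' proximal 3' end, segment i between adjacent ends. Each mean is the
#' difference of cumulative counts at the segment boundaries divided by the
#' segment length; zero-depth bases inside retained gaps count as zeros.
#'
#' @param v Depth vector in 3'UTR coordinates (padded with zeros if shorter
#'   than the most distal end).
#' @param ends Numeric vector of representative 3' end positions, strictly
#'   increasing.
#' @return Tibble: `index`, `start`, `end`, `length`, `mean_depth`.
#' @export
segment_depths <- function(v, ends) {
  ends <- as.numeric(ends)
  if (length(ends) == 0) stop("no 3' ends supplied", call. = FALSE)
  if (any(diff(ends) <= 0)) stop("duplicate or unsorted 3' ends", call. = FALSE)
  if (ends[1] < 1) stop("3' end before position 1", call. = FALSE)
  n <- max(ends)
  if (length(v) < n) v <- c(v, numeric(n - length(v)))
  cum <- c(0, cumsum(as.numeric(v)))
  starts <- c(1, head(ends, -1) + 1)
  tibble::tibble(index = seq_along(ends), start = starts, end = ends,
                 length = ends - starts + 1,
                 mean_depth = (cum[ends + 1] - cum[starts]) / (ends - starts + 1))
}

#' Relative abundance of nested 3'UTR isoforms
#'
#' For segment depths `d[1..n]`, the raw abundance of isoform i < n is
#' `(d[i] - d[i+1]) / d[1]` and of the longest isoform `d[n] / d[1]`.
#' Coverage noise can invert a step; negative raw values are clamped to zero
#' and the vector renormalized to sum 1. Both raw and normalized values are
#' returned.
#'
#' @param d Numeric vector of segment mean depths (from [segment_depths()]);
#'   `d[1]` must be positive.
#' @return Tibble: `index`, `raw`, `ra` (normalized fractions summing to 1).
#' @export
relative_abundance <- function(d) {
  d <- as.numeric(d)
  if (length(d) == 0 || d[1] <= 0) {
    stop("gene unquantifiable: no coverage in the first segment", call. = FALSE)
  }
  raw <- c(-diff(d), d[length(d)]) / d[1]
  clamped <- pmax(raw, 0)
  if (sum(clamped) == 0) stop("gene unquantifiable: degenerate abundances",
                              call. = FALSE)
  tibble::tibble(index = seq_along(d), raw = raw, ra = clamped / sum(clamped))
}

#' Classify a gene's quantitative APA profile
#'
#' P1: a single 3'UTR (no APA). P2: the proximal isoform exceeds 80% of the
#' mRNAs (strictly). P3: proximal at most 80% and the summed abundance of
#' the most distal isoforms (third-shortest onward) strictly under 10%
#' (typically two main isoforms). P4: that distal sum reaches 10% (three or
#' more isoforms of quantitative importance).
#'
#' @param ra Normalized abundance vector ordered by isoform length.
#' @return `"P1"`, `"P2"`, `"P3"` or `"P4"`.
#' @export
classify_profile <- function(ra) {
  n <- length(ra)
  if (n == 0) stop("empty abundance vector", call. = FALSE)
  if (n == 1) return("P1")
  if (ra[1] > 0.80) return("P2")
  distal <- if (n >= 3) sum(ra[3:n]) else 0
  if (distal < 0.10) "P3" else "P4"
}

#' Quantify one gene's isoforms from its 3'UTR coverage
#'
#' @param v Depth vector in 3'UTR coordinates.
#' @param sites PolyA site tibble for the gene (post-merge, post-filter).
#' @return One-row tibble: `n_isoforms`, `ra` (list-column), `raw`
#'   (list-column), `profile`, `any_very_short` (reliability flag: a very
#'   short proximal isoform makes its abundance estimate unreliable).
#' @export
quantify_gene <- function(v, sites) {
  segs <- segment_depths(v, sites$representative_end)
  ab <- relative_abundance(segs$mean_depth)
  tibble::tibble(n_isoforms = nrow(ab), ra = list(ab$ra), raw = list(ab$raw),
                 profile = classify_profile(ab$ra),
                 any_very_short = any(sites$very_short))
}

#' Summary statistics of 3'UTR isoform lengths
#'
#' Restricted to genes within the isoform-count cap (`in_stats`). Reports
#' median lengths per isoform group (sUTR, pUTR, and all dUTRs pooled), the
#' per-gene dUTR1/pUTR length ratio and its median, and the distribution of
#' isoform counts per gene.
#'
#' @param catalog Isoform catalog tibble from [catalog_isoforms()].
#' @return List of tibbles: `medians` (`group`, `n`, `median_length`),
#'   `ratio` (`gene_id`, `dutr1_putr_ratio`) with attribute
#'   `median_ratio`, and `bins` (`n_isoforms`, `n_genes`).
#' @export
length_stats <- function(catalog) {
  cat_ok <- catalog[catalog$in_stats, , drop = FALSE]
  grp <- ifelse(cat_ok$category == "sUTR", "sUTR",
                ifelse(cat_ok$category == "pUTR", "pUTR", "dUTR"))
  medians <- tibble::as_tibble(dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, length = cat_ok$length), .data$group),
    n = dplyr::n(), median_length = stats::median(.data$length), .groups = "drop"))
  pu <- cat_ok[cat_ok$category == "pUTR", c("gene_id", "length")]
  du <- cat_ok[cat_ok$category == "dUTR1", c("gene_id", "length")]
  ratio <- dplyr::inner_join(pu, du, by = "gene_id", suffix = c("_p", "_d"))
  ratio <- tibble::tibble(gene_id = ratio$gene_id,
                          dutr1_putr_ratio = ratio$length_d / ratio$length_p)
  attr(ratio, "median_ratio") <- if (nrow(ratio) > 0) {
    stats::median(ratio$dutr1_putr_ratio)
  } else {
    NA_real_
  }
  per_gene <- dplyr::distinct(cat_ok[, c("gene_id", "n_isoforms")])
  bins <- tibble::as_tibble(dplyr::count(per_gene, .data$n_isoforms,
                                         name = "n_genes"))
  list(medians = medians, ratio = ratio, bins = bins)
}
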