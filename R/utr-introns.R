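# Splicing inside annotated 3'UTRs from splice-junction evidence.
#
# Junction extraction from alignments is upstream of this package; here the
# junction records are filtered, assigned to 3'UTR spans and classified as
# obligatory (the intron is always excised: no retained coverage) or
# optional (spliced and unspliced forms coexist: intronic coverage remains).

#' Read splice junctions
#'
#' Accepts 12-column BED (blocks encode the anchors; the intron is the
#' inter-block gap; `score` = supporting read depth) or a 6-column TSV
#' (`chrom`, `start`, `end`, `name`, `depth`, `strand` with `start`/`end`
#' the 0-based half-open intron interval).
#'
#' @param path Junction file path.
#' @return Tibble: `chrom`, `donor`, `acceptor` (0-based half-open intron
#'   interval), `strand`, `depth`.
#' @export
read_junctions <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    return(tibble::tibble(chrom = character(), donor = numeric(),
                          acceptor = numeric(), strand = character(),
                          depth = numeric()))
  }
  ncol <- length(strsplit(first, "\t")[[1]])
  if (ncol >= 12) {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- GenomicRanges::width(gr$blocks)
    donor <- GenomicRanges::start(gr) - 1L + vapply(bl, `[`, integer(1), 1)
    acceptor <- GenomicRanges::end(gr) -
      vapply(bl, function(x) x[length(x)], integer(1))
    tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                   donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                   strand = as.character(GenomicRanges::strand(gr)),
                   depth = as.numeric(gr$score))
  } else {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "depth", "strand"),
                         col_types = "cddcdc", comment = "#", progress = FALSE)
    tibble::tibble(chrom = x$chrom, donor = x$start, acceptor = x$end,
                   strand = x$strand, depth = x$depth)
  }
}

#' Filter junction records
#'
#' Keeps junctions with depth strictly greater than `min_depth` and, for
#' duplicate (chrom, donor, acceptor) records, the best-scoring one.
#'
#' @param junctions Junction tibble from [read_junctions()].
#' @param min_depth Depth threshold, strict (default 1: depth > 1 kept).
#' @return Filtered tibble.
#' @export
filter_junctions <- function(junctions, min_depth = 1) {
  x <- junctions[junctions$depth > min_depth, , drop = FALSE]
  x <- dplyr::arrange(x, .data$chrom, .data$donor, .data$acceptor,
                      dplyr::desc(.data$depth))
  dplyr::distinct(x, .data$chrom, .data$donor, .data$acceptor,
                  .keep_all = TRUE)
}

#' Classify a 3'UTR intron as obligatory or optional
#'
#' A junction strictly contained in a gene's 3'UTR span is obligatory when
#' the mean coverage inside the intron is at most `retention_threshold`
#' (the intron is never retained) and optional otherwise (both spliced and
#' unspliced transcripts are present). A junction not contained in the span
#' is mode `"none"`.
#'
#' @param junction One-row junction tibble.
#' @param utr_span Length-2 numeric, the gene's 3'UTR genomic span (0-based
#'   half-open).
#' @param track `coverage_track` covering the junction.
#' @param retention_threshold Mean intronic depth at or under which the
#'   intron counts as always-excised (default 1).
#' @return `"obligatory"`, `"optional"` or `"none"`.
#' @export
classify_intron <- function(junction, utr_span, track, retention_threshold = 1) {
  if (!(junction$donor > utr_span[1] && junction$acceptor < utr_span[2])) {
    return("none")
  }
  mean_depth <- track_sum(track, junction$donor, junction$acceptor) /
    (junction$acceptor - junction$donor)
  if (mean_depth <= retention_threshold) "obligatory" else "optional"
}

#' Assign and classify junctions within annotated 3'UTRs
#'
#' @param junctions Filtered junction tibble.
#' @param catalog Isoform catalog (for each gene's distal-most length).
#' @param genes Gene-model tibble.
#' @param tracks Coverage-track tibble from [load_bedgraph()].
#' @param retention_threshold See [classify_intron()].
#' @return Junction tibble with `gene_id` and `mode` columns; junctions
#'   contained in no 3'UTR keep `gene_id = NA`, `mode = "none"`.
#' @export
annotate_introns <- function(junctions, catalog, genes, tracks,
                             retention_threshold = 1) {
  spans <- dplyr::summarise(dplyr::group_by(catalog, .data$gene_id),
                            max_len = max(.data$length), .groups = "drop")
  spans <- dplyr::left_join(spans, genes, by = "gene_id")
  spans$utr_start <- ifelse(spans$strand == "+", spans$stop_anchor,
                            spans$stop_anchor - spans$max_len)
  spans$utr_end <- ifelse(spans$strand == "+", spans$stop_anchor + spans$max_len,
                          spans$stop_anchor)
  junctions$gene_id <- NA_character_
  junctions$mode <- "none"
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    hit <- spans[spans$chrom == j$chrom &
                   (j$strand == "." | spans$strand == j$strand) &
                   spans$utr_start < j$donor & j$acceptor < spans$utr_end, ]
    if (nrow(hit) == 0) next
    hit <- hit[1, ]
    tr <- NULL
    for (k in seq_len(nrow(tracks))) {
      t <- tracks$track[[k]]
      if (t$chrom == j$chrom && t$start <= j$donor && j$acceptor <= t$end) {
        tr <- t
        break
      }
    }
    if (is.null(tr)) next
    junctions$gene_id[i] <- hit$gene_id
    junctions$mode[i] <- classify_intron(j, c(hit$utr_start, hit$utr_end), tr,
                                         retention_threshold)
  }
  junctions
}
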