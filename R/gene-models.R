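# Gene models, stop-codon anchors, and target-family mask regions.
#
# All internal coordinates are 0-based half-open; GTF (1-based inclusive) and
# BED (0-based half-open) are converted at the I/O boundary. The stop anchor
# is the half-open boundary immediately 3' of the stop codon in mRNA
# orientation, so 3'UTR position 1 is the first transcribed base after the
# stop: for a + strand gene at anchor a that base is [a, a+1); for a - strand
# gene it is [a-1, a).

#' Read a per-gene curation override table
#'
#' Overrides resolve the hand-curated special cases that a clustered gene
#' family accumulates: transcripts to discard, genes to drop outright, genes
#' annotated at two independent loci, and mask regions whose span must be
#' forced.
#'
#' @param path Path to a tab-separated file with columns `gene_id`, `action`
#'   (`drop_transcript`, `drop_gene`, `set_alt_locus`, `force_region_span`)
#'   and `payload` (action-specific: a transcript id, empty, empty, or a
#'   `chrom:start-end` span in 0-based half-open coordinates).
#' @return A tibble with those three columns.
#' @export
read_curation <- function(path) {
  cur <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  required <- c("gene_id", "action")
  if (!all(required %in% names(cur))) {
    stop("curation file must have columns gene_id and action", call. = FALSE)
  }
  if (!"payload" %in% names(cur)) cur$payload <- NA_character_
  known <- c("drop_transcript", "drop_gene", "set_alt_locus", "force_region_span")
  bad <- setdiff(unique(cur$action), known)
  if (length(bad) > 0) {
    stop("unknown curation action(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(cur[, c("gene_id", "action", "payload")])
}

#' Parse gene models from a GTF annotation
#'
#' Builds one gene model per gene (or per curated locus): the CDS envelope —
#' the union span from the 5'-most start codon to the 3'-most stop codon over
#' all isoforms — a strand-aware stop-codon anchor, and a target-family flag.
#' Genes without any CDS feature (typically pseudogenes) are skipped and
#' reported in the `skipped` attribute of the result.
#'
#' @param gtf_path Path to a GTF file (GENCODE dialect: `CDS`, `stop_codon`
#'   and `exon` features with `gene_id`/`gene_name`/`transcript_id`
#'   attributes).
#' @param target_pattern Regular expression applied to `gene_name` (falling
#'   back to `gene_id`) deciding family membership, e.g. `"^Olfr"`.
#' @param curation Optional curation tibble (see [read_curation()]) or a path
#'   to one. `drop_transcript`/`drop_gene` are applied before anchors are
#'   derived; `set_alt_locus` splits a gene whose transcripts occupy two
#'   disjoint CDS clusters into independent loci suffixed `@1`, `@2`, ...
#' @return A tibble with one row per gene model: `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `cds_start`, `cds_end` (0-based half-open envelope,
#'   stop codon included), `stop_anchor`, `gene_start`, `gene_end` (exon
#'   envelope), `is_target`. Attributes: `skipped` (tibble of gene_id,
#'   reason), `unused_overrides`.
#' @export
parse_gene_models <- function(gtf_path, target_pattern = "^Olfr", curation = NULL) {
  if (is.character(curation)) curation <- read_curation(curation)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  feat <- as.data.frame(gr)
  needed <- c("type", "gene_id")
  if (!all(needed %in% names(feat))) {
    stop("GTF is missing gene_id attributes", call. = FALSE)
  }
  if (!"gene_name" %in% names(feat)) feat$gene_name <- feat$gene_id
  if (!"transcript_id" %in% names(feat)) feat$transcript_id <- NA_character_
  feat <- tibble::as_tibble(feat[, c("seqnames", "start", "end", "strand", "type",
                                     "gene_id", "gene_name", "transcript_id")])
  names(feat)[1] <- "chrom"
  feat$chrom <- as.character(feat$chrom)
  feat$strand <- as.character(feat$strand)
  feat$type <- as.character(feat$type)
  # to 0-based half-open
  feat$start <- feat$start - 1L

  skipped <- tibble::tibble(gene_id = character(), reason = character())
  used_override <- logical(if (is.null(curation)) 0 else nrow(curation))

  if (!is.null(curation)) {
    drops <- curation[curation$action == "drop_transcript", ]
    if (nrow(drops) > 0) {
      hit <- feat$transcript_id %in% drops$payload
      used_override[curation$action == "drop_transcript"] <-
        drops$payload %in% feat$transcript_id
      feat <- feat[!hit, ]
    }
    gdrops <- curation[curation$action == "drop_gene", ]
    if (nrow(gdrops) > 0) {
      hit <- feat$gene_id %in% gdrops$gene_id | feat$gene_name %in% gdrops$gene_id
      used_override[curation$action == "drop_gene"] <-
        gdrops$gene_id %in% c(feat$gene_id, feat$gene_name)
      dropped_ids <- unique(feat$gene_id[hit])
      if (length(dropped_ids) > 0) {
        skipped <- dplyr::bind_rows(skipped, tibble::tibble(
          gene_id = dropped_ids, reason = "curation: drop_gene"))
      }
      feat <- feat[!hit, ]
    }
  }

  alt_locus_ids <- character()
  if (!is.null(curation)) {
    alt <- curation[curation$action == "set_alt_locus", ]
    alt_locus_ids <- alt$gene_id
    used_override[curation$action == "set_alt_locus"] <-
      alt$gene_id %in% c(feat$gene_id, feat$gene_name)
  }

  models <- list()
  multi_stop <- character()
  for (gid in unique(feat$gene_id)) {
    gf <- feat[feat$gene_id == gid, ]
    gname <- gf$gene_name[1]
    cds <- gf[gf$type %in% c("CDS", "stop_codon"), ]
    if (nrow(cds) == 0) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        gene_id = gid, reason = "no CDS feature (pseudogene?)"))
      next
    }
    split_loci <- (gid %in% alt_locus_ids) || (gname %in% alt_locus_ids)
    loci <- if (split_loci) .split_cds_loci(cds) else list(cds)
    for (k in seq_along(loci)) {
      lc <- loci[[k]]
      lid <- if (length(loci) > 1) paste0(gid, "@", k) else gid
      gx <- gf[gf$transcript_id %in% unique(lc$transcript_id) |
                 is.na(gf$transcript_id), ]
      exons <- gx[gx$type == "exon", ]
      strand <- lc$strand[1]
      cds_start <- min(lc$start)
      cds_end <- max(lc$end)
      anchor <- .stop_anchors(lc, strand)
      if (length(anchor) > 1) {
        multi_stop <- c(multi_stop, lid)
        next
      }
      models[[length(models) + 1L]] <- tibble::tibble(
        gene_id = lid, gene_name = gname, chrom = lc$chrom[1], strand = strand,
        cds_start = cds_start, cds_end = cds_end, stop_anchor = anchor,
        gene_start = if (nrow(exons) > 0) min(exons$start) else cds_start,
        gene_end = if (nrow(exons) > 0) max(exons$end) else cds_end,
        is_target = grepl(target_pattern, gname) || grepl(target_pattern, gid))
    }
  }
  if (length(multi_stop) > 0) {
    stop("irreconcilable multiple stop anchors (resolve via curation): ",
         paste(multi_stop, collapse = ", "), call. = FALSE)
  }
  out <- if (length(models) > 0) dplyr::bind_rows(models) else tibble::tibble(
    gene_id = character(), gene_name = character(), chrom = character(),
    strand = character(), cds_start = integer(), cds_end = integer(),
    stop_anchor = integer(), gene_start = integer(), gene_end = integer(),
    is_target = logical())
  out <- dplyr::arrange(out, .data$chrom, .data$cds_start)
  attr(out, "skipped") <- skipped
  if (!is.null(curation)) {
    attr(out, "unused_overrides") <- curation[!used_override &
                                                curation$action != "force_region_span", ]
  }
  out
}

# distinct stop anchors for a set of CDS/stop_codon features of one locus
.stop_anchors <- function(cds, strand) {
  sc <- cds[cds$type == "stop_codon", ]
  if (nrow(sc) > 0) {
    per_tx <- split(sc, sc$transcript_id)
    anch <- vapply(per_tx, function(x) {
      if (strand == "+") max(x$end) else min(x$start)
    }, numeric(1))
    return(sort(unique(anch)))
  }
  # no stop_codon features: infer from the CDS envelope 3' edge
  if (strand == "+") max(cds$end) else min(cds$start)
}

# cluster one gene's CDS features into disjoint genomic loci
.split_cds_loci <- function(cds) {
  ir <- IRanges::reduce(IRanges::IRanges(cds$start + 1L, cds$end))
  if (length(ir) <= 1) return(list(cds))
  idx <- S4Vectors::subjectHits(IRanges::findOverlaps(
    IRanges::IRanges(cds$start + 1L, cds$end), ir))
  # assign each transcript to the locus holding most of its CDS
  tx_locus <- tapply(idx, cds$transcript_id, function(i) as.integer(names(sort(table(i), decreasing = TRUE))[1]))
  lapply(sort(unique(tx_locus)), function(k) {
    cds[cds$transcript_id %in% names(tx_locus)[tx_locus == k], ]
  })
}

#' Build target-family mask regions
#'
#' Groups runs of consecutive target-family CDSs with no intervening
#' non-target CDS into regions running from the proximal end of the closest
#' upstream non-target CDS to the proximal end of the closest downstream
#' non-target CDS. Where a run has no flanking non-target gene on its
#' chromosome, the boundary is placed `edge_default` nt beyond the terminal
#' target CDS.
#'
#' @param genes Gene-model tibble from [parse_gene_models()]; at least one
#'   row must have `is_target = TRUE`.
#' @param edge_default Distance (nt) used for a missing flank. Default 25000.
#' @param curation Optional curation tibble; `force_region_span` overrides
#'   (payload `chrom:start-end`, 0-based half-open) replace the span of the
#'   region containing the named gene.
#' @return A tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_genes`, `gene_ids` (list-column), `gene_density` (member CDS count
#'   per Mb of flanking-to-flanking distance).
#' @export
build_mask <- function(genes, edge_default = 25000, curation = NULL) {
  if (is.character(curation)) curation <- read_curation(curation)
  stopifnot(is.data.frame(genes))
  if (!any(genes$is_target)) stop("no target genes in input", call. = FALSE)
  genes <- dplyr::arrange(genes, .data$chrom, .data$cds_start, .data$cds_end)
  regions <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    runs <- rle(g$is_target)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values)) {
      members <- g[idx_start[r]:idx_end[r], ]
      up <- if (idx_start[r] > 1) g[idx_start[r] - 1L, ] else NULL
      down <- if (idx_end[r] < nrow(g)) g[idx_end[r] + 1L, ] else NULL
      start <- if (!is.null(up)) up$cds_end else max(0L, min(members$cds_start) - edge_default)
      end <- if (!is.null(down)) down$cds_start else max(members$cds_end) + edge_default
      if (end <= start) {
        stop("non-positive mask region span around gene(s) ",
             paste(members$gene_id, collapse = ", "), call. = FALSE)
      }
      regions[[length(regions) + 1L]] <- tibble::tibble(
        chrom = chr, start = start, end = end, n_genes = nrow(members),
        gene_ids = list(members$gene_id))
    }
  }
  out <- dplyr::bind_rows(regions)
  if (!is.null(curation)) {
    forced <- curation[curation$action == "force_region_span", ]
    for (i in seq_len(nrow(forced))) {
      hit <- vapply(out$gene_ids, function(ids) forced$gene_id[i] %in% ids, logical(1))
      if (any(hit)) {
        span <- .parse_span(forced$payload[i])
        out$chrom[hit] <- span$chrom
        out$start[hit] <- span$start
        out$end[hit] <- span$end
      }
    }
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  # regions on one chromosome must not overlap
  for (chr in unique(out$chrom)) {
    o <- out[out$chrom == chr, ]
    if (nrow(o) > 1 && any(o$start[-1] < o$end[-nrow(o)])) {
      stop("overlapping mask regions on ", chr, call. = FALSE)
    }
  }
  out$region_id <- seq_len(nrow(out))
  out$gene_density <- out$n_genes / ((out$end - out$start) / 1e6)
  out[, c("region_id", "chrom", "start", "end", "n_genes", "gene_ids", "gene_density")]
}

.parse_span <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("bad span payload: ", x, call. = FALSE)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Mask regions as BED records
#'
#' @param regions Region tibble from [build_mask()].
#' @return A tibble of BED fields (`chrom`, `start`, `end`, `name`), sorted,
#'   0-based half-open.
#' @export
mask_intervals <- function(regions) {
  out <- tibble::tibble(chrom = regions$chrom, start = regions$start,
                        end = regions$end,
                        name = paste0("region_", regions$region_id))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write mask regions to a BED file
#'
#' @param regions Region tibble from [build_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(regions, path) {
  bed <- mask_intervals(regions)
  lines <- "# target-family mask regions (BED, 0-based half-open)"
  if (nrow(bed) > 0) {
    lines <- c(lines, paste(bed$chrom, format(bed$start, scientific = FALSE, trim = TRUE),
                            format(bed$end, scientific = FALSE, trim = TRUE), bed$name,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a mask BED file back into a region tibble
#'
#' @param path BED path written by [write_mask_bed()].
#' @return A region tibble (`region_id`, `chrom`, `start`, `end`).
#' @export
read_mask_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(region_id = integer(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t")
  tibble::tibble(region_id = seq_along(parts),
                 chrom = vapply(parts, `[`, "", 1),
                 start = as.numeric(vapply(parts, `[`, "", 2)),
                 end = as.numeric(vapply(parts, `[`, "", 3)))
}
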