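# Ground-truthed synthetic data: clustered genes, nested 3'UTR isoforms with
# stepwise coverage drops, planted PAS hexamers, Poisson-noised depth with
# optional 3' positional bias, gaps, and 3'UTR introns.
#
# The generator emulates the coverage structure the pipeline consumes: per
# gene, expected depth at 3'UTR position p is depth_scale/1000 times the
# summed abundance of the isoforms whose end is at or beyond p, modulated by
# an exponential 3' decay, zeroed on planted gaps, and realized as
# independent per-base Poisson draws. Per-base noise (not fragment-level
# simulation) is the right granularity because the pipeline's sole input
# currency is per-base depth.

#' Describe one synthetic gene
#'
#' @param gene_id Gene name.
#' @param strand `"+"` or `"-"`.
#' @param cds_len CDS length (nt), stop codon included.
#' @param utr_ends Numeric vector of true 3' end positions (nt after stop),
#'   strictly increasing.
#' @param abundances Isoform abundances (same length as `utr_ends`, summing
#'   to 1).
#' @param is_target Family-membership flag (default TRUE).
#' @param gaps Optional list of `c(start, end)` 3'UTR intervals (1-based
#'   inclusive) forced to zero coverage (repeat/mappability dropouts).
#' @param intron Optional `c(start, end, retention)`: a 3'UTR intron
#'   (1-based inclusive 3'UTR interval) whose coverage is multiplied by
#'   `retention` (0 = obligatory excision, between 0 and 1 = optional).
#' @return One-row tibble with list-columns, for [synthetic_truth()].
#' @export
synthetic_gene <- function(gene_id, strand = "+", cds_len = 1000,
                           utr_ends = 1500, abundances = 1, is_target = TRUE,
                           gaps = NULL, intron = NULL) {
  utr_ends <- as.numeric(utr_ends)
  abundances <- as.numeric(abundances)
  stopifnot(length(utr_ends) == length(abundances),
            all(diff(utr_ends) > 0), all(abundances > 0),
            abs(sum(abundances) - 1) < 1e-8, cds_len >= 6)
  tibble::tibble(gene_id = gene_id, strand = strand, cds_len = cds_len,
                 utr_ends = list(utr_ends), abundances = list(abundances),
                 is_target = is_target, gaps = list(gaps),
                 intron = list(intron))
}

#' Assemble a synthetic truth specification
#'
#' Lays the genes out along one synthetic chromosome (a `-` strand gene has
#' its 3'UTR on the genomic left of its CDS), optionally flanked by two
#' non-target genes so mask construction can run on the generated GTF.
#'
#' @param genes Tibble of rows from [synthetic_gene()].
#' @param depth_scale Expected CDS depth in counts/kb (default 200; per-base
#'   Poisson mean `depth_scale / 1000`).
#' @param bias 3' positional decay rate per kb (default 0 = off): expected
#'   depth at 3'UTR position p is multiplied by `exp(-bias * p / 1000)`.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @param chrom Chromosome name.
#' @param spacer Intergenic spacing (nt, default 2000).
#' @param pas_offset Offset (nt, relative to each true end) at which a
#'   canonical AATAAA is planted (default -20; the surrounding 100-nt
#'   windows are otherwise kept hexamer-free by rejection).
#' @param add_flanks Add non-target flanking genes (default TRUE).
#' @return A `synthetic_truth` object (list with `genes` layout tibble and
#'   the generation parameters).
#' @export
synthetic_truth <- function(genes, depth_scale = 200, bias = 0, seed = 1,
                            chrom = "chrS", spacer = 2000, pas_offset = -20,
                            add_flanks = TRUE) {
  stopifnot(nrow(genes) >= 1)
  layout <- genes
  layout$cds_start <- NA_real_
  layout$cds_end <- NA_real_
  layout$stop_anchor <- NA_real_
  layout$gene_start <- NA_real_
  layout$gene_end <- NA_real_
  x <- spacer
  if (add_flanks) x <- x + 300 + spacer  # room for the left flank gene
  for (i in seq_len(nrow(layout))) {
    max_end <- max(layout$utr_ends[[i]])
    if (layout$strand[i] == "+") {
      layout$cds_start[i] <- x
      layout$cds_end[i] <- x + layout$cds_len[i]
      layout$stop_anchor[i] <- layout$cds_end[i]
      layout$gene_start[i] <- x
      layout$gene_end[i] <- layout$stop_anchor[i] + max_end
    } else {
      layout$stop_anchor[i] <- x + max_end
      layout$cds_start[i] <- layout$stop_anchor[i]
      layout$cds_end[i] <- layout$cds_start[i] + layout$cds_len[i]
      layout$gene_start[i] <- x
      layout$gene_end[i] <- layout$cds_end[i]
    }
    x <- layout$gene_end[i] + spacer
  }
  chrom_len <- x
  if (add_flanks) chrom_len <- chrom_len + 300 + spacer
  structure(list(genes = layout, depth_scale = depth_scale, bias = bias,
                 seed = seed, chrom = chrom, chrom_len = ceiling(chrom_len),
                 pas_offset = pas_offset, add_flanks = add_flanks),
            class = "synthetic_truth")
}

# expected per-base depth over a gene's 3'UTR positions 1..n
.expected_utr_depth <- function(gene_row, n, depth_scale, bias) {
  ends <- gene_row$utr_ends[[1]]
  ab <- gene_row$abundances[[1]]
  p <- seq_len(n)
  lambda <- (depth_scale / 1000) *
    vapply(p, function(q) sum(ab[ends >= q]), numeric(1)) *
    exp(-bias * p / 1000)
  gaps <- gene_row$gaps[[1]]
  if (!is.null(gaps)) {
    for (g in gaps) lambda[seq.int(g[1], min(g[2], n))] <- 0
  }
  intr <- gene_row$intron[[1]]
  if (!is.null(intr)) {
    idx <- seq.int(intr[1], min(intr[2], n))
    lambda[idx] <- lambda[idx] * intr[3]
  }
  lambda
}

#' Generate a synthetic dataset bundle
#'
#' Writes FASTA, GTF, bedGraph (one per strand when `stranded`), a junction
#' BED for planted introns, and a truth JSON; also returns everything in
#' memory. Byte-identical across reruns with the same truth (the seed is
#' part of the truth).
#'
#' @param truth A `synthetic_truth` object.
#' @param dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param noise Draw per-base Poisson noise (default TRUE); `FALSE` writes
#'   the expected depth itself (noiseless fixtures).
#' @param stranded Write strand-split coverage (default TRUE).
#' @return List: `truth`, `genes` (gene-model tibble as [parse_gene_models()]
#'   returns), `regions`, `tracks` (named by strand), `sequence`,
#'   `planted_pas`, `junctions`, and file `paths` when `dir` is given.
#' @export
generate_dataset <- function(truth, dir = NULL, noise = TRUE, stranded = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  gl <- truth$genes
  chrom <- truth$chrom
  n <- truth$chrom_len

  # --- depth per strand ---------------------------------------------------
  depth <- list(`+` = numeric(n), `-` = numeric(n))
  for (i in seq_len(nrow(gl))) {
    g <- gl[i, ]
    lam_cds <- rep(truth$depth_scale / 1000, g$cds_len)
    max_end <- max(g$utr_ends[[1]])
    lam_utr <- .expected_utr_depth(g, max_end, truth$depth_scale, truth$bias)
    if (g$strand == "+") {
      idx <- seq.int(g$cds_start + 1, g$stop_anchor + max_end)
      lam <- c(lam_cds, lam_utr)
    } else {
      idx <- seq.int(g$stop_anchor - max_end + 1, g$cds_end)
      lam <- c(rev(lam_utr), lam_cds)
    }
    depth[[g$strand]][idx] <- depth[[g$strand]][idx] +
      if (noise) rpois(length(lam), lam) else lam
  }

  # --- sequence with planted PAS ------------------------------------------
  seq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  planted <- list()
  guard <- c(canonical_pas(),
             as.character(Biostrings::reverseComplement(
               Biostrings::DNAStringSet(canonical_pas()))))
  # pass 1: rejection — keep every end's +/-130 nt window hexamer-free
  for (i in seq_len(nrow(gl))) {
    g <- gl[i, ]
    for (e in g$utr_ends[[1]]) {
      win <- .utr_to_genomic(g, max(1, e - 130), e + 130)
      win <- c(max(1, win[1]), min(n, win[2]))
      repeat {
        s <- paste(seq[win[1]:win[2]], collapse = "")
        if (!any(vapply(guard, function(h) grepl(h, s, fixed = TRUE),
                        logical(1)))) break
        seq[win[1]:win[2]] <- sample(c("A", "C", "G", "T"),
                                     win[2] - win[1] + 1, replace = TRUE)
      }
    }
  }
  # pass 2: plant a canonical hexamer at pas_offset from each true end
  for (i in seq_len(nrow(gl))) {
    g <- gl[i, ]
    for (e in g$utr_ends[[1]]) {
      pas_utr <- e + truth$pas_offset
      if (pas_utr >= 1) {
        hx <- strsplit(canonical_pas()[1], "")[[1]]
        span <- .utr_to_genomic(g, pas_utr, pas_utr + 5)
        if (g$strand == "-") {
          hx <- rev(chartr("ACGT", "TGCA", hx))
        }
        seq[span[1]:span[2]] <- hx
        planted[[length(planted) + 1L]] <- tibble::tibble(
          gene_id = g$gene_id, hexamer = canonical_pas()[1], utr_pos = pas_utr,
          end_pos = e)
      }
    }
  }
  planted <- if (length(planted) > 0) dplyr::bind_rows(planted) else
    tibble::tibble(gene_id = character(), hexamer = character(),
                   utr_pos = numeric(), end_pos = numeric())

  # --- gene models, flanks, region ----------------------------------------
  genes <- tibble::tibble(
    gene_id = gl$gene_id, gene_name = gl$gene_id, chrom = chrom,
    strand = gl$strand, cds_start = gl$cds_start, cds_end = gl$cds_end,
    stop_anchor = gl$stop_anchor, gene_start = gl$gene_start,
    gene_end = gl$gene_end, is_target = gl$is_target)
  if (truth$add_flanks) {
    flanks <- tibble::tibble(
      gene_id = c("NTleft", "NTright"), gene_name = c("NTleft", "NTright"),
      chrom = chrom, strand = "+",
      cds_start = c(0, n - 300), cds_end = c(300, n),
      stop_anchor = c(300, n), gene_start = c(0, n - 300),
      gene_end = c(300, n), is_target = FALSE)
    genes <- dplyr::bind_rows(flanks[1, ], genes, flanks[2, ])
  }
  regions <- if (truth$add_flanks) {
    build_mask(genes)
  } else {
    tibble::tibble(region_id = 1L, chrom = chrom, start = 0, end = n,
                   n_genes = nrow(gl), gene_ids = list(gl$gene_id),
                   gene_density = nrow(gl) / (n / 1e6))
  }

  # --- junctions from planted introns -------------------------------------
  junctions <- list()
  for (i in seq_len(nrow(gl))) {
    g <- gl[i, ]
    intr <- g$intron[[1]]
    if (is.null(intr)) next
    span <- .utr_to_genomic(g, intr[1], intr[2])
    jdepth <- max(2, round((1 - intr[3]) * truth$depth_scale / 1000 *
                             sum(g$abundances[[1]][g$utr_ends[[1]] >= intr[2]]) * 10))
    junctions[[length(junctions) + 1L]] <- tibble::tibble(
      chrom = chrom, donor = span[1] - 1, acceptor = span[2],
      strand = g$strand, depth = jdepth)
  }
  junctions <- if (length(junctions) > 0) dplyr::bind_rows(junctions) else
    tibble::tibble(chrom = character(), donor = numeric(),
                   acceptor = numeric(), strand = character(), depth = numeric())

  # --- tracks --------------------------------------------------------------
  region_tracks <- function(dep, strand_label) {
    tr <- lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      coverage_track(chrom, r$start, r$end, dep[seq.int(r$start + 1, r$end)],
                     stranded = stranded, strand = strand_label)
    })
    tibble::tibble(region_id = regions$region_id, chrom = regions$chrom,
                   start = regions$start, end = regions$end, track = tr)
  }
  tracks <- if (stranded) {
    list(`+` = region_tracks(depth[["+"]], "+"),
         `-` = region_tracks(depth[["-"]], "-"))
  } else {
    list(`*` = region_tracks(depth[["+"]] + depth[["-"]], "*"))
  }

  out <- list(truth = truth, genes = genes, regions = regions, tracks = tracks,
              sequence = paste(seq, collapse = ""), planted_pas = planted,
              junctions = junctions)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  junctions = file.path(dir, "junctions.bed"),
                  truth = file.path(dir, "truth.json"))
    ss <- Biostrings::DNAStringSet(setNames(out$sequence, chrom))
    Biostrings::writeXStringSet(ss, paths$fasta)
    .write_gtf(genes, paths$gtf)
    .write_junction_bed(junctions, paths$junctions)
    if (stranded) {
      paths$bedgraph_plus <- file.path(dir, "coverage_plus.bedGraph")
      paths$bedgraph_minus <- file.path(dir, "coverage_minus.bedGraph")
      .write_bedgraph(chrom, depth[["+"]], paths$bedgraph_plus)
      .write_bedgraph(chrom, depth[["-"]], paths$bedgraph_minus)
    } else {
      paths$bedgraph <- file.path(dir, "coverage.bedGraph")
      .write_bedgraph(chrom, depth[["+"]] + depth[["-"]], paths$bedgraph)
    }
    truth_json <- list(seed = truth$seed, depth_scale = truth$depth_scale,
                       bias = truth$bias, chrom = chrom,
                       genes = lapply(seq_len(nrow(gl)), function(i) {
                         g <- gl[i, ]
                         list(gene_id = g$gene_id, strand = g$strand,
                              cds_start = g$cds_start, cds_end = g$cds_end,
                              stop_anchor = g$stop_anchor,
                              utr_ends = g$utr_ends[[1]],
                              abundances = g$abundances[[1]])
                       }),
                       planted_pas = planted)
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

# genomic 0-based base indices (1-based vector positions) covered by 3'UTR
# positions [p1, p2] of a gene; returns 1-based c(from, to) into the
# chromosome sequence/depth vectors
.utr_to_genomic <- function(gene_row, p1, p2) {
  a <- gene_row$stop_anchor
  if (gene_row$strand == "+") c(a + p1, a + p2) else c(a - p2 + 1, a - p1 + 1)
}

.write_bedgraph <- function(chrom, depth, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0
  lines <- paste(chrom, format(starts[keep], scientific = FALSE, trim = TRUE),
                 format(ends[keep], scientific = FALSE, trim = TRUE),
                 format(r$values[keep], scientific = FALSE, trim = TRUE),
                 sep = "\t")
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}

.write_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s.t1";',
                     g$gene_id, g$gene_name, g$gene_id)
    # GTF is 1-based inclusive
    exon <- c(g$gene_start + 1, g$gene_end)
    if (g$strand == "+") {
      cds <- c(g$cds_start + 1, g$cds_end - 3)
      stopc <- c(g$cds_end - 2, g$cds_end)
    } else {
      cds <- c(g$cds_start + 4, g$cds_end)
      stopc <- c(g$cds_start + 1, g$cds_start + 3)
    }
    rowf <- function(type, span) {
      paste(g$chrom, "utrapa", type, span[1], span[2], ".", g$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(lines, rowf("exon", exon), rowf("CDS", cds),
               rowf("stop_codon", stopc))
  }
  writeLines(lines, path)
  invisible(path)
}

.write_junction_bed <- function(junctions, path) {
  if (nrow(junctions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(junctions$chrom,
                 format(junctions$donor, scientific = FALSE, trim = TRUE),
                 format(junctions$acceptor, scientific = FALSE, trim = TRUE),
                 paste0("J", seq_len(nrow(junctions))),
                 format(junctions$depth, scientific = FALSE, trim = TRUE),
                 junctions$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' End-recovery precision experiment
#'
#' Simulates single-end genes (3'UTR length uniform on `utr_range`, expected
#' CDS depth `depth_scale` counts/kb, per-base Poisson noise, no positional
#' bias), runs the change-point end detector with `params` on each, and
#' reports the fraction of genes whose called 3' end (the distal-most
#' detected end) lies within `tol` nt of the planted end.
#'
#' @param n_genes Number of simulated genes (default 500).
#' @param depth_scale Expected CDS depth, counts/kb (default 200).
#' @param seed Integer seed.
#' @param utr_range 3'UTR length range, nt (default `c(500, 3000)`).
#' @param cds_len CDS length, nt (default 1000).
#' @param params `seg_params`.
#' @param tol Recovery tolerance, nt (default 100 — the precision window).
#' @return List: `recovery` (fraction in `[0, 1]`), `n_genes`, `details`
#'   tibble (`gene`, `true_end`, `called_end`, `recovered`).
#' @export
precision_experiment <- function(n_genes = 500, depth_scale = 200, seed = 1,
                                 utr_range = c(500, 3000), cds_len = 1000,
                                 params = seg_params(), tol = 100) {
  set.seed(seed)
  true_end <- sample(seq.int(utr_range[1], utr_range[2]), n_genes,
                     replace = TRUE)
  lam <- depth_scale / 1000
  called <- rep(NA_real_, n_genes)
  for (i in seq_len(n_genes)) {
    pad <- params$merge_radius + 100
    v <- c(rpois(cds_len + true_end[i], lam), numeric(pad))
    track <- coverage_track("sim", 0, length(v), v)
    gene <- tibble::tibble(gene_id = paste0("g", i), chrom = "sim",
                           strand = "+", cds_start = 0, cds_end = cds_len,
                           stop_anchor = cds_len)
    ends <- detect_ends(track, gene, neighbors = NULL, params = params)
    if (nrow(ends) > 0) called[i] <- max(ends$utr_pos)
  }
  recovered <- !is.na(called) & abs(called - true_end) <= tol
  list(recovery = mean(recovered), n_genes = n_genes,
       details = tibble::tibble(gene = seq_len(n_genes), true_end = true_end,
                                called_end = called, recovered = recovered))
}
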