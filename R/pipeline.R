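# End-to-end orchestration: mask -> coverage -> detect -> catalog -> PAS ->
# quantify (-> introns), per dataset. Regions are processed independently;
# their order does not affect the result.

#' Run the APA annotation pipeline on one dataset
#'
#' @param gtf Path to the gene annotation GTF, or a gene-model tibble from
#'   [parse_gene_models()].
#' @param bedgraphs Named list/character of bedGraph paths keyed by strand
#'   (`"+"`/`"-"` for strand-split coverage, `"*"` for unstranded), or a
#'   named list of pre-built track tibbles (from [load_bedgraph()] or
#'   [generate_dataset()]).
#' @param fasta Optional genome FASTA path (or a named character vector of
#'   chromosome sequences) enabling the PAS scan.
#' @param junctions Optional junction file path (see [read_junctions()]) or
#'   junction tibble enabling 3'UTR intron classification.
#' @param target_pattern Regex deciding target-family membership.
#' @param params `seg_params`.
#' @param curation Optional curation table or path (see [read_curation()]).
#' @param variants Variant PAS hexamers for the rescue scan.
#' @param precision_threshold Counts/kb for the precision flag (default 200).
#' @param out_dir Optional directory; when given, the catalog, profile, PAS,
#'   and intron tables are written as TSV alongside a run log.
#' @return An `apa_run` object: list with `genes`, `regions`, `expression`,
#'   `ends`, `sites`, `discarded_fusions`, `catalog`, `profiles`,
#'   `pas_matches`, `introns`, `utr_coverage`, `params`, `stranded`.
#' @export
run_apa_pipeline <- function(gtf, bedgraphs, fasta = NULL, junctions = NULL,
                             target_pattern = "^Olfr", params = seg_params(),
                             curation = NULL, variants = variant_pas(),
                             precision_threshold = 200, out_dir = NULL) {
  genes <- if (is.character(gtf)) {
    parse_gene_models(gtf, target_pattern, curation)
  } else {
    gtf
  }
  regions <- build_mask(genes, curation = curation)

  if (is.character(bedgraphs)) bedgraphs <- as.list(bedgraphs)
  if (is.null(names(bedgraphs)) || any(!nzchar(names(bedgraphs)))) {
    stop("bedgraphs must be named by strand ('+', '-', or '*')", call. = FALSE)
  }
  stranded <- !("*" %in% names(bedgraphs))
  tracks <- lapply(names(bedgraphs), function(st) {
    bg <- bedgraphs[[st]]
    if (is.character(bg)) {
      load_bedgraph(bg, regions, stranded = stranded, strand = st)
    } else {
      bg
    }
  })
  names(tracks) <- names(bedgraphs)

  seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
      ss <- Biostrings::readDNAStringSet(fasta)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    } else {
      fasta
    }
  }

  targets <- genes[genes$is_target, , drop = FALSE]
  expression <- list()
  ends_all <- list()
  utr_cov <- list()
  for (i in seq_len(nrow(targets))) {
    g <- targets[i, ]
    st <- if (stranded) g$strand else "*"
    trk_tbl <- tracks[[st]]
    if (is.null(trk_tbl)) next
    ridx <- which(trk_tbl$chrom == g$chrom & trk_tbl$start <= g$cds_start &
                    g$cds_end <= trk_tbl$end)
    if (length(ridx) == 0) next
    track <- trk_tbl$track[[ridx[1]]]
    ex <- expression_status(track, g, precision_threshold)
    expression[[length(expression) + 1L]] <- ex
    if (!ex$expressed) next
    v <- scan_region(track, g, neighbors = genes, params = params)
    utr_cov[[g$gene_id]] <- v
    ends <- filter_ends(segment_changepoints(v, params))
    if (nrow(ends) == 0) next
    ends$gene_id <- g$gene_id
    ends$genomic_pos <- if (g$strand == "+") g$stop_anchor + ends$utr_pos - 1 else
      g$stop_anchor - ends$utr_pos
    ends_all[[length(ends_all) + 1L]] <- ends
  }
  expression <- dplyr::bind_rows(expression)
  ends_all <- if (length(ends_all) > 0) dplyr::bind_rows(ends_all) else
    tibble::tibble(gene_id = character(), utr_pos = integer())

  sites <- merge_gene_ends(ends_all, params$precision_window)
  fus <- discard_fusions(sites, genes, stranded = stranded)
  sites <- fus$kept

  pas <- NULL
  if (!is.null(seqs) && nrow(sites) > 0) {
    utr_seqs <- list()
    for (gid in unique(sites$gene_id)) {
      g <- genes[genes$gene_id == gid, ]
      if (!g$chrom %in% names(seqs)) next
      utr_seqs[[gid]] <- utr_sequence(seqs[[g$chrom]], 0, g,
                                      length = params$scan_cap)
    }
    pas <- annotate_pas(sites, utr_seqs, variants = variants)
    sites <- pas$sites
  }

  catalog <- catalog_isoforms(sites)

  profiles <- list()
  for (gid in unique(sites$gene_id)) {
    s <- sites[sites$gene_id == gid, ]
    v <- utr_cov[[gid]]
    q <- tryCatch(quantify_gene(v, s), error = function(e) NULL)
    if (is.null(q)) next
    q$gene_id <- gid
    profiles[[length(profiles) + 1L]] <- q
  }
  profiles <- if (length(profiles) > 0) {
    dplyr::bind_rows(profiles)[, c("gene_id", "n_isoforms", "ra", "raw",
                                   "profile", "any_very_short")]
  } else {
    tibble::tibble(gene_id = character(), n_isoforms = integer(), ra = list(),
                   raw = list(), profile = character(),
                   any_very_short = logical())
  }
  # per-isoform abundance into the catalog
  catalog$relative_abundance <- NA_real_
  for (i in seq_len(nrow(catalog))) {
    p <- profiles[profiles$gene_id == catalog$gene_id[i], ]
    if (nrow(p) == 1 && catalog$rank[i] <= length(p$ra[[1]])) {
      catalog$relative_abundance[i] <- p$ra[[1]][catalog$rank[i]]
    }
  }

  introns <- NULL
  if (!is.null(junctions)) {
    jx <- if (is.character(junctions)) read_junctions(junctions) else junctions
    jx <- filter_junctions(jx)
    trk_for_introns <- if (stranded) {
      dplyr::bind_rows(lapply(names(tracks), function(st) tracks[[st]]))
    } else {
      tracks[["*"]]
    }
    introns <- annotate_introns(jx, catalog, genes, trk_for_introns)
  }

  run <- structure(list(genes = genes, regions = regions,
                        expression = expression, ends = ends_all,
                        sites = sites, discarded_fusions = fus$discarded,
                        catalog = catalog, profiles = profiles,
                        pas_matches = if (is.null(pas)) NULL else pas$matches,
                        introns = introns, utr_coverage = utr_cov,
                        params = params, stranded = stranded),
                   class = "apa_run")
  if (!is.null(out_dir)) write_apa_run(run, out_dir)
  run
}

#' Write the tables of an `apa_run` to TSV
#'
#' @param run An `apa_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_apa_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$catalog[, setdiff(names(run$catalog), character(0))],
                   file.path(out_dir, "catalog.tsv"))
  prof <- run$profiles
  if (nrow(prof) > 0) {
    prof$ra <- vapply(prof$ra, function(x) paste(signif(x, 6), collapse = ","),
                      character(1))
    prof$raw <- vapply(prof$raw, function(x) paste(signif(x, 6), collapse = ","),
                       character(1))
  }
  readr::write_tsv(prof, file.path(out_dir, "profiles.tsv"))
  if (!is.null(run$pas_matches)) {
    readr::write_tsv(run$pas_matches, file.path(out_dir, "pas_matches.tsv"))
  }
  if (!is.null(run$introns)) {
    readr::write_tsv(run$introns, file.path(out_dir, "introns.tsv"))
  }
  readr::write_tsv(run$discarded_fusions,
                   file.path(out_dir, "discarded_fusions.tsv"))
  g <- glance(run)
  writeLines(c("# utrapa run summary",
               paste0(names(g), ": ", vapply(g[1, ], format, character(1)))),
             file.path(out_dir, "run_summary.txt"))
  invisible(out_dir)
}

#' @export
print.apa_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<apa_run> %d annotated gene(s), %d isoform(s), ",
                     "%.1f%% with APA\n"),
              g$n_genes, g$n_isoforms, g$pct_apa))
  invisible(x)
}

#' Tidy the isoform catalog of a pipeline run
#'
#' @param x An `apa_run`.
#' @param ... Unused.
#' @return The isoform catalog tibble (one row per gene x isoform) with
#'   per-gene profile joined in.
#' @method tidy apa_run
#' @export
tidy.apa_run <- function(x, ...) {
  dplyr::left_join(x$catalog,
                   x$profiles[, c("gene_id", "profile", "any_very_short")],
                   by = "gene_id")
}

#' One-row summary of a pipeline run
#'
#' @param x An `apa_run`.
#' @param ... Unused.
#' @return Tibble with gene/isoform counts, the APA percentage, P1-P4
#'   profile percentages, and the canonical-PAS match percentage (NA when no
#'   sequence was supplied).
#' @method glance apa_run
#' @export
glance.apa_run <- function(x, ...) {
  per_gene <- dplyr::distinct(x$catalog[, c("gene_id", "n_isoforms")])
  n_genes <- nrow(per_gene)
  prof_pct <- function(p) {
    if (nrow(x$profiles) == 0) return(NA_real_)
    100 * mean(x$profiles$profile == p)
  }
  tibble::tibble(
    n_genes = n_genes,
    n_isoforms = if (n_genes) sum(per_gene$n_isoforms) else 0L,
    pct_apa = if (n_genes) 100 * mean(per_gene$n_isoforms > 1) else NA_real_,
    pct_p1 = prof_pct("P1"), pct_p2 = prof_pct("P2"),
    pct_p3 = prof_pct("P3"), pct_p4 = prof_pct("P4"),
    pct_canonical_pas = if (!is.null(x$pas_matches) && nrow(x$sites) > 0) {
      100 * mean(x$sites$has_canonical)
    } else {
      NA_real_
    })
}

#' Bar chart of quantitative APA profiles
#'
#' @param run An `apa_run`.
#' @return A ggplot.
#' @export
plot_profiles <- function(run) {
  stopifnot(inherits(run, "apa_run"))
  df <- dplyr::count(run$profiles, .data$profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profile, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "quantitative profile", y = "genes",
                  title = "Per-gene 3'UTR isoform profiles") +
    ggplot2::theme_minimal()
}

#' 3'UTR coverage of one gene with its called ends
#'
#' @param run An `apa_run`.
#' @param gene_id Gene to plot.
#' @return A ggplot of per-base depth in 3'UTR coordinates with called 3'
#'   ends marked.
#' @export
plot_gene_coverage <- function(run, gene_id) {
  v <- run$utr_coverage[[gene_id]]
  if (is.null(v)) stop("no coverage stored for ", gene_id, call. = FALSE)
  df <- tibble::tibble(utr_pos = seq_along(v), depth = as.numeric(v))
  ends <- run$ends[run$ends$gene_id == gene_id, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$utr_pos, y = .data$depth)) +
    ggplot2::geom_step(color = "grey30") +
    ggplot2::labs(x = "nt after stop codon", y = "depth", title = gene_id) +
    ggplot2::theme_minimal()
  if (nrow(ends) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ends$utr_pos,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' @rdname plot_profiles
#' @param object An `apa_run`.
#' @param ... Unused.
#' @method autoplot apa_run
#' @export
autoplot.apa_run <- function(object, ...) plot_profiles(object)
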