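# Cross-dataset conservation of 3'UTR isoform annotations.
#
# Isoforms are aligned across datasets positionally by length rank (the
# single or proximal UTR with its counterpart, dUTR1 with dUTR1, ...). Two
# annotations of the same gene/rank are "conserved" when both are present
# and their lengths differ by strictly less than 200 nt — twice the 100-nt
# precision window, since each annotation carries its own uncertainty.

#' Pairwise conservation of two isoform lengths
#'
#' @param len_a,len_b Isoform lengths (nt after stop); `NA` = not annotated.
#' @param threshold Conservation threshold (nt), strict (default 200).
#' @return Logical; `FALSE` when either length is absent.
#' @export
pairwise_conserved <- function(len_a, len_b, threshold = 200) {
  ifelse(is.na(len_a) | is.na(len_b), FALSE, abs(len_a - len_b) < threshold)
}

#' Dataset labels for a four-way comparison
#'
#' @param name Dataset names (must match the catalog list).
#' @param sex `"male"`/`"female"` per dataset.
#' @param series Experimental series identifier per dataset.
#' @return Tibble of labels; `(sex, series)` pairs must be unique.
#' @export
dataset_labels <- function(name, sex, series) {
  out <- tibble::tibble(name = name, sex = sex, series = series)
  if (anyDuplicated(paste(sex, series))) {
    stop("(sex, series) pairs must be unique", call. = FALSE)
  }
  out
}

# the four canonical comparisons of a 2-sex x 2-series design:
# two same-sex/cross-series pairs and two cross-sex/within-series pairs
.four_comparisons <- function(labels) {
  sexes <- unique(labels$sex)
  series <- unique(labels$series)
  if (nrow(labels) != 4 || length(sexes) != 2 || length(series) != 2) {
    return(NULL)
  }
  pick <- function(sx, sr) labels$name[labels$sex == sx & labels$series == sr]
  list(
    same_sex = list(c(pick(sexes[1], series[1]), pick(sexes[1], series[2])),
                    c(pick(sexes[2], series[1]), pick(sexes[2], series[2]))),
    cross_sex = list(c(pick(sexes[1], series[1]), pick(sexes[2], series[1])),
                     c(pick(sexes[1], series[2]), pick(sexes[2], series[2]))))
}

#' Summary conservation flag for one gene/rank record
#'
#' Main-text convention: ROBUST = conserved in all four comparisons of the
#' 2-sex x 2-series design; SEX-SPE = conserved in both same-sex
#' (cross-series) comparisons but in neither cross-sex (within-series)
#' comparison; EXP-SPE = the converse; otherwise none. The supplementary
#' convention (`convention = "supplementary"`) swaps the SEX-SPE/EXP-SPE
#' wordings.
#'
#' @param lengths Named numeric vector of the record's lengths, names =
#'   dataset names (`NA` = absent).
#' @param labels Label tibble from [dataset_labels()] (4 rows).
#' @param threshold Conservation threshold (nt).
#' @param convention `"main_text"` (default) or `"supplementary"`.
#' @return One of `"ROBUST"`, `"SEX-SPE"`, `"EXP-SPE"`, `"none"`.
#' @export
summary_flags <- function(lengths, labels, threshold = 200,
                          convention = c("main_text", "supplementary")) {
  convention <- match.arg(convention)
  cmp <- .four_comparisons(labels)
  if (is.null(cmp)) stop("summary flags need exactly 2 sexes x 2 series",
                         call. = FALSE)
  cons <- function(pair) pairwise_conserved(lengths[[pair[1]]], lengths[[pair[2]]],
                                            threshold)
  same_sex <- vapply(cmp$same_sex, cons, logical(1))
  cross_sex <- vapply(cmp$cross_sex, cons, logical(1))
  if (all(same_sex) && all(cross_sex)) return("ROBUST")
  sex_spe <- all(same_sex) && !any(cross_sex)
  exp_spe <- all(cross_sex) && !any(same_sex)
  if (convention == "supplementary") {
    tmp <- sex_spe; sex_spe <- exp_spe; exp_spe <- tmp
  }
  if (sex_spe) "SEX-SPE" else if (exp_spe) "EXP-SPE" else "none"
}

#' Compare isoform catalogs across datasets
#'
#' Builds one record per gene and length rank present in any dataset, with
#' per-dataset lengths, pairwise conservation calls, and — for a full
#' 2-sex x 2-series set of four datasets — the summary flag.
#'
#' @param catalogs Named list of isoform catalogs (from
#'   [catalog_isoforms()]).
#' @param labels Optional [dataset_labels()] tibble (required for summary
#'   flags; its `name` column must match `names(catalogs)`).
#' @param threshold Conservation threshold (nt), strict.
#' @param convention Flag-wording convention, see [summary_flags()].
#' @return Tibble: `gene_id`, `utr_rank` (s/pUTR, dUTR1, ...),
#'   `len_<dataset>` columns, `conserved_<a>.<b>` columns for every dataset
#'   pair, `very_short` (in any dataset), and `flag` when four labeled
#'   datasets are supplied.
#' @export
compare_catalogs <- function(catalogs, labels = NULL, threshold = 200,
                             convention = "main_text") {
  stopifnot(length(catalogs) >= 2, !is.null(names(catalogs)))
  dsn <- names(catalogs)
  longs <- lapply(dsn, function(nm) {
    cc <- catalogs[[nm]]
    tibble::tibble(gene_id = cc$gene_id,
                   utr_rank = ifelse(cc$rank == 1, "s/pUTR",
                                     paste0("dUTR", cc$rank - 1)),
                   length = cc$length, very_short = cc$very_short,
                   dataset = nm)
  })
  long <- dplyr::bind_rows(longs)
  wide <- tidyr::pivot_wider(long, id_cols = c("gene_id", "utr_rank"),
                             names_from = "dataset",
                             values_from = c("length", "very_short"),
                             names_glue = "{.value}_{dataset}")
  out <- wide[, c("gene_id", "utr_rank", paste0("length_", dsn))]
  names(out) <- c("gene_id", "utr_rank", paste0("len_", dsn))
  vs <- as.matrix(wide[, paste0("very_short_", dsn)])
  out$very_short <- apply(vs, 1, function(x) any(x, na.rm = TRUE))
  pairs <- utils::combn(dsn, 2, simplify = FALSE)
  for (p in pairs) {
    out[[paste0("conserved_", p[1], ".", p[2])]] <-
      pairwise_conserved(out[[paste0("len_", p[1])]],
                         out[[paste0("len_", p[2])]], threshold)
  }
  if (!is.null(labels) && nrow(labels) == 4) {
    stopifnot(setequal(labels$name, dsn))
    out$flag <- vapply(seq_len(nrow(out)), function(i) {
      lens <- setNames(as.numeric(out[i, paste0("len_", dsn)]), dsn)
      summary_flags(lens, labels, threshold, convention)
    }, character(1))
  }
  dplyr::arrange(out, .data$gene_id, .data$utr_rank)
}

#' Gene-set intersections across catalogs
#'
#' @param catalogs Named list of isoform catalogs.
#' @return List: `common` (gene ids present in every catalog), `venn`
#'   (tibble of membership patterns and counts over all non-empty regions),
#'   `pair_counts` (per-pair overlap sizes).
#' @export
common_genes <- function(catalogs) {
  stopifnot(length(catalogs) >= 1, !is.null(names(catalogs)))
  sets <- lapply(catalogs, function(cc) unique(cc$gene_id))
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  common <- if (length(universe) == 0) character(0) else
    universe[rowSums(memb) == length(sets)]
  venn <- if (length(universe) == 0) {
    tibble::tibble(pattern = character(), n = integer())
  } else {
    pat <- apply(memb, 1, function(x) paste(names(sets)[x], collapse = "&"))
    tibble::as_tibble(dplyr::count(tibble::tibble(pattern = pat), .data$pattern,
                                   name = "n"))
  }
  pairs <- if (length(sets) >= 2) utils::combn(names(sets), 2, simplify = FALSE)
           else list()
  pair_counts <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(a = p[1], b = p[2],
                   n_common = length(intersect(sets[[p[1]]], sets[[p[2]]])))
  }))
  list(common = sort(common), venn = venn, pair_counts = pair_counts)
}
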