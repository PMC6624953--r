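# Fixture builders shared across test files.

# Write a small GENCODE-style GTF. features: list of c(type, start, end)
# in 1-based inclusive coordinates, one entry per feature.
write_toy_gtf <- function(path, genes) {
  lines <- unlist(lapply(genes, function(g) {
    vapply(g$features, function(f) {
      paste(g$chrom, "test", f[[1]], f[[2]], f[[3]], ".", g$strand, ".",
            sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                    g$gene_id, if (is.null(g$gene_name)) g$gene_id else g$gene_name,
                    f[[4]]),
            sep = "\t")
    }, character(1))
  }))
  writeLines(lines, path)
  path
}

# one-row gene-model tibble without going through a GTF
toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     cds_start = 0, cds_end = 1000,
                     stop_anchor = if (strand == "+") cds_end else cds_start,
                     gene_start = cds_start, gene_end = cds_end,
                     is_target = TRUE) {
  tibble::tibble(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
                 strand = strand, cds_start = cds_start, cds_end = cds_end,
                 stop_anchor = stop_anchor, gene_start = gene_start,
                 gene_end = gene_end, is_target = is_target)
}

# standard multi-gene synthetic bundle used by closure/pipeline tests:
# nested isoforms on both strands, a single-isoform gene, spacing >= 300 nt
# between true ends and abundance steps that pass min_fold. Default depth is
# the study regime of 200 reads/kb of 75-nt reads, i.e. 15000 counts/kb in
# the per-base depth-sum currency (15x per-base coverage).
closure_truth <- function(seed = 101, depth_scale = 15000, with_intron = FALSE) {
  genes <- dplyr::bind_rows(
    synthetic_gene("OlfrS1", "+", 1000, c(500, 1200, 2400), c(0.5, 0.3, 0.2)),
    synthetic_gene("OlfrS2", "-", 900, c(800, 1900), c(0.6, 0.4)),
    synthetic_gene("OlfrS3", "+", 1200, 1500, 1,
                   intron = if (with_intron) c(400, 900, 0) else NULL))
  synthetic_truth(genes, depth_scale = depth_scale, seed = seed)
}
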