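test_that("single-isoform gene yields envelope CDS and strand-aware stop anchor", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gtf, list(
    list(gene_id = "OlfrA", chrom = "chr7", strand = "+",
         features = list(list("exon", 100, 500, "tA.1"),
                         list("CDS", 100, 397, "tA.1"),
                         list("stop_codon", 398, 400, "tA.1")))))
  gm <- parse_gene_models(gtf, target_pattern = "^Olfr")
  expect_equal(nrow(gm), 1)
  expect_equal(gm$cds_start, 99)   # 0-based half-open
  expect_equal(gm$cds_end, 400)
  expect_equal(gm$stop_anchor, 400)  # 3'UTR position 1 = genomic base 400
  expect_true(gm$is_target)
})

test_that("CDS envelope spans all isoforms and minus-strand anchor is minimal", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gtf, list(
    list(gene_id = "OlfrB", chrom = "chr2", strand = "+",
         features = list(list("CDS", 100, 397, "tB.1"),
                         list("stop_codon", 398, 400, "tB.1"),
                         list("CDS", 150, 397, "tB.2"),
                         list("stop_codon", 398, 400, "tB.2"))),
    list(gene_id = "OlfrC", chrom = "chr2", strand = "-",
         features = list(list("stop_codon", 1001, 1003, "tC.1"),
                         list("CDS", 1004, 1600, "tC.1")))))
  gm <- parse_gene_models(gtf, "^Olfr")
  b <- gm[gm$gene_id == "OlfrB", ]
  expect_equal(c(b$cds_start, b$cds_end), c(99, 400))  # union envelope
  cc <- gm[gm$gene_id == "OlfrC", ]
  expect_equal(cc$stop_anchor, 1000)  # 0-based start of the stop codon
  expect_equal(c(cc$cds_start, cc$cds_end), c(1000, 1600))
})

test_that("genes without CDS are skipped and curation drop_gene removes genes", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gtf, list(
    list(gene_id = "OlfrD", chrom = "chr1", strand = "+",
         features = list(list("CDS", 10, 97, "tD.1"),
                         list("stop_codon", 98, 100, "tD.1"))),
    list(gene_id = "OlfrPs", chrom = "chr1", strand = "+",
         features = list(list("exon", 500, 900, "tP.1"))),
    list(gene_id = "OlfrE", chrom = "chr1", strand = "+",
         features = list(list("CDS", 2000, 2297, "tE.1"),
                         list("stop_codon", 2298, 2300, "tE.1")))))
  cur <- tibble::tibble(gene_id = "OlfrE", action = "drop_gene",
                        payload = NA_character_)
  gm <- parse_gene_models(gtf, "^Olfr", curation = cur)
  expect_equal(gm$gene_id, "OlfrD")
  skipped <- attr(gm, "skipped")
  expect_setequal(skipped$gene_id, c("OlfrPs", "OlfrE"))
})

test_that("irreconcilable multi-stop genes error unless curated away", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  entry <- list(
    list(gene_id = "OlfrF", chrom = "chr3", strand = "+",
         features = list(list("CDS", 100, 397, "tF.1"),
                         list("stop_codon", 398, 400, "tF.1"),
                         list("CDS", 100, 697, "tF.2"),
                         list("stop_codon", 698, 700, "tF.2"))))
  write_toy_gtf(gtf, entry)
  expect_error(parse_gene_models(gtf, "^Olfr"), "OlfrF")
  cur <- tibble::tibble(gene_id = "OlfrF", action = "drop_transcript",
                        payload = "tF.2")
  gm <- parse_gene_models(gtf, "^Olfr", curation = cur)
  expect_equal(gm$stop_anchor, 400)
})

test_that("set_alt_locus splits a dual-locus gene into independent models", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gtf, list(
    list(gene_id = "OlfrG", chrom = "chr4", strand = "+",
         features = list(list("CDS", 100, 397, "tG.1"),
                         list("stop_codon", 398, 400, "tG.1"),
                         list("CDS", 5000, 5297, "tG.2"),
                         list("stop_codon", 5298, 5300, "tG.2")))))
  cur <- tibble::tibble(gene_id = "OlfrG", action = "set_alt_locus",
                        payload = NA_character_)
  gm <- parse_gene_models(gtf, "^Olfr", curation = cur)
  expect_equal(nrow(gm), 2)
  expect_setequal(gm$gene_id, c("OlfrG@1", "OlfrG@2"))
  expect_setequal(gm$stop_anchor, c(400, 5300))
})

test_that("mask regions follow flanking non-target CDS boundaries and the 25-kb edge rule", {
  genes <- dplyr::bind_rows(
    toy_gene("NT_A", cds_start = 1000, cds_end = 2000, is_target = FALSE),
    toy_gene("OlfrT1", cds_start = 10000, cds_end = 11000),
    toy_gene("OlfrT2", cds_start = 20000, cds_end = 21000),
    toy_gene("NT_B", cds_start = 30000, cds_end = 31000, is_target = FALSE),
    # second chromosome: no upstream non-target gene at all
    toy_gene("OlfrT3", chrom = "chr16", cds_start = 40000, cds_end = 41000),
    toy_gene("NT_C", chrom = "chr16", cds_start = 90000, cds_end = 91000,
             is_target = FALSE))
  regions <- build_mask(genes)
  r1 <- regions[regions$chrom == "chr1", ]
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(2000, 30000))  # flank CDS proximal ends
  expect_equal(r1$n_genes, 2)
  r16 <- regions[regions$chrom == "chr16", ]
  expect_equal(r16$start, 40000 - 25000)  # default edge when no upstream flank
  expect_equal(r16$end, 90000)
})

test_that("gene density is member CDS count per Mb of flank-to-flank span", {
  genes <- dplyr::bind_rows(
    toy_gene("NT_A", cds_start = 0, cds_end = 1000, is_target = FALSE),
    toy_gene("T1", cds_start = 100000, cds_end = 101000),
    toy_gene("T2", cds_start = 200000, cds_end = 201000),
    toy_gene("NT_B", cds_start = 501000, cds_end = 502000, is_target = FALSE))
  regions <- build_mask(genes)
  # 2 CDSs over 501000 - 1000 = 0.5 Mb
  expect_equal(regions$gene_density, 4.0)
})

test_that("build_mask is invariant to input row order", {
  genes <- dplyr::bind_rows(
    toy_gene("NT_A", cds_start = 0, cds_end = 500, is_target = FALSE),
    toy_gene("T1", cds_start = 5000, cds_end = 6000),
    toy_gene("NT_B", cds_start = 9000, cds_end = 9500, is_target = FALSE),
    toy_gene("T2", cds_start = 15000, cds_end = 16000))
  set.seed(3)
  shuffled <- genes[sample(nrow(genes)), ]
  a <- build_mask(genes)
  b <- build_mask(shuffled)
  expect_equal(a[, c("chrom", "start", "end", "n_genes")],
               b[, c("chrom", "start", "end", "n_genes")])
})

test_that("mask BED output round-trips region spans exactly", {
  genes <- dplyr::bind_rows(
    toy_gene("NT_A", cds_start = 0, cds_end = 500, is_target = FALSE),
    toy_gene("T1", cds_start = 1000, cds_end = 9000))
  regions <- build_mask(genes)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_mask_bed(regions, bed)
  back <- read_mask_bed(bed)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  expect_equal(back$chrom, regions$chrom)
  # empty region table writes a comment-only file that reads back empty
  write_mask_bed(regions[0, ], bed)
  expect_equal(nrow(read_mask_bed(bed)), 0)
})

test_that("every target gene lands in exactly one region", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    starts <- sort(sample(seq(1000, 500000, by = 1000), n))
    genes <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      toy_gene(paste0("G", i), cds_start = starts[i], cds_end = starts[i] + 500,
               is_target = runif(1) < 0.7)
    }))
    if (!any(genes$is_target)) genes$is_target[1] <- TRUE
    regions <- build_mask(genes)
    counts <- table(unlist(regions$gene_ids))
    expect_true(all(counts == 1))
    expect_setequal(names(counts), genes$gene_id[genes$is_target])
    expect_true(all(regions$n_genes >= 1))
  }
})
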