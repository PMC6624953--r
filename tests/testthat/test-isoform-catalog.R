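test_that("pilot-gene end sets merge into four polyA sites each", {
  # raw RNA-Seq-deduced 3' ends of the two pilot odorant-receptor genes
  s1507 <- merge_ends(c(1193, 1273, 2593, 4013, 4943))
  expect_equal(nrow(s1507), 4)
  expect_equal(c(s1507$span_start[1], s1507$span_end[1]), c(1193, 1273))
  expect_equal(s1507$representative_end, c(1273, 2593, 4013, 4943))
  s15 <- merge_ends(c(902, 2462, 2742, 4762, 4837))
  expect_equal(nrow(s15), 4)
  expect_equal(c(s15$span_start[4], s15$span_end[4]), c(4762, 4837))
})

test_that("merging is single-linkage, strict at 100 nt, and matches the union-find oracle", {
  # transitive chaining: pairwise gaps 90 < 100 chain into one 180-nt site
  chain <- merge_ends(c(100, 190, 280))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$span_end - chain$span_start, 180)
  # exactly 100 nt apart: no merge
  expect_equal(nrow(merge_ends(c(500, 600))), 2)
  set.seed(17)
  for (rep in 1:20) {
    ends <- sort(sample(1:3000, sample(2:12, 1)))
    got <- merge_ends(ends)$members
    expect_equal(unname(got), oracle_merge(ends))
  }
})

test_that("merging its own representatives is idempotent", {
  set.seed(19)
  for (rep in 1:20) {
    ends <- sort(sample(1:5000, sample(3:10, 1)))
    sites <- merge_ends(ends)
    again <- merge_ends(sites$representative_end)
    expect_equal(again$representative_end, sites$representative_end)
  }
})

test_that("fusion isoforms are discarded by strand-aware overlap rules", {
  gA <- toy_gene("OlfrA", cds_start = 1000, cds_end = 2000)
  gB <- toy_gene("OlfrB", cds_start = 6000, cds_end = 7000,
                 gene_start = 5600, gene_end = 7000)  # 5'UTR at 5600-6000
  gOpp <- toy_gene("NTopp", strand = "-", cds_start = 2500, cds_end = 3000,
                   is_target = FALSE)
  genes <- dplyr::bind_rows(gA, gB, gOpp)
  sites <- merge_gene_ends(tibble::tibble(
    gene_id = c("OlfrA", "OlfrA", "OlfrA"),
    utr_pos = c(400, 1500, 4500)), 100)
  # stranded: end at utr 4500 (genomic 6500) runs into OlfrB's CDS; the
  # opposite-strand CDS at 2500-3000 (utr 500-1000) is ignored
  res <- discard_fusions(sites, genes, stranded = TRUE)
  expect_equal(nrow(res$kept), 2)
  expect_equal(res$discarded$offending_gene, "OlfrB")
  # unstranded: the opposite-strand overlap (coverage superposition) also
  # discards the 1500-nt isoform, but not the 400-nt one
  res2 <- discard_fusions(sites, genes, stranded = FALSE)
  expect_equal(res2$kept$representative_end, 400)
  expect_true("NTopp" %in% res2$discarded$offending_gene)
  # an isoform reaching a neighboring target gene's 5'UTR is a fusion too
  sites_5p <- merge_gene_ends(tibble::tibble(gene_id = "OlfrA",
                                             utr_pos = 3700), 100)
  res3 <- discard_fusions(sites_5p, genes, stranded = TRUE)  # genomic 5700
  expect_equal(nrow(res3$kept), 0)
  expect_equal(res3$discarded$offending_gene, "OlfrB")
})

test_that("catalog ranks, categories and the statistics cap follow isoform count", {
  one <- merge_gene_ends(tibble::tibble(gene_id = "g1", utr_pos = 800), 100)
  expect_equal(catalog_isoforms(one)$category, "sUTR")
  four <- merge_gene_ends(tibble::tibble(
    gene_id = "g4", utr_pos = c(300, 900, 1700, 2600)), 100)
  cat4 <- catalog_isoforms(four)
  expect_equal(cat4$category, c("pUTR", "dUTR1", "dUTR2", "dUTR3"))
  expect_true(all(diff(cat4$length) > 0))
  expect_true(all(cat4$in_stats))
  six <- merge_gene_ends(tibble::tibble(
    gene_id = "g6", utr_pos = c(200, 500, 900, 1400, 2000, 2700)), 100)
  cat6 <- catalog_isoforms(six)
  expect_equal(nrow(cat6), 6)       # catalogued
  expect_true(all(!cat6$in_stats))  # but out of the summary statistics
  # empty site table: unannotated gene, empty catalog
  expect_equal(nrow(catalog_isoforms(one[0, ])), 0)
})

test_that("category labels are a pure function of rank and isoform count", {
  expect_equal(utr_category(1, 1), "sUTR")
  expect_equal(utr_category(1:3, 3), c("pUTR", "dUTR1", "dUTR2"))
  expect_equal(utr_category(5, 5), "dUTR4")
})
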