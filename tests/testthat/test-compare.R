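labels4 <- dataset_labels(
  name = c("m14", "m17", "f14", "f17"),
  sex = c("male", "male", "female", "female"),
  series = c("2014", "2017", "2014", "2017"))

test_that("pairwise conservation is strict at 200 nt and absence is never conserved", {
  expect_true(pairwise_conserved(1576, 1476))   # delta 100
  expect_false(pairwise_conserved(1000, 1200))  # delta exactly 200: strict
  expect_true(pairwise_conserved(1000, 1199))
  expect_false(pairwise_conserved(NA, 1000))
})

test_that("summary flags implement the four-comparison design", {
  # conserved everywhere -> ROBUST
  expect_equal(summary_flags(c(m14 = 1000, m17 = 1050, f14 = 980, f17 = 1010),
                             labels4), "ROBUST")
  # same-sex conserved, cross-sex divergent in both series -> SEX-SPE
  expect_equal(summary_flags(c(m14 = 1000, m17 = 1050, f14 = 1500, f17 = 1550),
                             labels4), "SEX-SPE")
  # cross-sex conserved within each series, series divergent -> EXP-SPE
  expect_equal(summary_flags(c(m14 = 1000, m17 = 1500, f14 = 1050, f17 = 1550),
                             labels4), "EXP-SPE")
  # mixed outcome -> none
  expect_equal(summary_flags(c(m14 = 1000, m17 = 1050, f14 = 1020, f17 = 1500),
                             labels4), "none")
  # the supplementary wording swaps the two specific labels
  expect_equal(summary_flags(c(m14 = 1000, m17 = 1050, f14 = 1500, f17 = 1550),
                             labels4, convention = "supplementary"), "EXP-SPE")
})

test_that("SEX-SPE and EXP-SPE are mutually exclusive over all pairwise outcomes", {
  # exhaustive truth table over the 2^4 outcomes of the four comparisons:
  # encode conserved pairs by picking lengths that realize each pattern
  combos <- expand.grid(ss1 = c(TRUE, FALSE), ss2 = c(TRUE, FALSE),
                        cs1 = c(TRUE, FALSE), cs2 = c(TRUE, FALSE))
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    # construct lengths: m14 fixed; m17 from ss1; f14 from cs1; f17 must
    # satisfy both ss2 (f14 vs f17) and cs2 (m17 vs f17) — search a grid
    m14 <- 10000
    m17 <- if (co$ss1) m14 else m14 + 5000
    f14 <- if (co$cs1) m14 + 100 else m14 + 2500
    f17 <- NA
    for (cand in seq(0, 30000, by = 50)) {
      ok_ss2 <- (abs(f14 - cand) < 200) == co$ss2
      ok_cs2 <- (abs(m17 - cand) < 200) == co$cs2
      if (ok_ss2 && ok_cs2) { f17 <- cand; break }
    }
    if (is.na(f17)) next  # pattern not realizable with these anchors
    flag <- summary_flags(c(m14 = m14, m17 = m17, f14 = f14, f17 = f17),
                          labels4)
    seen <- c(seen, flag)
    both <- (co$ss1 && co$ss2 && !co$cs1 && !co$cs2) &&
      (co$cs1 && co$cs2 && !co$ss1 && !co$ss2)
    expect_false(both)  # definitionally impossible
    if (co$ss1 && co$ss2 && !co$cs1 && !co$cs2) expect_equal(flag, "SEX-SPE")
    if (co$cs1 && co$cs2 && !co$ss1 && !co$ss2) expect_equal(flag, "EXP-SPE")
    if (all(unlist(co))) expect_equal(flag, "ROBUST")
  }
  expect_true(all(c("ROBUST", "SEX-SPE", "EXP-SPE", "none") %in% seen))
  expect_false(any(seen == "SEX-SPE" & seen == "EXP-SPE"))
})

test_that("summary flags are symmetric under relabeling of sexes and series", {
  lens <- c(m14 = 1000, m17 = 1050, f14 = 1500, f17 = 1550)
  swapped_series <- dataset_labels(
    name = c("m14", "m17", "f14", "f17"),
    sex = c("male", "male", "female", "female"),
    series = c("B", "A", "B", "A"))
  swapped_sex <- dataset_labels(
    name = c("m14", "m17", "f14", "f17"),
    sex = c("female", "female", "male", "male"),
    series = c("2014", "2017", "2014", "2017"))
  expect_equal(summary_flags(lens, swapped_series), "SEX-SPE")
  expect_equal(summary_flags(lens, swapped_sex), "SEX-SPE")
})

test_that("catalog comparison aligns ranks positionally and flags records", {
  mk <- function(gene, lens) {
    catalog_isoforms(merge_gene_ends(
      tibble::tibble(gene_id = gene, utr_pos = lens), 100))
  }
  cats <- list(m14 = mk("gA", c(500, 1600)), m17 = mk("gA", c(540, 1650)),
               f14 = mk("gA", c(510, 2600)), f17 = mk("gA", c(530, 2700)))
  cmp <- compare_catalogs(cats, labels4)
  expect_equal(nrow(cmp), 2)  # s/pUTR and dUTR1 records
  sp <- cmp[cmp$utr_rank == "s/pUTR", ]
  expect_equal(sp$flag, "ROBUST")
  d1 <- cmp[cmp$utr_rank == "dUTR1", ]
  expect_equal(d1$flag, "SEX-SPE")
  # a rank absent from one dataset is recorded and never conserved
  cats$m17 <- mk("gA", 540)
  cmp2 <- compare_catalogs(cats, labels4)
  d1b <- cmp2[cmp2$utr_rank == "dUTR1", ]
  expect_true(is.na(d1b$len_m17))
  expect_false(d1b$conserved_m14.m17)
})

test_that("gene-set intersections match brute-force membership counts", {
  cats <- list(
    a = tibble::tibble(gene_id = c("A", "B", "C")),
    b = tibble::tibble(gene_id = c("B", "C", "D")),
    c = tibble::tibble(gene_id = c("B", "E")),
    d = tibble::tibble(gene_id = c("B", "C", "E")))
  res <- common_genes(cats)
  expect_equal(res$common, "B")
  expect_equal(sum(res$venn$n), 5)  # union size A..E
  # brute-force recount of every Venn partition
  uni <- c("A", "B", "C", "D", "E")
  pat <- vapply(uni, function(g) {
    paste(names(cats)[vapply(cats, function(x) g %in% x$gene_id, logical(1))],
          collapse = "&")
  }, character(1))
  brute <- as.data.frame(table(pat), stringsAsFactors = FALSE)
  got <- res$venn[order(res$venn$pattern), ]
  expect_equal(got$n, brute$Freq[order(brute$pat)])
  pc <- res$pair_counts
  expect_equal(pc$n_common[pc$a == "a" & pc$b == "b"], 2)
  expect_equal(common_genes(list(a = cats$a[0, ], b = cats$b))$common,
               character(0))
})
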