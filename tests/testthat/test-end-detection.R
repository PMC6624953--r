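test_that("scan projects coverage into nt-after-stop space on both strands", {
  # + strand: depth 5 for 300 nt after the stop, then nothing
  d <- numeric(2000); d[1001:1300] <- 5
  tr <- coverage_track("chr1", 0, 2000, d)
  g <- toy_gene("gp", cds_start = 500, cds_end = 1000)
  v <- scan_region(tr, g)
  expect_equal(length(v), 300)
  expect_true(all(v == 5))
  # - strand mirror: 3'UTR runs leftward from the anchor
  d2 <- numeric(2000); d2[701:1000] <- 4
  g2 <- toy_gene("gm", strand = "-", cds_start = 1000, cds_end = 1500)
  v2 <- scan_region(coverage_track("chr1", 0, 2000, d2), g2)
  expect_equal(length(v2), 300)
  expect_true(all(v2 == 4))
})

test_that("zero gaps up to merge_radius are bridged, longer gaps truncate the scan", {
  base <- c(rep(3, 400), numeric(150), rep(3, 200))
  tr_short <- coverage_track("c", 0, 2000,
                             c(numeric(1000), base, numeric(2000 - 1000 - length(base))))
  g <- toy_gene("g", cds_start = 500, cds_end = 1000)
  v <- scan_region(tr_short, g)  # 150-nt gap retained
  expect_equal(length(v), 750)
  expect_true(all(v[401:550] == 0))
  base2 <- c(rep(3, 400), numeric(250), rep(3, 200))
  tr_long <- coverage_track("c", 0, 2000,
                            c(numeric(1000), base2, numeric(2000 - 1000 - length(base2))))
  v2 <- scan_region(tr_long, g)  # 250-nt gap truncates at the gap start
  expect_equal(length(v2), 400)
  expect_true(attr(v2, "truncated_at_gap"))
})

test_that("scan stops at the nearest neighboring CDS edge and region boundary", {
  d <- rep(2, 3000)
  tr <- coverage_track("c", 0, 3000, d)
  g <- toy_gene("g", cds_start = 100, cds_end = 600)
  nb <- toy_gene("nb", cds_start = 1600, cds_end = 2000)
  v <- scan_region(tr, g, neighbors = dplyr::bind_rows(g, nb))
  expect_equal(length(v), 1000)  # stops at the neighbor CDS start
  # anchor at the region edge: unannotatable
  edge_gene <- toy_gene("ge", cds_start = 2500, cds_end = 3000)
  expect_equal(length(scan_region(tr, edge_gene)), 0)
})

test_that("noiseless staircases are segmented exactly at their boundaries", {
  v <- c(rep(100, 500), rep(20, 400))
  ends <- segment_changepoints(v)
  expect_equal(ends$utr_pos, c(500, 900))
  expect_equal(ends$kind, c("changepoint", "extinction"))
  expect_equal(ends$drop_ratio[1], 0.2)
  # a 100 -> 90 step fails min_fold 0.8: only the extinction end remains
  v2 <- c(rep(100, 500), rep(90, 400))
  expect_equal(segment_changepoints(v2)$utr_pos, 900)
  # constant coverage: extinction end only
  v3 <- rep(7, 1000)
  e3 <- segment_changepoints(v3)
  expect_equal(e3$utr_pos, 1000)
  expect_equal(e3$downstream_mean, 0)
  # all-zero coverage: nothing
  expect_equal(nrow(segment_changepoints(numeric(500))), 0)
})

test_that("detector matches the exhaustive Poisson-deviance oracle", {
  set.seed(23)
  cases <- list(
    c(rep(50, 300), rep(10, 300)),
    c(rep(80, 400), rep(30, 500), rep(5, 400)),
    c(rep(9, 150), rep(2, 350), rep(1, 500)),
    rpois(1200, 3),
    c(rpois(600, 20), rpois(700, 4)),
    c(rpois(500, 15), rpois(500, 8), rpois(500, 1)))
  for (v in cases) {
    expect_equal(segment_changepoints(v)$utr_pos, oracle_segment(v))
  }
})

test_that("raising min_fold never loses ends on noiseless staircases", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    lens <- sample(150:500, k, replace = TRUE)
    depths <- sort(round(runif(k, 1, 100)), decreasing = TRUE)
    v <- rep(depths, lens)
    n05 <- nrow(segment_changepoints(v, seg_params(min_fold = 0.5)))
    n08 <- nrow(segment_changepoints(v, seg_params(min_fold = 0.8)))
    expect_gte(n08, n05)
  }
})

test_that("trailing zeros beyond the extinction end do not change the result", {
  v <- c(rep(40, 300), rep(8, 300))
  expect_equal(segment_changepoints(v), segment_changepoints(c(v, numeric(500))))
})

test_that("max_isoform caps the number of segments", {
  v <- rep(c(1024, 256, 64, 16, 4), each = 200) # four valid drops
  expect_equal(nrow(segment_changepoints(v)), 5)
  capped <- segment_changepoints(v, seg_params(max_isoform = 3))
  expect_equal(nrow(capped), 3)
})

test_that("very short ends are retained and flagged, sub-UTR positions dropped", {
  ends <- tibble::tibble(utr_pos = c(-5L, 69L, 100L, 900L),
                         upstream_mean = 1, downstream_mean = 0,
                         drop_ratio = 0, kind = "changepoint")
  out <- filter_ends(ends)
  expect_equal(out$utr_pos, c(69L, 100L, 900L))
  expect_equal(out$very_short, c(TRUE, FALSE, FALSE))  # strict < 100
  expect_equal(nrow(filter_ends(ends[0, ])), 0)
})
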