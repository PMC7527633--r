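test_that("nearest-rank threshold selects the literal top fraction", {
  vals <- sample(1:200)
  thr <- empirical_threshold(vals, q = 0.01)
  expect_equal(thr, 199)
  expect_equal(sum(vals >= thr), 2)
  # infinities outrank everything and are always selected
  thr2 <- empirical_threshold(c(vals, Inf, Inf), q = 0.01)
  expect_true(all(c(Inf, Inf) >= thr2))
  # degenerate ties warn and select everything
  expect_warning(thr3 <- empirical_threshold(rep(5, 50), q = 0.1),
                 "identical")
  expect_equal(sum(rep(5, 50) >= thr3), 50)
  expect_error(empirical_threshold(numeric(0)), "no values")
})

test_that("decreasing q never increases the selected count", {
  set.seed(8)
  vals <- rnorm(500)
  counts <- vapply(c(0.2, 0.1, 0.05, 0.01), function(q) {
    sum(vals >= empirical_threshold(vals, q))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

fake_stats <- function(fst, ratio, valid = TRUE, chrom = "chr1",
                       start = NULL) {
  n <- length(fst)
  start <- start %||% seq(0, by = 1e4, length.out = n)
  tibble::tibble(chrom = chrom, start = start, end = start + 1e5,
                 partial = FALSE, n_snvs = 50L, pi_pop1 = 1e-4,
                 pi_pop2 = 1e-4 * ratio, pi_ratio = ratio, fst = fst,
                 valid = valid)
}

test_that("joint selection is an intersection, never a union", {
  set.seed(9)
  st <- fake_stats(fst = runif(300), ratio = runif(300, 0.5, 2))
  thr <- scan_thresholds(st, q = 0.05)
  sel <- select_windows(st, thr)
  expect_true(all(sel$fst >= thr$fst_threshold &
                    sel$pi_ratio >= thr$ratio_threshold))
  n_fst <- sum(st$fst >= thr$fst_threshold)
  n_ratio <- sum(st$pi_ratio >= thr$ratio_threshold)
  expect_lte(nrow(sel), min(n_fst, n_ratio))
  # a window in the top tail of F_ST only is not selected
  st2 <- fake_stats(fst = c(10, 1:99 / 100), ratio = c(0.1, 1:99 / 10))
  thr2 <- scan_thresholds(st2, q = 0.02)
  sel2 <- select_windows(st2, thr2)
  expect_false(st2$start[1] %in% sel2$start)
  # invalid windows are never selected
  st3 <- fake_stats(fst = c(10, runif(99)), ratio = c(10, runif(99, 0.5, 2)),
                    valid = c(FALSE, rep(TRUE, 99)))
  sel3 <- select_windows(st3, scan_thresholds(st3, q = 0.05))
  expect_false(st3$start[1] %in% sel3$start)
})

test_that("regions merge overlapping and book-ended windows", {
  sel <- fake_stats(fst = c(0.9, 0.8, 0.7), ratio = c(3, 4, 5),
                    start = c(0, 1e4, 2e6))
  reg <- merge_regions(sel)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(0, 2e6))
  expect_equal(reg$end, c(1.1e5, 2.1e6))
  expect_equal(reg$n_windows, c(2L, 1L))
  expect_equal(reg$max_fst, c(0.9, 0.7))
  expect_equal(reg$max_ratio, c(4, 5))
  # book-ended windows merge
  sel2 <- fake_stats(fst = c(0.9, 0.8), ratio = c(3, 3),
                     start = c(0, 1e5))
  expect_equal(nrow(merge_regions(sel2)), 1)
  # merging is idempotent on already-disjoint regions
  reg2 <- merge_regions(sel)
  expect_equal(merge_regions(dplyr::mutate(reg2, fst = max_fst,
                                           pi_ratio = max_ratio,
                                           n_snvs = 1L))[, c("chrom", "start", "end")],
               reg2[, c("chrom", "start", "end")])
})

test_that("157 disjoint 100-kb selections total 15.7 Mb", {
  sel <- fake_stats(fst = rep(0.9, 157), ratio = rep(3, 157),
                    start = seq(0, by = 5e5, length.out = 157))
  reg <- merge_regions(sel)
  expect_equal(nrow(reg), 157)
  expect_equal(sum(reg$end - reg$start), 15.7e6)
})

test_that("region span is bounded by window count and region count", {
  set.seed(10)
  sel <- fake_stats(fst = runif(40, 0.5, 1), ratio = runif(40, 2, 5),
                    start = sort(sample(seq(0, 5e6, by = 1e4), 40)))
  reg <- merge_regions(sel)
  span <- sum(reg$end - reg$start)
  expect_lte(span, nrow(sel) * 1e5)
  expect_gte(span, nrow(reg) * 1e5)
})

test_that("gene-region overlap matches a brute-force interval scan", {
  genes <- synthetic_gene_models(c(chr1 = 1e6, chr2 = 1e6), spacing = 5e4)
  set.seed(11)
  starts <- sort(sample(seq(0, 9e5, by = 1e4), 6))
  regions <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 6, TRUE),
                            start = starts, end = starts + 1.5e5)
  got <- genes_in_regions(regions, genes)
  for (k in seq_len(nrow(regions))) {
    expected <- genes$gene_id[genes$chrom == regions$chrom[k] &
                                genes$start < regions$end[k] &
                                genes$end > regions$start[k]]
    expect_setequal(got$genes[[k]], expected)
  }
  # 1-bp overlap counts; full containment mode excludes it
  g1 <- genes[1, ]  # chr1 gene at [10000, 12600)
  r <- tibble::tibble(chrom = "chr1", start = 12599, end = 20000)
  expect_equal(genes_in_regions(r, genes)$n_genes, 1L)
  expect_equal(genes_in_regions(r, genes, full_containment = TRUE)$n_genes, 0L)
})

test_that("feature overlap summarises per class with percentages", {
  regions <- tibble::tibble(chrom = "chr1", start = c(0, 5e5),
                            end = c(1e5, 6e5))
  feats <- tibble::tibble(
    chrom = "chr1",
    start = c(1e4, 9e4, 5.5e5, 2e5, 3e5),
    end = c(2e4, 1.1e5, 5.6e5, 2.1e5, 3.1e5),
    class = c("A", "A", "B", "A", "C")
  )
  out <- feature_overlap(regions, feats)
  expect_equal(out$n_overlapping[out$class == "A"], 2L)
  expect_equal(out$n_overlapping[out$class == "B"], 1L)
  expect_equal(out$n_overlapping[out$class == "C"], 0L)
  expect_equal(out$pct_of_overlapping[out$class == "A"], 100 * 2 / 3)
  expect_equal(out$pct_of_overlapping[out$class == "B"], 100 * 1 / 3)
  empty <- feature_overlap(regions, feats[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("recovery scoring handles identity and degenerate cases", {
  truth <- tibble::tibble(chrom = "chr1", start = c(1e6, 5e6),
                          end = c(1.3e6, 5.3e6))
  sc <- score_recovery(truth, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$jaccard, 1)
  expect_equal(sc$interval_recall, 1)
  none <- score_recovery(truth[0, ], truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
  # partial overlap arithmetic
  det <- tibble::tibble(chrom = "chr1", start = 1.15e6, end = 1.45e6)
  sc2 <- score_recovery(det, truth)
  expect_equal(sc2$precision, 1.5e5 / 3e5)
  expect_equal(sc2$recall, 1.5e5 / 6e5)
  expect_equal(sc2$interval_recall, 0.5)
})

test_that("null scans select no more than each marginal top-q count", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), n_sites = 5000,
                    background_f = 0.05, sweep_intervals = NULL,
                    missing_rate = 0, seed = 14)
  ws <- window_stats(simulate_cohort(cfg)$genotypes)
  sc <- sweep_scan(ws, q = 0.01)
  n_fst <- sum(ws$fst >= sc$thresholds$fst_threshold & ws$valid, na.rm = TRUE)
  n_rat <- sum(ws$pi_ratio >= sc$thresholds$ratio_threshold & ws$valid,
               na.rm = TRUE)
  expect_lte(nrow(sc$selected), min(n_fst, n_rat))
})
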