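test_that("site_pi matches explicit allele-pair enumeration", {
  # {A,A,T,T}: 4 of 6 pairs differ -> 2/3
  expect_equal(site_pi(c(0L, 2L)), 2 / 3)
  expect_equal(oracle_site_pi(c(0L, 2L)), 2 / 3)
  # two heterozygotes: same allele counts, same value
  expect_equal(site_pi(c(1L, 1L)), 2 / 3)
  # monomorphic
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)
  # one called heterozygote still carries two alleles: one differing pair
  expect_equal(site_pi(c(1L, NA, NA)), 1)
  expect_equal(oracle_site_pi(c(1L, NA, NA)), 1)
  # fewer than two called alleles contributes zero
  expect_equal(site_pi(c(NA, NA, NA)), 0)
  # random cases against the oracle
  set.seed(4)
  for (k in 1:20) {
    d <- sample(c(0L, 1L, 2L, NA), 7, replace = TRUE)
    expect_equal(site_pi(d), oracle_site_pi(d))
  }
})

test_that("window_pi equals the explicit pairwise-difference oracle", {
  g <- random_g(n = 6, m = 20, miss = 0.2, seed = 9,
                pos = sort(sample(1:50000, 20)),
                chrom_lengths = c(chr1 = 60000))
  wp <- window_pi(g, "pop1", window_size = 30000, step_size = 15000,
                  min_snvs = 1)
  for (k in seq_len(nrow(wp))) {
    expect_equal(wp$pi[k],
                 oracle_window_pi(g, "pop1", wp$chrom[k], wp$start[k],
                                  wp$end[k]))
  }
  # zero-SNV window: pi 0 and invalid
  g2 <- make_g(matrix(c(0L, 1L, 2L, 0L), 4, 1), pos = 5,
               chrom_lengths = c(chr1 = 250000))
  wp2 <- window_pi(g2, "pop1", window_size = 100000, step_size = 100000)
  expect_equal(wp2$pi[2], 0)
  expect_false(wp2$valid[2])
})

test_that("window pi sums are additive over disjoint windows", {
  g <- random_g(n = 8, m = 50, miss = 0.1, seed = 11,
                pos = sort(sample(1:99999, 50)),
                chrom_lengths = c(chr1 = 1e5))
  whole <- window_pi(g, "pop1", window_size = 1e5, step_size = 1e5)
  parts <- window_pi(g, "pop1", window_size = 2e4, step_size = 2e4)
  expect_equal(sum(parts$pi * (parts$end - parts$start)),
               whole$pi[1] * 1e5)
})

test_that("Watterson's theta follows the harmonic-number closed form", {
  # S = 1 segregating site, 4 called alleles, span 100 kb
  d <- matrix(c(0L, 1L), nrow = 2, ncol = 1)
  g <- make_g(d, populations = c("pop1", "pop1"), pos = 50,
              chrom_lengths = c(chr1 = 1e5))
  th <- watterson_theta(g, "pop1", min_snvs = 1)
  expect_equal(th$theta[1], 1 / ((1 + 1 / 2 + 1 / 3) * 1e5))
  expect_equal(th$s[1], 1L)
  # S = 0
  g0 <- make_g(matrix(0L, 2, 1), populations = c("pop1", "pop1"),
               pos = 50, chrom_lengths = c(chr1 = 1e5))
  expect_equal(watterson_theta(g0, "pop1")$theta[1], 0)
  # no missingness: matches textbook theta_W with n = 2N alleles
  set.seed(5)
  d2 <- matrix(rbinom(10 * 30, 2, 0.3), nrow = 10)
  g2 <- make_g(d2, populations = rep("pop1", 10),
               pos = sort(sample(1:9e4, 30)), chrom_lengths = c(chr1 = 1e5))
  th2 <- watterson_theta(g2, "pop1", min_snvs = 1)
  S <- sum(apply(d2, 2, function(x) {
    a <- sum(x); a > 0 && a < 2 * length(x)
  }))
  expect_equal(th2$theta[1], S / (sum(1 / 1:19) * 1e5))
})

test_that("Weir-Cockerham limits behave: no differentiation and fixation", {
  # p1 = p2, equal sizes, HWE genotypes -> a ~ 0, estimate <= 0
  d1 <- c(rep(0L, 4), rep(1L, 8), rep(2L, 4))
  comp <- wc_fst_components(d1, d1)
  est <- comp$a / (comp$a + comp$b + comp$c)
  expect_lt(abs(comp$a), 0.01)
  expect_lte(est, 0)
  # fixed difference, all homozygous -> exactly 1
  comp2 <- wc_fst_components(rep(0L, 10), rep(2L, 10))
  expect_equal(comp2$a / (comp2$a + comp2$b + comp2$c), 1)
})

test_that("Weir-Cockerham components match a literal transcription", {
  # HWE-rounded genotype counts at p1 = 0.2 (n = 20), p2 = 0.8 (n = 13)
  d1 <- c(rep(0L, 13), rep(1L, 6), rep(2L, 1))
  d2 <- c(rep(0L, 1), rep(1L, 4), rep(2L, 8))
  mine <- wc_fst_components(d1, d2)
  oracle <- oracle_wc(d1, d2)
  expect_equal(mine$a, oracle$a)
  expect_equal(mine$b, oracle$b)
  expect_equal(mine$c, oracle$c)
  # randomized cases, with missingness
  set.seed(12)
  for (k in 1:25) {
    x <- sample(c(0L, 1L, 2L, NA), 15, replace = TRUE)
    y <- sample(c(0L, 1L, 2L, NA), 9, replace = TRUE)
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
    mine <- wc_fst_components(x, y)
    oracle <- oracle_wc(x, y)
    expect_equal(mine$a, oracle$a)
    expect_equal(mine$b, oracle$b)
    expect_equal(mine$c, oracle$c)
  }
  # a population with < 2 called alleles is skipped
  expect_null(wc_fst_components(c(NA, NA, NA), c(0L, 1L, 2L)))
})

test_that("window F_ST hits its null and fixed-difference limits", {
  # fixed differences at every site -> 1.0
  n1 <- 6; n2 <- 5; m <- 12
  g <- make_g(rbind(matrix(0L, n1, m), matrix(2L, n2, m)),
              populations = rep(c("pop1", "pop2"), c(n1, n2)),
              pos = seq(1000, by = 500, length.out = m),
              chrom_lengths = c(chr1 = 1e4))
  wf <- window_fst(g, window_size = 1e4, step_size = 1e4, min_snvs = 1)
  expect_equal(wf$fst[1], 1)
  expect_equal(genome_fst(g, "hudson"), 1)
})

test_that("window statistics are invariant to sample order and allele swap", {
  sim <- small_cohort(seed = 6, n_sites = 800)
  g <- sim$genotypes
  ws <- window_stats(g, min_snvs = 1)
  # permute samples
  perm <- sample(nrow(g$dosages))
  gp <- genotype_matrix(g$dosages[perm, ], g$sites, g$samples[perm, ],
                        chrom_lengths = g$chrom_lengths)
  wsp <- window_stats(gp, min_snvs = 1)
  expect_equal(ws$fst, wsp$fst)
  expect_equal(ws$pi_pop1, wsp$pi_pop1)
  # relabel REF/ALT (dosage d -> 2 - d)
  d2 <- 2L - g$dosages
  gs <- genotype_matrix(d2, transform(g$sites, ref = alt, alt = ref),
                        g$samples, chrom_lengths = g$chrom_lengths)
  wss <- window_stats(gs, min_snvs = 1)
  expect_equal(ws$fst, wss$fst)
  expect_equal(ws$pi_pop1, wss$pi_pop1)
  expect_equal(ws$pi_ratio, wss$pi_ratio)
})

test_that("WC and Hudson estimators agree on balanced HWE cohorts", {
  cfg <- sim_config(n_pop1 = 16, n_pop2 = 16,
                    chrom_lengths = c(chr1 = 2e6), n_sites = 8000,
                    background_f = 0.1, sweep_intervals = NULL,
                    missing_rate = 0, seed = 10)
  g <- simulate_cohort(cfg)$genotypes
  wc <- window_stats(g, estimator = "wc")
  hu <- window_stats(g, estimator = "hudson")
  ok <- wc$valid
  expect_lt(max(abs(wc$fst[ok] - hu$fst[ok])), 0.02)
})

test_that("the diversity ratio has sweep-scan semantics", {
  expect_equal(pi_ratio(2e-4, 2e-4), 1)
  expect_identical(pi_ratio(0, 1e-4), Inf)
  expect_true(is.na(pi_ratio(0, 0)))
  # planted sweeps push the ratio up relative to the background median
  sim <- simulate_cohort(sim_config(
    chrom_lengths = c(chr1 = 10e6), n_sites = 10000,
    sweep_intervals = tibble::tibble(chrom = "chr1", start = 4e6,
                                     end = 4.3e6), seed = 2
  ))
  ws <- window_stats(sim$genotypes)
  insw <- ws$start >= 4e6 & ws$end <= 4.3e6
  expect_gt(median(ws$pi_ratio[insw]), median(ws$pi_ratio[ws$valid]))
})
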