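# Small genotype-matrix builders and independent brute-force oracles used
# across the suite. Oracles deliberately take the slow, literal route
# (explicit enumeration) so they share no code with the implementation.

make_g <- function(dosages, populations = NULL, chrom = "chr1", pos = NULL,
                   ref = NULL, alt = NULL, qual = NULL, chrom_lengths = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(populations)) {
    populations <- rep(c("pop1", "pop2"), c(ceiling(n / 2), floor(n / 2)))
  }
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  sites <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = ref %||% rep("A", m), alt = alt %||% rep("G", m)
  )
  if (!is.null(qual)) sites$qual <- qual
  samples <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)), population = populations
  )
  genotype_matrix(dosages, sites, samples, chrom_lengths = chrom_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random dosage matrix with given missing rate.
random_g <- function(n = 8, m = 40, miss = 0.1, seed = 1, ...) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(seq_len(m), each = n)]),
              nrow = n)
  d[runif(n * m) < miss] <- NA
  make_g(d, ...)
}

# --- oracles ---------------------------------------------------------------

# Per-site diversity by explicit enumeration of all pairs of called alleles.
oracle_site_pi <- function(dosages) {
  alleles <- integer(0)
  for (d in dosages) {
    if (is.na(d)) next
    alleles <- c(alleles, switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L)))
  }
  c_tot <- length(alleles)
  if (c_tot < 2) return(0)
  diff <- 0L; pairs <- 0L
  for (i in seq_len(c_tot - 1)) {
    for (j in (i + 1):c_tot) {
      pairs <- pairs + 1L
      if (alleles[i] != alleles[j]) diff <- diff + 1L
    }
  }
  diff / pairs
}

# Window diversity: sum of per-site oracle values over sites inside the
# 0-based half-open window, divided by span.
oracle_window_pi <- function(g, population, chrom, start, end) {
  rows <- which(g$samples$population == population)
  tot <- 0
  for (k in seq_len(nrow(g$sites))) {
    if (g$sites$chrom[k] != chrom) next
    p0 <- g$sites$pos[k] - 1
    if (p0 < start || p0 >= end) next
    tot <- tot + oracle_site_pi(g$dosages[rows, k])
  }
  tot / (end - start)
}

# Literal transcription of the two-population Weir & Cockerham (1984)
# variance components, written from the published formulas with r kept
# symbolic and every sum explicit.
oracle_wc <- function(d1, d2) {
  d <- list(d1[!is.na(d1)], d2[!is.na(d2)])
  r <- 2
  n <- vapply(d, length, numeric(1))
  if (any(n < 1)) return(NULL)
  p <- vapply(d, function(x) sum(x) / (2 * length(x)), numeric(1))
  h <- vapply(d, function(x) mean(x == 1), numeric(1))
  nbar <- sum(n) / r
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Pairwise r^2 by direct correlation of two dosage vectors.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  suppressWarnings(cor(x[ok], y[ok])^2)
}

# Count sites inside a half-open region by literal membership test
# (region end exclusive against the site position).
oracle_region_count <- function(g, chrom, start, end) {
  count <- 0L
  for (k in seq_len(nrow(g$sites))) {
    if (g$sites$chrom[k] == chrom && g$sites$pos[k] >= start &&
        g$sites$pos[k] < end) {
      count <- count + 1L
    }
  }
  count
}

# Small simulated cohort shared by several structure tests.
small_cohort <- function(seed = 5, n_sites = 4000, f = 0.1) {
  simulate_cohort(sim_config(
    chrom_lengths = c(chr1 = 2e6), n_sites = n_sites, background_f = f,
    sweep_intervals = NULL, missing_rate = 0.02, seed = seed
  ))
}
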