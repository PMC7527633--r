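#' Per-site nucleotide diversity for one population
#'
#' Unbiased pairwise heterozygosity at a single biallelic site:
#' `2 * c_ref * c_alt / (c * (c - 1))` where `c` is the number of called
#' alleles and `c_ref`, `c_alt` the allele counts. Equals the mean fraction of
#' differing allele pairs over all `choose(c, 2)` pairs of called alleles.
#'
#' @param dosages Integer vector of ALT dosages (0/1/2, `NA` = missing) for the
#'   samples of one population at one site.
#' @return Per-site diversity; 0 when fewer than two alleles are called.
#' @export
site_pi <- function(dosages) {
  n <- sum(!is.na(dosages))
  ca <- 2 * n
  if (ca < 2) return(0)
  alt <- sum(dosages, na.rm = TRUE)
  2 * alt * (ca - alt) / (ca * (ca - 1))
}

# Vectorised site_pi from allele_counts() bookkeeping.
site_pi_vec <- function(ac) {
  ifelse(ac$c >= 2, 2 * ac$a * (ac$c - ac$a) / (ac$c * pmax(ac$c - 1, 1)), 0)
}

#' Weir-Cockerham variance components at one site
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components of the
#' Weir-Cockerham F_ST estimator for two populations from genotype dosages,
#' using sample sizes, allele frequencies and observed heterozygosities.
#' The per-site estimate is `a / (a + b + c)`; multi-site estimates should
#' use the ratio of summed components (see [window_fst()]).
#'
#' @param dosages_pop1,dosages_pop2 Integer dosage vectors (0/1/2/`NA`) for
#'   the two populations at one site.
#' @return A list with components `a`, `b`, `c`, or `NULL` when either
#'   population has fewer than two called alleles (site skipped).
#' @export
wc_fst_components <- function(dosages_pop1, dosages_pop2) {
  n1 <- sum(!is.na(dosages_pop1)); n2 <- sum(!is.na(dosages_pop2))
  if (2 * n1 < 2 || 2 * n2 < 2 || (n1 + n2) / 2 <= 1) return(NULL)
  comp <- wc_components_vec(
    n1 = n1, n2 = n2,
    p1 = sum(dosages_pop1, na.rm = TRUE) / (2 * n1),
    p2 = sum(dosages_pop2, na.rm = TRUE) / (2 * n2),
    h1 = sum(dosages_pop1 == 1L, na.rm = TRUE) / n1,
    h2 = sum(dosages_pop2 == 1L, na.rm = TRUE) / n2
  )
  list(a = comp$a, b = comp$b, c = comp$c)
}

# Vectorised Weir-Cockerham (1984) two-population components from per-site
# diploid counts n_i, ALT frequencies p_i and observed het proportions h_i.
wc_components_vec <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# All per-site quantities needed by the window statistics, vectorised over
# sites. Sites unusable for F_ST (a population with < 2 called alleles, or
# mean sample size <= 1) carry NA components.
per_site_stats <- function(g) {
  pops <- populations(g)
  if (length(pops) != 2) abort("two-population statistics need exactly two population labels.")
  ac1 <- allele_counts(g, pops[1])
  ac2 <- allele_counts(g, pops[2])
  pi1 <- site_pi_vec(ac1)
  pi2 <- site_pi_vec(ac2)
  usable <- ac1$c >= 2 & ac2$c >= 2 & (ac1$n + ac2$n) / 2 > 1
  p1 <- ifelse(ac1$c > 0, ac1$a / ac1$c, NA_real_)
  p2 <- ifelse(ac2$c > 0, ac2$a / ac2$c, NA_real_)
  wc <- wc_components_vec(n1 = ac1$n, n2 = ac2$n, p1 = p1, p2 = p2,
                          h1 = ifelse(ac1$n > 0, ac1$h / ac1$n, NA_real_),
                          h2 = ifelse(ac2$n > 0, ac2$h / ac2$n, NA_real_))
  a <- ifelse(usable, wc$a, NA_real_)
  b <- ifelse(usable, wc$b, NA_real_)
  cc <- ifelse(usable, wc$c, NA_real_)
  # Hudson: between-population heterozygosity and unbiased mean within
  hb <- ifelse(usable, p1 * (1 - p2) + p2 * (1 - p1), NA_real_)
  hw <- ifelse(usable, (pi1 + pi2) / 2, NA_real_)
  list(pi1 = pi1, pi2 = pi2, a = a, b = b, c = cc, hb = hb, hw = hw,
       usable = usable, pops = pops)
}

default_chrom_lengths <- function(g, chrom_lengths = NULL) {
  cl <- chrom_lengths %||% g$chrom_lengths
  if (is.null(cl)) {
    cl <- tapply(g$sites$pos, g$sites$chrom, max)
    cl <- setNames(as.numeric(cl), names(cl))
    inform("no chromosome lengths available; using the largest observed position per chromosome.")
  }
  cl
}

#' Sliding-window diversity and differentiation statistics
#'
#' The workhorse of the sweep scan: computes, on a sliding-window grid
#' (default 100-kb windows, 10-kb steps), per-population nucleotide diversity
#' normalised by window span, the diversity ratio `pi_pop2 / pi_pop1`
#' (wild over domestic, so diversity loss in population 1 inflates it), and
#' window F_ST as a ratio of summed per-site components — Weir-Cockerham
#' `sum(a) / sum(a + b + c)` by default, or the Hudson estimator
#' `1 - sum(hw) / sum(hb)`.
#'
#' Windows with fewer than `min_snvs` SNVs, partial trailing windows, and
#' windows with an undefined F_ST denominator are flagged `valid = FALSE`;
#' invalid windows never enter empirical thresholds or selections.
#' A window with `pi_pop1 = 0` and `pi_pop2 > 0` gets an infinite ratio and is
#' retained (it sorts above every finite value); `0/0` gives `NA`.
#'
#' @param g A [genotype_matrix()] with two populations.
#' @param window_size,step_size Grid geometry in bp.
#' @param min_snvs Minimum SNV count for a window to be considered valid.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @param chrom_lengths Optional named chromosome lengths; defaults to those
#'   stored in `g`.
#' @return A tibble of class `window_stats`: `chrom`, `start`, `end`,
#'   `partial`, `n_snvs`, `pi_pop1`, `pi_pop2`, `pi_ratio`, `fst`, `valid`.
#' @export
window_stats <- function(g, window_size = 100000, step_size = 10000,
                         min_snvs = 10, estimator = c("wc", "hudson"),
                         chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  estimator <- match.arg(estimator)
  cl <- default_chrom_lengths(g, chrom_lengths)
  grid <- make_windows(cl, window_size, step_size)
  ps <- per_site_stats(g)
  pairs <- window_site_pairs(grid, g$sites$chrom, g$sites$pos)
  nw <- nrow(grid)

  n_snvs <- count_by_window(pairs, nw)
  span <- grid$end - grid$start
  pi1 <- sum_by_window(ps$pi1, pairs, nw) / span
  pi2 <- sum_by_window(ps$pi2, pairs, nw) / span
  if (estimator == "wc") {
    num <- sum_by_window(ps$a, pairs, nw)
    den <- sum_by_window(ps$a + ps$b + ps$c, pairs, nw)
    fst <- ifelse(den != 0, num / den, NA_real_)
  } else {
    num <- sum_by_window(ps$hw, pairs, nw)
    den <- sum_by_window(ps$hb, pairs, nw)
    fst <- ifelse(den != 0, 1 - num / den, NA_real_)
  }
  ratio <- pi_ratio(pi1, pi2)

  out <- grid
  out$n_snvs <- n_snvs
  out$pi_pop1 <- pi1
  out$pi_pop2 <- pi2
  out$pi_ratio <- ratio
  out$fst <- fst
  out$valid <- n_snvs >= min_snvs & !grid$partial & !is.na(fst)
  attr(out, "estimator") <- estimator
  attr(out, "populations") <- ps$pops
  attr(out, "window_size") <- window_size
  attr(out, "step_size") <- step_size
  class(out) <- c("window_stats", class(out))
  out
}

#' Diversity ratio with sweep-scan semantics
#'
#' `pi_pop2 / pi_pop1` (reference/wild over focal/domestic). A window where
#' the focal population has lost all diversity while the reference retains
#' some returns `+Inf` (kept: it outranks any finite ratio); `0/0` returns
#' `NA` (uninformative window).
#'
#' @param pi_pop1,pi_pop2 Numeric vectors of per-window diversity.
#' @return Numeric vector of ratios.
#' @export
pi_ratio <- function(pi_pop1, pi_pop2) {
  ifelse(pi_pop1 > 0, pi_pop2 / pi_pop1,
         ifelse(pi_pop2 > 0, Inf, NA_real_))
}

#' Per-window nucleotide diversity for one population
#'
#' Window diversity is the sum of per-site diversities ([site_pi()]) over the
#' window's SNVs divided by the window span in bp. Sites with fewer than two
#' called alleles in the population contribute zero and are excluded from the
#' population's SNV count.
#'
#' @param g A [genotype_matrix()].
#' @param population Population label.
#' @inheritParams window_stats
#' @return A tibble `chrom`, `start`, `end`, `partial`, `n_snvs`, `pi`,
#'   `valid`.
#' @export
window_pi <- function(g, population, window_size = 100000, step_size = 10000,
                      min_snvs = 10, chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            population %in% g$samples$population)
  cl <- default_chrom_lengths(g, chrom_lengths)
  grid <- make_windows(cl, window_size, step_size)
  ac <- allele_counts(g, population)
  piv <- site_pi_vec(ac)
  pairs <- window_site_pairs(grid, g$sites$chrom, g$sites$pos)
  nw <- nrow(grid)
  n_snvs <- count_by_window(pairs, nw, keep = ac$c >= 2)
  grid$n_snvs <- n_snvs
  grid$pi <- sum_by_window(piv, pairs, nw) / (grid$end - grid$start)
  grid$valid <- n_snvs >= min_snvs & !grid$partial
  grid
}

#' Per-window Watterson's theta for one population
#'
#' `theta_W = S / (a_n * span)` with `S` the number of sites segregating in
#' the population within the window and `a_n` the harmonic number
#' `sum_{i=1}^{n-1} 1/i`, where `n` is the (floored) median called allele
#' count over the window's sites — a robust choice under scattered
#' missingness.
#'
#' @inheritParams window_pi
#' @return A tibble `chrom`, `start`, `end`, `partial`, `s`, `theta`, `valid`.
#' @export
watterson_theta <- function(g, population, window_size = 100000,
                            step_size = 10000, min_snvs = 10,
                            chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            population %in% g$samples$population)
  cl <- default_chrom_lengths(g, chrom_lengths)
  grid <- make_windows(cl, window_size, step_size)
  ac <- allele_counts(g, population)
  seg <- ac$c >= 2 & ac$a > 0 & ac$a < ac$c
  pairs <- window_site_pairs(grid, g$sites$chrom, g$sites$pos)
  nw <- nrow(grid)
  s_count <- count_by_window(pairs, nw, keep = seg)
  n_snvs <- count_by_window(pairs, nw, keep = ac$c >= 2)
  # per-window median called allele count (floored) over usable sites
  n_med <- rep(NA_real_, nw)
  use <- ac$c[pairs$site] >= 2
  if (any(use)) {
    med <- tapply(ac$c[pairs$site][use], pairs$win[use], median)
    n_med[as.integer(names(med))] <- floor(med)
  }
  a_n <- vapply(n_med, function(n) {
    if (is.na(n) || n < 2) return(NA_real_)
    sum(1 / seq_len(n - 1))
  }, numeric(1))
  grid$s <- s_count
  grid$theta <- ifelse(s_count == 0, 0,
                       s_count / (a_n * (grid$end - grid$start)))
  grid$valid <- n_snvs >= min_snvs & !grid$partial
  grid
}

#' Per-window F_ST
#'
#' Convenience wrapper around [window_stats()] returning only the window
#' F_ST columns. Negative Weir-Cockerham values are retained (not clamped):
#' clamping would distort the empirical quantile used by the scan.
#'
#' @inheritParams window_stats
#' @return A tibble `chrom`, `start`, `end`, `partial`, `n_snvs`, `fst`,
#'   `valid`.
#' @export
window_fst <- function(g, window_size = 100000, step_size = 10000,
                       min_snvs = 10, estimator = c("wc", "hudson"),
                       chrom_lengths = NULL) {
  ws <- window_stats(g, window_size, step_size, min_snvs, estimator,
                     chrom_lengths)
  as_tibble(ws)[, c("chrom", "start", "end", "partial", "n_snvs", "fst",
                    "valid")]
}

#' Genome-wide F_ST point estimate
#'
#' Ratio-of-averages over all usable sites: `sum(a) / sum(a + b + c)` for
#' Weir-Cockerham, `1 - sum(hw) / sum(hb)` for Hudson.
#'
#' @inheritParams window_stats
#' @return A single number.
#' @export
genome_fst <- function(g, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ps <- per_site_stats(g)
  if (estimator == "wc") {
    sum(ps$a, na.rm = TRUE) / sum(ps$a + ps$b + ps$c, na.rm = TRUE)
  } else {
    1 - sum(ps$hw, na.rm = TRUE) / sum(ps$hb, na.rm = TRUE)
  }
}
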