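#' Simulate a two-population diploid cohort with planted sweeps
#'
#' Draws ancestral allele frequencies from a neutral folded site-frequency
#' spectrum, diverges the two populations under the Balding-Nichols model
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose expected F_ST equals `F`), and
#' samples diploid genotypes binomially. Inside the configured sweep
#' intervals, population 1 diverges at `sweep_f` instead of `background_f`
#' and its frequency is pushed deterministically toward the nearer of {0, 1}
#' so that its expected heterozygosity is scaled by
#' `sweep_diversity_scale` — the low-diversity, high-differentiation signature
#' a selective sweep leaves in the domesticated population.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (a `sim_truth` object holding the planted sweep intervals, the
#'   per-site ancestral and per-population frequencies, and the seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config <- validate_sim_config(config)
  set.seed(config$seed)

  alloc <- allocate_sites(config$chrom_lengths, config$n_sites)
  chrom <- rep(names(alloc), times = alloc)
  pos <- unlist(lapply(names(alloc), function(ch) {
    sort(sample.int(config$chrom_lengths[[ch]], alloc[[ch]], replace = FALSE))
  }), use.names = FALSE)
  m <- length(pos)

  # ancestral frequency from the neutral folded spectrum P(i) ~ 1/i over
  # allele counts of the pooled sample, truncated to [0.02, 0.98]
  n_alleles <- 2L * (config$n_pop1 + config$n_pop2)
  i <- sample.int(n_alleles - 1L, m, replace = TRUE,
                  prob = 1 / seq_len(n_alleles - 1L))
  p_anc <- pmin(pmax(i / n_alleles, 0.02), 0.98)

  in_sweep <- sites_in_intervals(chrom, pos, config$sweep_intervals)

  f1 <- ifelse(in_sweep, config$sweep_f, config$background_f)
  p1 <- rbeta(m, p_anc * (1 - f1) / f1, (1 - p_anc) * (1 - f1) / f1)
  p2 <- rbeta(m, p_anc * (1 - config$background_f) / config$background_f,
              (1 - p_anc) * (1 - config$background_f) / config$background_f)
  p1[in_sweep] <- shrink_heterozygosity(p1[in_sweep],
                                        config$sweep_diversity_scale)

  d1 <- matrix(rbinom(config$n_pop1 * m, 2L, rep(p1, each = config$n_pop1)),
               nrow = config$n_pop1)
  d2 <- matrix(rbinom(config$n_pop2 * m, 2L, rep(p2, each = config$n_pop2)),
               nrow = config$n_pop2)
  dosages <- rbind(d1, d2)

  if (config$missing_rate > 0) {
    dosages[runif(length(dosages)) < config$missing_rate] <- NA_integer_
  }

  alleles <- draw_ref_alt(m, config$tstv_target)
  qual <- round(rgamma(m, shape = 2, scale = 60), 2)

  samples <- tibble(
    sample = c(sprintf("%s_%02d", config$pop_labels[1], seq_len(config$n_pop1)),
               sprintf("%s_%02d", config$pop_labels[2], seq_len(config$n_pop2))),
    population = rep(config$pop_labels, c(config$n_pop1, config$n_pop2))
  )
  sites <- tibble(chrom = chrom, pos = pos, ref = alleles$ref,
                  alt = alleles$alt, qual = qual)

  g <- genotype_matrix(dosages, sites, samples,
                       chrom_lengths = config$chrom_lengths)
  truth <- structure(
    list(sweep_intervals = config$sweep_intervals,
         ancestral_freq = p_anc, freq_pop1 = p1, freq_pop2 = p2,
         sites = sites[, c("chrom", "pos")], seed = config$seed,
         config = config),
    class = "sim_truth"
  )
  list(genotypes = g, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d planted sweeps, %d sites, seed %d\n",
              nrow(x$sweep_intervals), nrow(x$sites), x$seed))
  invisible(x)
}

# Move a frequency toward the nearer of {0, 1} so that 2q(1-q) is scaled by s.
# Solving 2q'(1-q') = s * 2q(1-q) on the near side gives the closed form below;
# the discriminant 1 - 4s q(1-q) >= 1 - s >= 0 for s in (0, 1].
shrink_heterozygosity <- function(q, s) {
  if (length(q) == 0) return(q)
  disc <- pmax(1 - 4 * s * q * (1 - q), 0)
  lo <- (1 - sqrt(disc)) / 2
  ifelse(q <= 0.5, lo, 1 - lo)
}

# Transition partners: A<->G, C<->T. A pair is a transition with probability
# tstv / (tstv + 1); otherwise one of the two transversions, equally.
draw_ref_alt <- function(m, tstv_target) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  transversions <- list(A = c("C", "T"), C = c("A", "G"),
                        G = c("C", "T"), T = c("A", "G"))
  ref <- sample(bases, m, replace = TRUE)
  is_ts <- runif(m) < tstv_target / (tstv_target + 1)
  pick <- runif(m) < 0.5
  alt <- ifelse(is_ts, transition[ref],
                ifelse(pick,
                       vapply(transversions[ref], `[`, character(1), 1L),
                       vapply(transversions[ref], `[`, character(1), 2L)))
  list(ref = unname(ref), alt = unname(alt))
}

# Logical vector: is site (chrom[i], pos[i]) inside any 0-based half-open
# interval? A 1-based position pos lies in [start, end) iff start < pos <= end.
sites_in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  if (is.null(intervals) || nrow(intervals) == 0) return(out)
  for (k in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[k] &
                    pos > intervals$start[k] & pos <= intervals$end[k])
  }
  out
}

#' Set genotypes to missing at random
#'
#' Each genotype is independently set to missing with probability `rate`;
#' deterministic under `seed`. Used to exercise call-rate and missingness
#' filters.
#'
#' @param g A [genotype_matrix()].
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return A new `genotype_matrix`.
#' @export
inject_missingness <- function(g, rate, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (rate < 0 || rate >= 1) abort("`rate` must lie in [0, 1).")
  if (rate == 0) return(g)
  d <- g$dosages
  set.seed(as.integer(seed))
  d[runif(length(d)) < rate] <- NA_integer_
  genotype_matrix(d, g$sites, g$samples, chrom_lengths = g$chrom_lengths)
}
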