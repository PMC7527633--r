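#' Site filters for the selection scan
#'
#' Removes sites failing any of the scan filters: call rate below
#' `min_call_rate`, pooled minor-allele frequency below `min_maf`, or missing
#' fraction above `max_missing` (the last two criteria are partially
#' redundant with the first and are applied jointly so either can be
#' tightened independently). Boundary values are retained: the filters
#' exclude strictly `< min_call_rate`, `< min_maf` and `> max_missing`.
#'
#' @param g A [genotype_matrix()].
#' @param min_call_rate Minimum fraction of called genotypes (default 0.90).
#' @param min_maf Minimum pooled minor-allele frequency (default 0.05).
#' @param max_missing Maximum missing fraction (default 0.20).
#' @return The filtered `genotype_matrix`, with attribute `"removed"` — a
#'   tibble of per-criterion removal counts (a site can fail several).
#' @export
filter_sites_scan <- function(g, min_call_rate = 0.90, min_maf = 0.05,
                              max_missing = 0.20) {
  ss <- site_stats(g)
  fail_call <- ss$call_rate < min_call_rate
  fail_maf <- is.na(ss$maf) | ss$maf < min_maf
  fail_miss <- ss$missing > max_missing
  keep <- !(fail_call | fail_maf | fail_miss)
  if (!any(keep)) warn("all sites removed by the scan filters.")
  out <- subset_sites(g, keep)
  attr(out, "removed") <- tibble(
    criterion = c("call_rate", "maf", "missing", "any"),
    n_removed = c(sum(fail_call), sum(fail_maf), sum(fail_miss), sum(!keep))
  )
  out
}

#' Site filters for population-structure analyses
#'
#' Removes sites with pooled MAF below `min_maf`, missing fraction of
#' `max_missing` or more (the structure filter excludes "missing rate
#' >= 0.05", i.e. retains strictly below), or site quality below `min_qual`.
#' LD pruning is a separate step ([ld_prune()]) applied afterwards. When the
#' matrix carries no quality scores the quality criterion is skipped with a
#' warning.
#'
#' @param g A [genotype_matrix()].
#' @param min_maf Minimum pooled minor-allele frequency (default 0.05).
#' @param max_missing Missingness bound; sites with `missing >= max_missing`
#'   are removed (default 0.05).
#' @param min_qual Minimum phred-scaled site quality (default 30).
#' @return The filtered `genotype_matrix` with a `"removed"` attribute as in
#'   [filter_sites_scan()].
#' @export
filter_sites_structure <- function(g, min_maf = 0.05, max_missing = 0.05,
                                   min_qual = 30) {
  ss <- site_stats(g)
  fail_maf <- is.na(ss$maf) | ss$maf < min_maf
  fail_miss <- ss$missing >= max_missing
  if (!"qual" %in% names(ss) || all(is.na(ss$qual))) {
    warn("no site quality scores available; skipping the quality filter.")
    fail_qual <- rep(FALSE, nrow(ss))
  } else {
    fail_qual <- !is.na(ss$qual) & ss$qual < min_qual
  }
  keep <- !(fail_maf | fail_miss | fail_qual)
  if (!any(keep)) warn("all sites removed by the structure filters.")
  out <- subset_sites(g, keep)
  attr(out, "removed") <- tibble(
    criterion = c("maf", "missing", "qual", "any"),
    n_removed = c(sum(fail_maf), sum(fail_miss), sum(fail_qual), sum(!keep))
  )
  out
}

#' Greedy window-based LD pruning
#'
#' plink-style `--indep-pairwise` pruning on genotype dosages: windows of
#' `window_snps` consecutive sites (never spanning chromosomes) advance by
#' `step_snps`; within each window, while any retained pair has squared
#' dosage correlation above `r2_max`, the member of the worst pair with the
#' lower MAF is removed (ties remove the later position). The surviving set
#' has no retained within-window pair exceeding `r2_max`.
#'
#' @param g A [genotype_matrix()].
#' @param window_snps Window size in SNVs (default 100).
#' @param step_snps Step in SNVs (default 10).
#' @param r2_max Maximum tolerated r-squared (plink's structure setting is
#'   0.01; 0.2 is the common tree/PCA setting).
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, window_snps = 100, step_snps = 10, r2_max = 0.2) {
  if (window_snps < 2) abort("`window_snps` must be >= 2.")
  if (step_snps < 1) abort("`step_snps` must be >= 1.")
  maf <- site_stats(g)$maf
  keep <- rep(TRUE, ncol(g$dosages))
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    m <- length(idx)
    starts <- unique(c(seq(1, max(1, m - 1), by = step_snps)))
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, m)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        cor(g$dosages[, win, drop = FALSE],
            use = "pairwise.complete.obs")^2
      )
      diag(r2) <- NA
      r2[is.na(r2)] <- -Inf
      diag(r2) <- -Inf
      while (max(r2) > r2_max) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        i <- win[worst[1]]; j <- win[worst[2]]
        drop_site <- if (isTRUE(maf[i] < maf[j])) i
          else if (isTRUE(maf[j] < maf[i])) j
          else max(i, j)  # tie: later position goes
        k <- match(drop_site, win)
        keep[drop_site] <- FALSE
        r2[k, ] <- -Inf
        r2[, k] <- -Inf
      }
      if (s + window_snps - 1 >= m) break
    }
  }
  subset_sites(g, keep)
}

#' Transition/transversion ratio of REF/ALT pairs
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' A<->G and C<->T; everything else is a transversion. Mammalian genome-wide
#' values run around 2-2.3.
#'
#' @param g A [genotype_matrix()].
#' @return The ratio (#transitions / #transversions); `Inf` with a warning
#'   when no transversion is present.
#' @export
tstv_ratio <- function(g) {
  ref <- g$sites$ref; alt <- g$sites$alt
  ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_tv <- sum(!ts)
  if (n_tv == 0) {
    warn("no transversions: Ts/Tv ratio undefined, returning Inf.")
    return(Inf)
  }
  sum(ts) / n_tv
}
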