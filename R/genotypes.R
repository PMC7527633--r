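#' Construct a genotype matrix object
#'
#' The central container of the package: a samples x sites matrix of ALT-allele
#' dosages (0, 1, 2 or `NA` for missing) together with per-site metadata and a
#' two-population sample sheet. All window statistics, filters and structure
#' analyses consume this object.
#'
#' @param dosages Integer matrix, samples in rows, sites in columns; entries in
#'   `{0, 1, 2, NA}`. Row names, when present, must match `samples$sample`.
#' @param sites Data frame with one row per site: columns `chrom`, `pos`
#'   (1-based bp), `ref`, `alt` (single nucleotides) and optionally `qual`
#'   (phred-scaled site quality).
#' @param samples Data frame with columns `sample` and `population`. Exactly
#'   two population labels are expected for two-population statistics; the
#'   first label in order of appearance is treated as population 1 (the
#'   "domestic" / focal population in sweep scans).
#' @param chrom_lengths Optional named numeric vector of chromosome lengths in
#'   bp; used to build sliding-window grids. When absent, grids fall back to
#'   the largest observed position per chromosome.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sites, samples, chrom_lengths = NULL) {
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  stopifnot(is.matrix(dosages))
  if (nrow(dosages) != nrow(samples)) {
    abort("`dosages` must have one row per sample.")
  }
  if (ncol(dosages) != nrow(sites)) {
    abort("`dosages` must have one column per site.")
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, ref, alt.")
  }
  if (!all(c("sample", "population") %in% names(samples))) {
    abort("`samples` needs columns sample and population.")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA.")
  if (any(sites$ref == sites$alt)) abort("REF and ALT must differ at every site.")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    sites <- sites[ord, ]
    dosages <- dosages[, ord, drop = FALSE]
  }
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- samples$sample
  structure(
    list(dosages = dosages, sites = sites, samples = samples,
         chrom_lengths = chrom_lengths),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf(
    "<genotype_matrix> %d samples x %d sites (%s)\n",
    nrow(x$dosages), ncol(x$dosages),
    paste(sprintf("%s: %d", names(pops), pops), collapse = ", ")
  ))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Population labels of a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return Character vector of the (at most two) population labels, population
#'   1 first.
#' @export
populations <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  unique(g$samples$population)
}

pop_rows <- function(g, population) {
  which(g$samples$population == population)
}

#' Subset a genotype matrix to a set of sites
#'
#' @param g A [genotype_matrix()].
#' @param keep Logical or integer index over sites.
#' @return A new `genotype_matrix`.
#' @export
subset_sites <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$sites[keep, ],
                  g$samples, chrom_lengths = g$chrom_lengths)
}

#' Per-site summary statistics
#'
#' Computes, for every site, the call rate (fraction of samples with a called
#' genotype), the pooled minor-allele frequency over all called alleles, and
#' the missing fraction.
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual` (if
#'   present), `call_rate`, `maf`, `missing`.
#' @export
site_stats <- function(g) {
  d <- g$dosages
  called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA_real_)
  out <- g$sites
  out$call_rate <- called / nrow(d)
  out$maf <- pmin(af, 1 - af)
  out$missing <- 1 - out$call_rate
  out
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, site) pair: `sample`,
#'   `population`, `chrom`, `pos`, `dosage`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  m <- nrow(x$dosages); s <- ncol(x$dosages)
  tibble(
    sample = rep(x$samples$sample, times = s),
    population = rep(x$samples$population, times = s),
    chrom = rep(x$sites$chrom, each = m),
    pos = rep(x$sites$pos, each = m),
    dosage = as.integer(x$dosages)
  )
}

# Per-population per-site allele bookkeeping used by pi, theta and F_ST.
# Returns, for one population: called allele count c, ALT allele count a,
# observed heterozygote count h, called diploid count n.
allele_counts <- function(g, population) {
  d <- g$dosages[pop_rows(g, population), , drop = FALSE]
  n <- colSums(!is.na(d))
  list(
    c = 2L * n,
    a = colSums(d, na.rm = TRUE),
    h = colSums(d == 1L, na.rm = TRUE),
    n = n
  )
}
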