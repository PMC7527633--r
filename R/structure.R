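#' Identity-by-state distance matrix
#'
#' `d(i, j)` is the mean over co-called sites of `|dosage_i - dosage_j| / 2`:
#' 0 for identical genotypes throughout, 1 for opposite homozygotes
#' everywhere. Allele-sharing on dosages, the same genotype-level input the
#' classic IBS tree pipelines use.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @return A symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
ibs_distance <- function(g) {
  d <- g$dosages
  n <- nrow(d)
  if (n < 2) abort("need at least two samples.")
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1)) {
    xi <- d[i, ]
    for (j in (i + 1):n) {
      diff <- abs(xi - d[j, ])
      ok <- !is.na(diff)
      if (!any(ok)) {
        abort(sprintf("samples %s and %s share no co-called site.",
                      rownames(d)[i], rownames(d)[j]))
      }
      out[i, j] <- out[j, i] <- mean(diff[ok]) / 2
    }
  }
  out
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -12),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimising the
#' Q-criterion `(m - 2) d(i,j) - r_i - r_j`, compute the two branch lengths
#' from the standard formulas, reduce the matrix, and stop when three nodes
#' remain (unrooted tree). Ties in Q are broken by lexicographic label order
#' (internal clusters carry their smallest member label). Negative branch
#' length estimates are clamped to zero with the deficit transferred to the
#' sibling edge, preserving the joined pair's distance.
#'
#' @param d Symmetric non-negative distance matrix with labels (matrix or
#'   `dist`).
#' @return An unrooted [ape::phylo] tree whose tips are the matrix labels.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbour joining needs at least three taxa.")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric.")
  if (any(d < 0)) abort("distances must be non-negative.")

  labels <- rownames(d)        # tie-break label per active cluster
  newick <- rownames(d)        # growing newick fragment per cluster
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1, function(ij) {
      lab <- sort(labels[ij])
      paste(lab[1], lab[2], sep = "\r")
    })
    pick <- cand[order(pair_lab)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    frag <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], li, newick[j], lj)
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], u = dnew),
               u = c(dnew, 0))
    lab_new <- min(labels[c(i, j)])
    labels <- c(labels[keep], lab_new)
    newick <- c(newick[keep], frag)
  }
  # final three-way join: l_i = (d_ij + d_ik - d_jk) / 2
  l1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 newick[1], l1, newick[2], l2, newick[3], l3)
  ape::read.tree(text = txt)
}

#' Is each population's sample set a single clade side of the tree?
#'
#' Checks whether the unrooted tree contains a bipartition separating all
#' population-1 tips from all population-2 tips.
#'
#' @param tree An [ape::phylo] tree.
#' @param samples A tibble `sample`, `population` covering all tips.
#' @return `TRUE` when the two populations are mutually monophyletic.
#' @export
populations_separated <- function(tree, samples) {
  pops <- unique(samples$population)
  stopifnot(length(pops) == 2)
  tips1 <- samples$sample[samples$population == pops[1]]
  ape::is.monophyletic(tree, tips = intersect(tree$tip.label, tips1))
}

#' Genotype principal component analysis
#'
#' Standardised-genotype PCA: each site is centred by `2 * p_hat` and scaled
#' by `sqrt(2 * p_hat * (1 - p_hat))` (the usual GRM normalisation), missing
#' entries are mean-imputed (zero after centring), and the sample covariance
#' matrix is eigendecomposed. `variance_explained[k]` is `lambda_k` over the
#' sum of all non-negative eigenvalues. Sign convention: the first nonzero
#' loading of every component is positive, making coordinates reproducible.
#'
#' @param g A [genotype_matrix()] (sites should be polymorphic post-filter;
#'   monomorphic sites are dropped).
#' @param n_components Number of components to return.
#' @return An object of class `genotype_pca`: `scores` (tibble with `sample`,
#'   `population`, `PC1..PCk`), `variance_explained`, `eigenvalues`,
#'   `n_sites`.
#' @export
genotype_pca <- function(g, n_components = 10) {
  d <- g$dosages
  if (nrow(d) < 2) abort("PCA needs at least two samples.")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  cov_s <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov_s, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  k <- min(n_components, length(lambda))
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (c_ in seq_len(k)) {
    nz <- which(abs(vecs[, c_]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, c_] < 0) vecs[, c_] <- -vecs[, c_]
  }
  scores <- as_tibble(setNames(as.data.frame(vecs %*%
                                               diag(sqrt(lambda[seq_len(k)]),
                                                    k)),
                               paste0("PC", seq_len(k))))
  structure(
    list(scores = bind_cols(g$samples, scores),
         variance_explained = lambda / sum(lambda),
         eigenvalues = lambda, n_sites = ncol(x)),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<genotype_pca> %d samples, %d sites; PC1 %.2f%%, PC2 %.2f%% of variance\n",
              nrow(x$scores), x$n_sites, 100 * ve[1],
              if (length(ve) > 1) 100 * ve[2] else NA))
  invisible(x)
}

#' Tidy PCA scores
#'
#' @param x A [genotype_pca()] object.
#' @param ... Unused.
#' @return The score tibble (`sample`, `population`, `PC1..PCk`).
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A [genotype_pca()] object.
#' @param ... Unused.
#' @return A one-row tibble with sample/site counts and the variance
#'   fractions of the first two components.
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_sites = x$n_sites,
         pc1_variance = x$variance_explained[1],
         pc2_variance = if (length(x$variance_explained) > 1) {
           x$variance_explained[2]
         } else NA_real_)
}

#' Linkage-disequilibrium decay curve
#'
#' For every intra-chromosomal site pair separated by at most `max_dist` bp,
#' the squared Pearson correlation of dosages over co-called samples is
#' averaged within distance bins.
#'
#' @param g A [genotype_matrix()].
#' @param population Optional population label; default uses all samples.
#' @param max_dist Maximum pair separation in bp.
#' @param bin_width Bin width in bp.
#' @return A tibble of class `ld_decay`: `bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs` (empty bins have `n_pairs = 0` and `NA` mean).
#' @export
ld_decay <- function(g, population = NULL, max_dist = 300000,
                     bin_width = 500) {
  d <- g$dosages
  if (!is.null(population)) {
    d <- d[pop_rows(g, population), , drop = FALSE]
  }
  nbins <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(nbins)
  n_pairs <- integer(nbins)
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[idx]
    m <- length(idx)
    if (m < 2) next
    hi <- findInterval(pos + max_dist, pos)
    for (a in seq_len(m - 1)) {
      if (hi[a] <= a) next
      J <- (a + 1):hi[a]
      r <- suppressWarnings(
        cor(d[, idx[a]], d[, idx[J], drop = FALSE],
            use = "pairwise.complete.obs")
      )[1, ]
      r2 <- r^2
      bins <- pmin(((pos[J] - pos[a] - 1) %/% bin_width) + 1, nbins)
      ok <- !is.na(r2)
      if (!any(ok)) next
      s <- rowsum(r2[ok], bins[ok])
      b <- as.integer(rownames(s))
      sum_r2[b] <- sum_r2[b] + s[, 1]
      cnt <- table(bins[ok])
      n_pairs[as.integer(names(cnt))] <- n_pairs[as.integer(names(cnt))] +
        as.integer(cnt)
    }
  }
  out <- tibble(
    bin_start = (seq_len(nbins) - 1) * bin_width,
    bin_end = pmin(seq_len(nbins) * bin_width, max_dist),
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1), NA_real_),
    n_pairs = n_pairs
  )
  class(out) <- c("ld_decay", class(out))
  out
}
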