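annotation_levels <- c("coding_nonsynonymous", "coding_synonymous",
                       "splicing", "utr5", "utr3", "intron",
                       "upstream", "downstream", "intergenic")

#' Functionally annotate SNVs against gene models
#'
#' Assigns exactly one category per variant with precedence
#' coding/splicing > UTR > intron > upstream/downstream > intergenic
#' (severity order: non-synonymous, synonymous, splicing, 5' UTR, 3' UTR,
#' intron, upstream, downstream, intergenic). A variant inside a CDS is
#' translated with the standard codon table on the coding strand
#' (reverse-complement for - strand genes): an unchanged amino acid is
#' synonymous, anything else non-synonymous. Splicing means an intronic
#' position within `splice_bp` of an exon boundary. Upstream/downstream are
#' strand-aware flanks of `upstream_bp` / `downstream_bp`. When a variant
#' overlaps several genes the most severe category wins and the ambiguity is
#' counted (reported via attribute `"n_ambiguous"` and a message).
#'
#' @param g A [genotype_matrix()].
#' @param genes A gene-model tibble ([read_gene_models()] or
#'   [synthetic_gene_models()]).
#' @param reference Reference sequences: a [Biostrings::DNAStringSet] or a
#'   FASTA path. Required when any gene carries a CDS.
#' @param upstream_bp,downstream_bp Flank sizes in bp.
#' @param splice_bp Intronic bases adjacent to an exon boundary called
#'   splicing.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `category` (factor over all
#'   nine categories), `gene_id` (`NA` for intergenic).
#' @export
annotate_variants <- function(g, genes, reference = NULL,
                              upstream_bp = 1000, downstream_bp = 1000,
                              splice_bp = 2) {
  sites <- g$sites
  m <- nrow(sites)
  has_cds <- any(vapply(genes$cds, nrow, integer(1)) > 0)
  if (has_cds) {
    if (is.null(reference)) abort("`reference` is required for coding annotation.")
    if (is.character(reference)) reference <- read_reference(reference)
  }
  severity <- rep(9L, m)  # intergenic
  gene_hit <- rep(NA_character_, m)
  n_hits <- integer(m)

  for (k in seq_len(nrow(genes))) {
    gn <- genes[k, ]
    left <- if (gn$strand == "+") upstream_bp else downstream_bp
    right <- if (gn$strand == "+") downstream_bp else upstream_bp
    idx <- which(sites$chrom == gn$chrom &
                   sites$pos > gn$start - left &
                   sites$pos <= gn$end + right)
    if (length(idx) == 0) next
    sev <- classify_against_gene(sites$pos[idx] - 1L, sites$ref[idx],
                                 sites$alt[idx], gn, reference, splice_bp)
    if (is.null(sev)) next  # gene skipped (CDS not a codon multiple)
    n_hits[idx] <- n_hits[idx] + 1L
    better <- sev < severity[idx]
    severity[idx[better]] <- sev[better]
    gene_hit[idx[better]] <- gn$gene_id
  }
  n_ambiguous <- sum(n_hits > 1)
  if (n_ambiguous > 0) {
    inform(sprintf("%d variant(s) overlap more than one gene; most severe category kept.",
                   n_ambiguous))
  }
  out <- tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    category = factor(annotation_levels[severity],
                      levels = annotation_levels),
    gene_id = gene_hit
  )
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

# Severity codes for one gene, for 0-based positions pos0 within the gene's
# extended span. Returns NULL when the gene is skipped.
classify_against_gene <- function(pos0, ref, alt, gn, reference, splice_bp) {
  exons <- gn$exons[[1]]; cds <- gn$cds[[1]]
  u5 <- gn$utr5[[1]]; u3 <- gn$utr3[[1]]
  sev <- integer(length(pos0))

  coding <- NULL
  if (nrow(cds) > 0) {
    total_cds <- sum(cds$end - cds$start)
    if (total_cds %% 3 != 0) {
      warn(sprintf("gene %s: CDS length %d not a codon multiple; gene skipped.",
                   gn$gene_id, total_cds))
      return(NULL)
    }
    coding <- build_coding_context(gn, reference)
  }

  in_any <- function(p, iv) {
    if (nrow(iv) == 0) return(rep(FALSE, length(p)))
    Reduce(`|`, lapply(seq_len(nrow(iv)),
                       function(i) p >= iv$start[i] & p < iv$end[i]))
  }

  inside <- pos0 >= gn$start & pos0 < gn$end
  in_cds <- if (nrow(cds) > 0) in_any(pos0, cds) else rep(FALSE, length(pos0))
  in_u5 <- in_any(pos0, u5)
  in_u3 <- in_any(pos0, u3)
  in_exon <- in_any(pos0, exons)
  intronic <- inside & !in_exon

  # flanks, strand-aware
  before <- pos0 < gn$start
  after <- pos0 >= gn$end
  if (gn$strand == "+") {
    sev[before] <- 7L; sev[after] <- 8L
  } else {
    sev[before] <- 8L; sev[after] <- 7L
  }
  sev[intronic] <- ifelse(splice_distance(pos0[intronic], exons) <= splice_bp,
                          3L, 6L)
  sev[in_u5] <- 4L
  sev[in_u3] <- 5L
  # exonic but neither CDS nor annotated UTR (non-coding exon): treat as intron
  stray <- inside & in_exon & !in_cds & !in_u5 & !in_u3
  sev[stray] <- 6L

  if (any(in_cds)) {
    syn <- coding_effect(pos0[in_cds], ref[in_cds], alt[in_cds], gn, coding)
    sev[in_cds] <- ifelse(syn, 2L, 1L)
  }
  sev
}

# 1-based distance of an intronic base to the nearest exon boundary: 1 for
# the base immediately flanking an exon.
splice_distance <- function(pos0, exons) {
  if (length(pos0) == 0) return(numeric(0))
  d <- rep(Inf, length(pos0))
  for (i in seq_len(nrow(exons))) {
    d <- pmin(d,
              ifelse(pos0 >= exons$end[i], pos0 - exons$end[i] + 1, Inf),
              ifelse(pos0 < exons$start[i], exons$start[i] - pos0, Inf))
  }
  d
}

# Spliced coding-strand CDS sequence and the genomic->coding index map.
build_coding_context <- function(gn, reference) {
  cds <- gn$cds[[1]]
  ref_chrom <- reference[[gn$chrom]]
  segs <- vapply(seq_len(nrow(cds)), function(i) {
    as.character(Biostrings::subseq(ref_chrom, start = cds$start[i] + 1L,
                                    end = cds$end[i]))
  }, character(1))
  genomic_seq <- paste(segs, collapse = "")
  total <- nchar(genomic_seq)
  coding_seq <- if (gn$strand == "+") genomic_seq else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomic_seq)))
  }
  cum_before <- cumsum(c(0, cds$end - cds$start))[seq_len(nrow(cds))]
  list(coding_seq = coding_seq, total = total, cds = cds,
       cum_before = cum_before)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# TRUE = synonymous, FALSE = non-synonymous, for CDS variants.
coding_effect <- function(pos0, ref, alt, gn, coding) {
  cds <- coding$cds
  seg <- vapply(pos0, function(p) {
    which(p >= cds$start & p < cds$end)[1]
  }, integer(1))
  gidx <- coding$cum_before[seg] + (pos0 - cds$start[seg])  # 0-based, genomic order
  cidx <- if (gn$strand == "+") gidx else coding$total - 1L - gidx
  ref_c <- if (gn$strand == "+") ref else COMPLEMENT[ref]
  alt_c <- if (gn$strand == "+") alt else COMPLEMENT[alt]
  have <- substring(coding$coding_seq, cidx + 1L, cidx + 1L)
  if (any(have != ref_c)) {
    bad <- which(have != ref_c)[1]
    abort(sprintf("REF disagrees with the reference at %s:%d (VCF %s, reference %s).",
                  gn$chrom, pos0[bad] + 1L, ref_c[bad], have[bad]))
  }
  codon_start <- (cidx %/% 3L) * 3L + 1L
  codon_ref <- substring(coding$coding_seq, codon_start, codon_start + 2L)
  offset <- cidx %% 3L
  codon_alt <- codon_ref
  substr(codon_alt, offset + 1L, offset + 1L) <- alt_c
  aa_ref <- Biostrings::GENETIC_CODE[codon_ref]
  aa_alt <- Biostrings::GENETIC_CODE[codon_alt]
  unname(aa_ref == aa_alt)
}

#' Category counts of an annotation
#'
#' The classic annotation summary table: one row per category with count and
#' percentage; rows always sum to the total variant count (the categories
#' partition the variants).
#'
#' @param annotation Output of [annotate_variants()].
#' @return A tibble `category`, `n`, `pct`.
#' @export
annotation_summary <- function(annotation) {
  out <- annotation |>
    count(.data$category, .drop = FALSE, name = "n")
  out$pct <- 100 * out$n / sum(out$n)
  out
}

#' Count SNVs in genomic regions
#'
#' @param g A [genotype_matrix()].
#' @param regions A tibble with `chrom`, `start`, `end` (half-open, sorted).
#'   A site is counted when `start <= pos < end`: the region end is
#'   exclusive against the site position.
#' @return `regions` with an `n_snvs` column.
#' @export
variants_in_regions <- function(g, regions) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    regions$n_snvs <- integer(0)
    return(regions)
  }
  regions$n_snvs <- vapply(seq_len(nrow(regions)), function(k) {
    r <- regions[k, ]
    sum(g$sites$chrom == r$chrom & g$sites$pos >= r$start &
          g$sites$pos < r$end)
  }, integer(1))
  regions
}
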