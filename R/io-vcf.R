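#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 (via vcfR), keeps biallelic SNVs only (multiallelic and
#' non-SNV records are skipped and counted), and encodes genotypes as
#' ALT-allele dosages. Half-calls and missing genotypes become `NA`.
#' Chromosome lengths are taken from `##contig` header lines when present.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample_populations Sample-to-population assignment: a data frame
#'   with columns `sample` and `population`, or a named character vector
#'   `c(sample = population)`. Every sample in the VCF must be covered.
#' @return A [genotype_matrix()] with attribute `"n_skipped"` (count of
#'   skipped records).
#' @export
read_vcf <- function(path, sample_populations) {
  if (is.data.frame(sample_populations)) {
    popmap <- setNames(sample_populations$population,
                       sample_populations$sample)
  } else {
    popmap <- sample_populations
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d multiallelic or non-SNV record(s).", n_skipped))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snv, , drop = FALSE]
  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, names(popmap))
  if (length(unknown) > 0) {
    abort(sprintf("samples missing from the population map: %s",
                  paste(unknown, collapse = ", ")))
  }
  lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosages <- matrix(lut[gt], nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE)
  qual <- suppressWarnings(as.numeric(fix[snv, "QUAL"]))
  sites <- tibble(
    chrom = fix[snv, "CHROM"],
    pos = as.integer(fix[snv, "POS"]),
    ref = ref[snv], alt = alt[snv], qual = qual
  )
  samples <- tibble(sample = vcf_samples,
                    population = unname(popmap[vcf_samples]))
  cl <- contig_lengths_from_meta(v@meta)
  g <- genotype_matrix(dosages, sites, samples, chrom_lengths = cl)
  attr(g, "n_skipped") <- n_skipped
  g
}

contig_lengths_from_meta <- function(meta) {
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) == 0) return(NULL)
  id <- stringr::str_match(contig, "ID=([^,>]+)")[, 2]
  len <- suppressWarnings(as.numeric(stringr::str_match(contig,
                                                        "length=([0-9]+)")[, 2]))
  ok <- !is.na(id) & !is.na(len)
  if (!any(ok)) return(NULL)
  setNames(len[ok], id[ok])
}

#' Write a genotype matrix as a plain-text VCF v4.2
#'
#' Emits a minimal GT-only VCF with `##contig` lines (when chromosome lengths
#' are known) and missing genotypes as `./.`. Output is deterministic byte
#' for byte, and a [read_vcf()] round-trip reproduces the dosages exactly.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosages
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  called <- !is.na(d)
  gt[called] <- gt_codes[d[called] + 1L]
  qual <- if (!is.null(g$sites$qual)) {
    ifelse(is.na(g$sites$qual), ".", sprintf("%.2f", g$sites$qual))
  } else rep(".", ncol(d))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    if (!is.null(g$chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(g$chrom_lengths),
              as.integer(g$chrom_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample), collapse = "\t")
  )
  body <- paste(
    g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt, qual,
    ".", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns `sample` and `population` (header optional:
#'   a headerless two-column file is accepted).
#' @return A tibble `sample`, `population`.
#' @export
read_population_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^sample\\b", first)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("sample", "population")
  as_tibble(df[, c("sample", "population")])
}
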