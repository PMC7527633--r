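#' Write a simulated cohort to disk
#'
#' Emits everything downstream stages consume: a plain-text VCF v4.2, a BED
#' of the true sweep intervals, a GFF3 of synthetic gene models tiled across
#' the genome, a FASTA reference consistent with the REF alleles, a
#' sample-to-population TSV, and a JSON sidecar of the simulation truth.
#' A [read_vcf()] round-trip reproduces the dosage matrix exactly.
#'
#' @param genotypes A [genotype_matrix()].
#' @param truth A `sim_truth` object (or `NULL`: no BED/JSON written).
#' @param outdir Output directory (created if needed).
#' @param write_fasta,write_gff Write the reference FASTA / gene-model GFF3?
#'   Both default to `TRUE`; FASTA generation is the only step whose cost
#'   grows with genome length rather than site count.
#' @param gene_spacing Spacing of synthetic genes in bp (see
#'   [synthetic_gene_models()]).
#' @return A tibble of the files written (`file`, `path`).
#' @export
write_cohort <- function(genotypes, truth = NULL, outdir,
                         write_fasta = TRUE, write_gff = TRUE,
                         gene_spacing = 250000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  add <- function(name, path) files[[length(files) + 1]] <<-
    tibble(file = name, path = path)

  vcf_path <- file.path(outdir, "cohort.vcf")
  write_vcf(genotypes, vcf_path)
  add("vcf", vcf_path)

  pop_path <- file.path(outdir, "populations.tsv")
  readr::write_tsv(genotypes$samples, pop_path)
  add("populations", pop_path)

  if (!is.null(truth)) {
    bed_path <- file.path(outdir, "truth_sweeps.bed")
    write_bed(truth$sweep_intervals, bed_path,
              names = sprintf("sweep%d", seq_len(nrow(truth$sweep_intervals))))
    add("truth_bed", bed_path)

    json_path <- file.path(outdir, "truth.json")
    jsonlite::write_json(
      list(seed = truth$seed,
           sweep_intervals = truth$sweep_intervals,
           sites = truth$sites,
           ancestral_freq = truth$ancestral_freq,
           freq_pop1 = truth$freq_pop1,
           freq_pop2 = truth$freq_pop2),
      json_path, auto_unbox = TRUE, digits = NA)
    add("truth_json", json_path)
  }

  cl <- genotypes$chrom_lengths
  if (write_gff && !is.null(cl)) {
    genes <- synthetic_gene_models(cl, spacing = gene_spacing)
    gff_path <- file.path(outdir, "genes.gff3")
    write_gff3(genes, gff_path)
    add("gff3", gff_path)
  }
  if (write_fasta && !is.null(cl)) {
    fa_path <- file.path(outdir, "reference.fa")
    write_reference_fasta(genotypes, fa_path)
    add("fasta", fa_path)
  }
  bind_rows(files)
}

#' Write intervals as a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @param names Optional feature names (4th column).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  lines <- if (is.null(names)) {
    sprintf("%s\t%d\t%d", intervals$chrom, as.integer(intervals$start),
            as.integer(intervals$end))
  } else {
    sprintf("%s\t%d\t%d\t%s", intervals$chrom, as.integer(intervals$start),
            as.integer(intervals$end), names)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read a BED file of features
#'
#' @param path Path to a BED file (3+ columns; 4th column, when present,
#'   becomes both `name` and `class`).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open) and, when
#'   available, `name` and `class`.
#' @export
read_bed <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields.",
                  which(nfield < 3)[1]))
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end) || any(end <= start)) {
    bad <- which(is.na(start) | is.na(end) | end <= start)[1]
    abort(sprintf("malformed BED line %d: bad coordinates.", bad))
  }
  out <- tibble(chrom = vapply(parts, `[`, character(1), 1),
                start = start, end = end)
  if (all(nfield >= 4)) {
    out$name <- vapply(parts, `[`, character(1), 4)
    out$class <- out$name
  }
  out
}

# Random reference sequence with the REF allele planted at every variant
# position. Deterministic given the genotype matrix is built under a seed,
# but independent of it here: bases are drawn from the current RNG stream.
write_reference_fasta <- function(g, path, seed = 99L) {
  cl <- g$chrom_lengths
  if (is.null(cl)) abort("reference FASTA needs chromosome lengths.")
  set.seed(as.integer(seed))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (ch in names(cl)) {
    len <- as.integer(cl[[ch]])
    seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    idx <- which(g$sites$chrom == ch)
    seq[g$sites$pos[idx]] <- g$sites$ref[idx]
    writeLines(sprintf(">%s", ch), con = con, sep = "\n")
    full <- paste(seq, collapse = "")
    starts <- seq.int(1L, len, by = 70L)  # 70-column wrapping
    chunks <- substring(full, starts, pmin(starts + 69L, len))
    writeLines(chunks, con = con, sep = "\n")
  }
  invisible(path)
}

#' Read a reference FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}
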