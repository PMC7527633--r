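# Gene models are tibbles with one row per gene and a single transcript per
# gene: columns gene_id, chrom, strand, start, end (0-based half-open
# transcript span) plus list-columns exons, cds, utr5, utr3, each a data.frame
# of (start, end) intervals in genomic order. CDS phase is implied by strand
# and interval order.

#' Synthetic gene models tiled across a genome
#'
#' Places a fixed multi-exon gene template (5' UTR, three CDS segments
#' totalling 1101 bp, introns, 3' UTR; 2600 bp span) every `spacing` bp on
#' each chromosome, alternating + and - strands so both orientations of the
#' coding-annotation logic are exercised.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param spacing Distance between successive gene starts (bp).
#' @param first_start Genomic start (0-based) of the first gene per
#'   chromosome.
#' @return A gene-model tibble.
#' @export
synthetic_gene_models <- function(chrom_lengths, spacing = 250000,
                                  first_start = 10000) {
  tpl <- gene_template()
  rows <- list()
  idx <- 0L
  for (ch in names(chrom_lengths)) {
    starts <- seq(first_start, by = spacing,
                  length.out = max(0, floor((chrom_lengths[[ch]] - first_start -
                                               tpl$span) / spacing) + 1))
    for (s in starts) {
      idx <- idx + 1L
      strand <- if (idx %% 2L == 1L) "+" else "-"
      f <- tpl$features(strand)
      rows[[idx]] <- tibble(
        gene_id = sprintf("gene%04d", idx), chrom = ch, strand = strand,
        start = s, end = s + tpl$span,
        exons = list(shift_intervals(f$exons, s)),
        cds = list(shift_intervals(f$cds, s)),
        utr5 = list(shift_intervals(f$utr5, s)),
        utr3 = list(shift_intervals(f$utr3, s))
      )
    }
  }
  bind_rows(rows)
}

shift_intervals <- function(iv, by) {
  data.frame(start = iv$start + by, end = iv$end + by)
}

# The template, as 0-based offsets on the + strand; the - strand version is
# the reflection about the span so the 5' UTR sits at the high-coordinate end.
gene_template <- function() {
  span <- 2600
  plus <- list(
    exons = data.frame(start = c(0, 1000, 2000), end = c(401, 1600, 2600)),
    cds = data.frame(start = c(200, 1000, 2000), end = c(401, 1600, 2300)),
    utr5 = data.frame(start = 0, end = 200),
    utr3 = data.frame(start = 2300, end = 2600)
  )
  reflect <- function(iv) {
    out <- data.frame(start = span - iv$end, end = span - iv$start)
    out[order(out$start), , drop = FALSE]
  }
  minus <- lapply(plus, reflect)
  list(span = span, features = function(strand) {
    if (strand == "+") plus else minus
  })
}

gff3_escape <- function(x) x  # ids here are plain [A-Za-z0-9_]

#' Write gene models as GFF3
#'
#' One gene / mRNA / exon / five_prime_UTR / CDS / three_prime_UTR hierarchy
#' per gene, 1-based inclusive coordinates, CDS phase computed in translation
#' order.
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, phase, attrs) {
    sprintf("%s\tsweepscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, start + 1L, end, strand, phase, attrs)
  }
  for (k in seq_len(nrow(genes))) {
    gn <- genes[k, ]
    gid <- gn$gene_id; tid <- paste0(gid, ".t1")
    lines <- c(lines,
      fmt(gn$chrom, "gene", gn$start, gn$end, gn$strand, ".",
          sprintf("ID=%s;Name=%s", gid, gid)),
      fmt(gn$chrom, "mRNA", gn$start, gn$end, gn$strand, ".",
          sprintf("ID=%s;Parent=%s", tid, gid)))
    ex <- gn$exons[[1]]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, fmt(gn$chrom, "exon", ex$start[i], ex$end[i],
                            gn$strand, ".", sprintf("Parent=%s", tid)))
    }
    u5 <- gn$utr5[[1]]
    for (i in seq_len(nrow(u5))) {
      lines <- c(lines, fmt(gn$chrom, "five_prime_UTR", u5$start[i],
                            u5$end[i], gn$strand, ".",
                            sprintf("Parent=%s", tid)))
    }
    cds <- gn$cds[[1]]
    ord <- if (gn$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    cum <- 0L
    for (i in ord) {
      phase <- (3L - cum %% 3L) %% 3L
      lines <- c(lines, fmt(gn$chrom, "CDS", cds$start[i], cds$end[i],
                            gn$strand, phase, sprintf("Parent=%s", tid)))
      cum <- cum + (cds$end[i] - cds$start[i])
    }
    u3 <- gn$utr3[[1]]
    for (i in seq_len(nrow(u3))) {
      lines <- c(lines, fmt(gn$chrom, "three_prime_UTR", u3$start[i],
                            u3$end[i], gn$strand, ".",
                            sprintf("Parent=%s", tid)))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports via rtracklayer and reconstructs one transcript per gene; when a
#' gene carries several transcripts the first is used and a message reports
#' the count. UTRs missing from the file are derived as exon minus CDS,
#' assigned 5'/3' by strand.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (0-based half-open coordinates).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L  # to 0-based half-open
  genes <- df[df$type == "gene", ]
  tx <- df[df$type == "mRNA" | df$type == "transcript", ]
  n_multi <- sum(table(unlist(tx$Parent)) > 1)
  if (n_multi > 0) {
    inform(sprintf("%d gene(s) with multiple transcripts; using the first of each.",
                   n_multi))
  }
  parent_of <- function(x) vapply(x$Parent, function(p) p[1], character(1))
  tx$gene <- parent_of(tx)
  tx <- tx[!duplicated(tx$gene), ]
  feats <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"), ]
  feats$tx <- parent_of(feats)
  rows <- lapply(seq_len(nrow(genes)), function(k) {
    gn <- genes[k, ]
    gid <- gn$ID
    t1 <- tx[tx$gene == gid, ]
    if (nrow(t1) == 0) return(NULL)
    f <- feats[feats$tx == t1$ID[1], ]
    iv <- function(type) {
      x <- f[f$type == type, c("start0", "end")]
      names(x) <- c("start", "end")
      x[order(x$start), , drop = FALSE]
    }
    exons <- iv("exon"); cds <- iv("CDS")
    u5 <- iv("five_prime_UTR"); u3 <- iv("three_prime_UTR")
    if (nrow(u5) == 0 && nrow(u3) == 0 && nrow(cds) > 0 && nrow(exons) > 0) {
      derived <- derive_utrs(exons, cds, as.character(gn$strand))
      u5 <- derived$utr5; u3 <- derived$utr3
    }
    tibble(gene_id = gid, chrom = as.character(gn$seqnames),
           strand = as.character(gn$strand),
           start = gn$start0, end = gn$end,
           exons = list(exons), cds = list(cds),
           utr5 = list(u5), utr3 = list(u3))
  })
  bind_rows(rows)
}

# Exonic bases outside the CDS, split into the regions 5' and 3' of the CDS
# footprint on the coding strand.
derive_utrs <- function(exons, cds, strand) {
  cds_lo <- min(cds$start); cds_hi <- max(cds$end)
  pieces_lo <- list(); pieces_hi <- list()
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (s < cds_lo) pieces_lo[[length(pieces_lo) + 1]] <-
        data.frame(start = s, end = min(e, cds_lo))
    if (e > cds_hi) pieces_hi[[length(pieces_hi) + 1]] <-
        data.frame(start = max(s, cds_hi), end = e)
  }
  lo <- if (length(pieces_lo)) do.call(rbind, pieces_lo) else
    data.frame(start = numeric(), end = numeric())
  hi <- if (length(pieces_hi)) do.call(rbind, pieces_hi) else
    data.frame(start = numeric(), end = numeric())
  if (strand == "+") list(utr5 = lo, utr3 = hi) else list(utr5 = hi, utr3 = lo)
}
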