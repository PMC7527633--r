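# A minimal hand-built gene on each strand, with a reference sequence
# constructed explicitly so every coding expectation can be worked out by eye.
hand_gene <- function(strand = "+") {
  tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = strand, start = 2000, end = 4600,
    exons = list(shift_df(gene_exons(strand), 2000)),
    cds = list(shift_df(gene_cds(strand), 2000)),
    utr5 = list(shift_df(gene_u5(strand), 2000)),
    utr3 = list(shift_df(gene_u3(strand), 2000))
  )
}
shift_df <- function(df, by) data.frame(start = df$start + by,
                                        end = df$end + by)
gene_exons <- function(s) {
  if (s == "+") data.frame(start = c(0, 1000, 2000), end = c(401, 1600, 2600))
  else data.frame(start = c(0, 1000, 2199), end = c(600, 1600, 2600))
}
gene_cds <- function(s) {
  if (s == "+") data.frame(start = c(200, 1000, 2000), end = c(401, 1600, 2300))
  else data.frame(start = c(300, 1000, 2199), end = c(600, 1600, 2400))
}
gene_u5 <- function(s) {
  if (s == "+") data.frame(start = 0, end = 200)
  else data.frame(start = 2400, end = 2600)
}
gene_u3 <- function(s) {
  if (s == "+") data.frame(start = 2300, end = 2600)
  else data.frame(start = 0, end = 300)
}

# reference: all "G" except planted codon bases
make_ref <- function(len = 10000, set = NULL) {
  s <- rep("G", len)
  if (!is.null(set)) s[set$pos] <- set$base  # 1-based
  Biostrings::DNAStringSet(setNames(paste(s, collapse = ""), "chr1"))
}

ann_for <- function(pos, ref, alt, genes, reference, ...) {
  g <- make_g(matrix(1L, 4, length(pos)), pos = pos, ref = ref, alt = alt,
              chrom_lengths = c(chr1 = 10000))
  annotate_variants(g, genes, reference, ...)
}

test_that("positional categories follow the precedence and distance rules", {
  genes <- hand_gene("+")
  ref <- make_ref()
  # gene span [2000, 4600): TSS at 2000 (0-based)
  ann <- ann_for(
    pos = c(1501, 2100, 2302, 2403, 2404, 3650, 4500, 5100, 7000),
    ref = rep("G", 9), alt = rep("A", 9),
    genes = genes, reference = ref
  )
  expect_equal(as.character(ann$category),
               c("upstream",          # 500 bp 5' of TSS
                 "utr5",              # in [2000, 2200)
                 "coding_synonymous", # third codon base, GGG -> GGA (Gly)
                 "splicing",          # intron base 2 after exon end 2401
                 "intron",            # intron base 3
                 "intron",            # mid second intron, 50 bp from exon
                 "utr3",              # in [4300, 4600)
                 "downstream",        # 500 bp past the end
                 "intergenic"))
  expect_equal(ann$gene_id[1], "g1")
  expect_true(is.na(ann$gene_id[9]))
})

test_that("codon translation distinguishes synonymous from non-synonymous", {
  genes <- hand_gene("+")
  # CDS starts at genomic 2200 (0-based) -> first codon bases 2200,2201,2202
  # plant GGA at the first codon: Gly
  ref <- make_ref(set = data.frame(pos = c(2201, 2202, 2203),
                                   base = c("G", "G", "A")))
  # third codon base GGA -> GGG is still glycine: synonymous
  ann_syn <- ann_for(2203, "A", "G", genes, ref)
  expect_equal(as.character(ann_syn$category), "coding_synonymous")
  # second base GGA -> GAA (Gly -> Glu): non-synonymous
  ann_non <- ann_for(2202, "G", "A", genes, ref)
  expect_equal(as.character(ann_non$category), "coding_nonsynonymous")
})

test_that("minus-strand genes translate on the reverse complement", {
  genes <- hand_gene("-")
  # last CDS interval [4199, 4400) genomic; coding starts at genomic 4399
  # (0-based 4399 = first coding base). All-G reference: first codon is
  # CCC (Pro) on the coding strand.
  ref <- make_ref()
  # genomic base at 0-based 4397 is the codon's third base; G->A genomic
  # means C->T coding: CCC -> CCT, still proline
  ann_syn <- ann_for(4398, "G", "A", genes, ref)
  expect_equal(as.character(ann_syn$category), "coding_synonymous")
  # middle base: CCC -> CTC (Pro -> Leu)
  ann_non <- ann_for(4399, "G", "A", genes, ref)
  expect_equal(as.character(ann_non$category), "coding_nonsynonymous")
  # strand-aware flanks: 500 bp left of a minus-strand gene is downstream
  ann_fl <- ann_for(c(1501, 5100), c("G", "G"), c("A", "A"), genes, ref)
  expect_equal(as.character(ann_fl$category), c("downstream", "upstream"))
})

test_that("REF mismatches and broken CDS are reported", {
  genes <- hand_gene("+")
  ref <- make_ref()
  expect_error(ann_for(2203, "T", "A", genes, ref), "REF disagrees")
  broken <- genes
  broken$cds[[1]]$end[1] <- broken$cds[[1]]$end[1] - 1  # 1100 bp: not %% 3
  expect_warning(ann <- ann_for(2500, "G", "A", broken, ref),
                 "not a codon multiple")
  expect_equal(as.character(ann$category), "intergenic")
})

test_that("synthetic cohort annotation matches construction-known truth", {
  sim <- simulate_cohort(sim_config(
    chrom_lengths = c(chrA = 400000, chrB = 300000), n_sites = 2500,
    sweep_intervals = NULL, missing_rate = 0, seed = 17
  ))
  g <- sim$genotypes
  td <- tempfile(); dir.create(td)
  write_cohort(g, NULL, td, gene_spacing = 25000)
  genes <- read_gene_models(file.path(td, "genes.gff3"))
  ref <- read_reference(file.path(td, "reference.fa"))
  ann <- annotate_variants(g, genes, ref)

  # partition: category counts sum to the variant total
  smry <- annotation_summary(ann)
  expect_equal(sum(smry$n), nrow(g$sites))

  # independent truth from the template arithmetic (positional categories)
  truth_cat <- vapply(seq_len(nrow(g$sites)), function(k) {
    p0 <- g$sites$pos[k] - 1
    ch <- g$sites$chrom[k]
    cand <- genes[genes$chrom == ch &
                    genes$start - 1000 <= p0 & genes$end + 1000 > p0, ]
    if (nrow(cand) == 0) return("intergenic")
    gn <- cand[1, ]
    off <- p0 - gn$start
    if (off < 0 || off >= 2600) {
      before <- off < 0
      if (gn$strand == "+") return(if (before) "upstream" else "downstream")
      return(if (before) "downstream" else "upstream")
    }
    tpl <- if (gn$strand == "+") {
      list(ex = gene_exons("+"), cds = gene_cds("+"), u5 = gene_u5("+"),
           u3 = gene_u3("+"))
    } else {
      list(ex = gene_exons("-"), cds = gene_cds("-"), u5 = gene_u5("-"),
           u3 = gene_u3("-"))
    }
    inside <- function(iv) any(off >= iv$start & off < iv$end)
    if (inside(tpl$cds)) return("coding")
    if (inside(tpl$u5)) return("utr5")
    if (inside(tpl$u3)) return("utr3")
    if (inside(tpl$ex)) return("intron")
    bounds <- sort(unique(c(tpl$ex$start, tpl$ex$end)))
    dist <- min(c(abs(off - bounds[off < bounds][1]),
                  off - bounds[bounds <= off][sum(bounds <= off)] + 1),
                na.rm = TRUE)
    if (dist <= 2) "splicing" else "intron"
  }, character(1))
  got <- as.character(ann$category)
  got[got %in% c("coding_synonymous", "coding_nonsynonymous")] <- "coding"
  expect_identical(got, truth_cat)
})

test_that("region SNV counts respect the half-open convention", {
  g <- make_g(matrix(1L, 2, 3), pos = c(1, 50, 100),
              chrom_lengths = c(chr1 = 1000))
  out <- variants_in_regions(g, tibble::tibble(chrom = "chr1", start = 0,
                                               end = 100))
  expect_equal(out$n_snvs, 2L)  # pos 1 and 50 counted; the exclusive end
  # leaves pos 100 outside [0, 100)
  empty <- variants_in_regions(g, tibble::tibble(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("region counts match brute-force membership on random input", {
  g <- random_g(n = 4, m = 1000, miss = 0, seed = 18,
                pos = sort(sample(1:1e5, 1000)),
                chrom_lengths = c(chr1 = 1e5))
  set.seed(19)
  starts <- sort(sample(seq(0, 9e4, by = 100), 10))
  regions <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + sample(500:5000, 10))
  out <- variants_in_regions(g, regions)
  for (k in seq_len(nrow(regions))) {
    expect_equal(out$n_snvs[k],
                 oracle_region_count(g, regions$chrom[k], regions$start[k],
                                     regions$end[k]))
  }
})
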