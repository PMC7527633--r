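#' Configuration for a full pipeline run
#'
#' Bundles every stage's inputs and thresholds. Exactly one of `simulation`
#' (a [sim_config()]) or `vcf` (+ `populations`) must be given. All defaults
#' are the scan's canonical values: 100-kb/10-kb windows, top 1% joint
#' thresholds, scan filters call rate >= 0.90 / MAF >= 0.05 / missing <= 0.20,
#' structure filters MAF >= 0.05 / missing < 0.05 / qual >= 30 with
#' 100-SNV/10-SNV LD pruning.
#'
#' @param simulation A [sim_config()], or `NULL` when reading a VCF.
#' @param vcf,populations Paths to a VCF and a sample-population TSV.
#' @param gff3,fasta,features Optional paths: gene models, reference FASTA,
#'   BED features for overlap summaries (simulation mode generates its own).
#' @param out_dir Output directory.
#' @param window_size,step_size,min_snvs,estimator,q Scan parameters (see
#'   [window_stats()], [sweep_scan()]).
#' @param min_call_rate,min_maf,max_missing Scan filters
#'   ([filter_sites_scan()]).
#' @param struct_min_maf,struct_max_missing,struct_min_qual Structure filters
#'   ([filter_sites_structure()]).
#' @param prune_window,prune_step,prune_r2 LD pruning ([ld_prune()]); the
#'   plink-style structure setting uses `prune_r2 = 0.01`.
#' @param ld_max_dist,ld_bin_width LD decay curve ([ld_decay()]).
#' @param pca_components Components returned by [genotype_pca()].
#' @param write_fasta Write the simulated reference FASTA (and run coding
#'   annotation)?
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, vcf = NULL, populations = NULL,
                       gff3 = NULL, fasta = NULL, features = NULL,
                       out_dir = "sweepscan_run",
                       window_size = 100000, step_size = 10000,
                       min_snvs = 10, estimator = "wc", q = 0.01,
                       min_call_rate = 0.90, min_maf = 0.05,
                       max_missing = 0.20,
                       struct_min_maf = 0.05, struct_max_missing = 0.05,
                       struct_min_qual = 30,
                       prune_window = 100, prune_step = 10, prune_r2 = 0.2,
                       ld_max_dist = 300000, ld_bin_width = 500,
                       pca_components = 10, write_fasta = TRUE) {
  if (is.null(simulation) == is.null(vcf)) {
    abort("provide exactly one of `simulation` or `vcf`.")
  }
  if (!is.null(vcf) && is.null(populations)) {
    abort("`populations` is required with `vcf`.")
  }
  if (!(q > 0 && q < 0.5)) abort("`q` must lie in (0, 0.5).")
  if (!estimator %in% c("wc", "hudson")) abort("`estimator` must be wc or hudson.")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments; a `simulation:` block is
#' passed to [sim_config()] (its `sweep_intervals` given as a list of
#' `{chrom, start, end}` entries).
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$chrom_lengths)) {
      sim$chrom_lengths <- unlist(sim$chrom_lengths)
    }
    if (!is.null(sim$sweep_intervals)) {
      sim$sweep_intervals <- bind_rows(lapply(sim$sweep_intervals, as_tibble))
    }
    y$simulation <- do.call(sim_config, sim)
  }
  do.call(run_config, y)
}

#' Run the full sweep-scan pipeline
#'
#' Executes simulate/read -> filter -> window statistics -> joint top-quantile
#' scan -> population structure -> annotation -> report, writing each stage's
#' outputs as plain TSV/BED/JSON plus a machine-readable manifest
#' (`manifest.json`: config, package version, per-file MD5 checksums, stage
#' wall times). Re-running with an identical config reproduces byte-identical
#' statistic tables. A stage failure aborts with the stage named and leaves a
#' `FAILED` marker in the output directory.
#'
#' @param config A [run_config()].
#' @return An object of class `sweepscan_run`: the key result objects plus
#'   the manifest, invisibly reusable by [pipeline_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sweepscan",
                   version = as.character(utils::packageVersion("sweepscan")),
                   config = serialize_config(config),
                   config_hash = rlang::hash(serialize_config(config)),
                   stages = list())
  outputs <- character(0)
  t_all <- Sys.time()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }

  truth <- NULL; genes <- NULL; reference <- NULL; features <- NULL
  g <- run_stage("input", function() {
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation)
      truth <<- sim$truth
      files <- write_cohort(sim$genotypes, sim$truth, out,
                            write_fasta = config$write_fasta)
      outputs <<- c(outputs, files$path)
      if ("gff3" %in% files$file) {
        genes <<- read_gene_models(files$path[files$file == "gff3"])
      }
      if ("fasta" %in% files$file) {
        reference <<- read_reference(files$path[files$file == "fasta"])
      }
      features <<- read_bed(files$path[files$file == "truth_bed"])
      sim$genotypes
    } else {
      popmap <- read_population_map(config$populations)
      if (!is.null(config$gff3)) genes <<- read_gene_models(config$gff3)
      if (!is.null(config$fasta)) reference <<- read_reference(config$fasta)
      if (!is.null(config$features)) features <<- read_bed(config$features)
      read_vcf(config$vcf, popmap)
    }
  })

  g_scan <- run_stage("filter", function() {
    gs <- filter_sites_scan(g, config$min_call_rate, config$min_maf,
                            config$max_missing)
    readr::write_tsv(attr(gs, "removed"), file.path(out, "filter_scan.tsv"))
    filt_path <- file.path(out, "filtered.vcf")
    write_vcf(gs, filt_path)
    outputs <- c(outputs, filt_path)
    gs
  })

  stats <- run_stage("stats", function() {
    ws <- window_stats(g_scan, config$window_size, config$step_size,
                       config$min_snvs, config$estimator)
    readr::write_tsv(as_tibble(ws), file.path(out, "windows.tsv"))
    ws
  })

  scan <- run_stage("scan", function() {
    sc <- sweep_scan(stats, q = config$q, genes = genes, features = features)
    reg <- sc$regions
    write_bed(reg, file.path(out, "regions.bed"),
              names = sprintf("region%d", seq_len(nrow(reg))))
    reg_flat <- reg
    if (!is.null(reg_flat$genes)) {
      reg_flat$genes <- vapply(reg_flat$genes, paste, character(1),
                               collapse = ",")
    }
    readr::write_tsv(reg_flat, file.path(out, "regions.tsv"))
    jsonlite::write_json(
      list(q = sc$thresholds$q, fst_threshold = sc$thresholds$fst_threshold,
           ratio_threshold = unbox_inf(sc$thresholds$ratio_threshold),
           n_valid_windows = sc$thresholds$n_windows),
      file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA)
    smry <- as.list(glance(sc))
    smry$ratio_threshold <- unbox_inf(smry$ratio_threshold)
    if (!is.null(truth)) {
      smry <- c(smry, as.list(score_recovery(reg, truth)))
    }
    jsonlite::write_json(smry, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(sc$feature_summary)) {
      readr::write_tsv(sc$feature_summary,
                       file.path(out, "feature_overlap.tsv"))
    }
    sc
  })

  structure_res <- run_stage("structure", function() {
    gs <- filter_sites_structure(g, config$struct_min_maf,
                                 config$struct_max_missing,
                                 config$struct_min_qual)
    readr::write_tsv(attr(gs, "removed"),
                     file.path(out, "filter_structure.tsv"))
    gp <- ld_prune(gs, config$prune_window, config$prune_step,
                   config$prune_r2)
    dmat <- ibs_distance(gp)
    write_phylip_dist(dmat, file.path(out, "distances.phylip"))
    tree <- neighbor_joining(dmat)
    ape::write.tree(tree, file.path(out, "tree.nwk"))
    pca <- genotype_pca(gp, config$pca_components)
    readr::write_tsv(tidy(pca), file.path(out, "pca_coords.tsv"))
    readr::write_tsv(tibble(component = seq_along(pca$eigenvalues),
                            eigenvalue = pca$eigenvalues,
                            variance_explained = pca$variance_explained),
                     file.path(out, "pca_eigenvalues.tsv"))
    ld <- bind_rows(lapply(populations(g), function(p) {
      mutate(ld_decay(gs, p, config$ld_max_dist, config$ld_bin_width),
             population = p, .before = 1)
    }))
    readr::write_tsv(ld, file.path(out, "ld_decay.tsv"))
    list(pruned = gp, distances = dmat, tree = tree, pca = pca,
         ld_decay = ld)
  })

  annotation <- run_stage("annotate", function() {
    if (is.null(genes) || is.null(reference)) return(NULL)
    ann <- annotate_variants(g, genes, reference)
    readr::write_tsv(ann, file.path(out, "annotation.tsv"))
    readr::write_tsv(annotation_summary(ann),
                     file.path(out, "annotation_summary.tsv"))
    ann
  })

  run <- structure(
    list(out_dir = out, config = config, genotypes = g, truth = truth,
         stats = stats, scan = scan, structure = structure_res,
         annotation = annotation),
    class = "sweepscan_run"
  )
  run_stage("report", function() {
    writeLines(pipeline_report(out), file.path(out, "report.txt"))
  })
  manifest$stages$total <- list(
    seconds = round(as.numeric(Sys.time() - t_all, units = "secs"), 3))
  files <- list.files(out, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json")]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(run)
}

unbox_inf <- function(x) if (is.infinite(x)) "Inf" else x

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    sim$chrom_lengths <- as.list(sim$chrom_lengths)
    sim$sweep_intervals <- as.data.frame(sim$sweep_intervals)
    cfg$simulation <- sim
  }
  cfg
}

#' @export
print.sweepscan_run <- function(x, ...) {
  cat(sprintf("<sweepscan_run> %s\n", x$out_dir))
  print(x$scan)
  invisible(x)
}

#' Human-readable summary of a completed run
#'
#' Re-reads a run directory's stage outputs and assembles the summary
#' document: SNV counts before/after each filter, Ts/Tv, the annotation
#' category table, window-statistic quantiles, thresholds, region count and
#' total span, genes per region, and recovery scores when simulation truth is
#' available. Missing stage outputs are flagged as gaps rather than errors.
#'
#' @param out_dir A run directory produced by [run_pipeline()].
#' @return Character vector of report lines (also written by the pipeline to
#'   `report.txt`).
#' @export
pipeline_report <- function(out_dir) {
  p <- function(...) file.path(out_dir, ...)
  lines <- c("sweepscan run report", "====================", "")
  gap <- function(what) sprintf("[missing] %s output not found", what)

  if (file.exists(p("filter_scan.tsv"))) {
    fs <- readr::read_tsv(p("filter_scan.tsv"), show_col_types = FALSE)
    win <- if (file.exists(p("windows.tsv"))) {
      readr::read_tsv(p("windows.tsv"), show_col_types = FALSE)
    } else NULL
    lines <- c(lines, "Scan site filters (sites removed per criterion):",
               sprintf("  %-10s %d", fs$criterion, fs$n_removed), "")
  } else lines <- c(lines, gap("filter"), "")

  if (file.exists(p("cohort.vcf")) || file.exists(p("filtered.vcf"))) {
    vcf <- if (file.exists(p("filtered.vcf"))) p("filtered.vcf") else p("cohort.vcf")
    nsites <- length(readr::read_lines(vcf)) -
      sum(startsWith(readr::read_lines(vcf, n_max = 1000), "#"))
    lines <- c(lines, sprintf("SNVs in %s: %d", basename(vcf), nsites), "")
  }

  if (file.exists(p("annotation_summary.tsv"))) {
    an <- readr::read_tsv(p("annotation_summary.tsv"), show_col_types = FALSE)
    lines <- c(lines, "Annotation categories:",
               sprintf("  %-22s %8d  %6.2f%%", an$category, an$n, an$pct),
               sprintf("  %-22s %8d", "total", sum(an$n)), "")
  } else lines <- c(lines, gap("annotation"), "")

  if (file.exists(p("windows.tsv"))) {
    win <- readr::read_tsv(p("windows.tsv"), show_col_types = FALSE)
    ok <- win$valid
    qs <- function(x) stats::quantile(x[ok & is.finite(x)],
                                      c(0.5, 0.95, 0.99), na.rm = TRUE)
    qf <- qs(win$fst); qr <- qs(win$pi_ratio)
    lines <- c(lines,
               sprintf("Windows: %d total, %d valid; mean SNVs/window %.1f",
                       nrow(win), sum(ok), mean(win$n_snvs[ok])),
               sprintf("  F_ST quantiles (50/95/99%%): %.4f %.4f %.4f",
                       qf[1], qf[2], qf[3]),
               sprintf("  pi-ratio quantiles (50/95/99%%): %.4f %.4f %.4f",
                       qr[1], qr[2], qr[3]), "")
  } else lines <- c(lines, gap("windows"), "")

  if (file.exists(p("thresholds.json")) && file.exists(p("summary.json"))) {
    th <- jsonlite::read_json(p("thresholds.json"))
    sm <- jsonlite::read_json(p("summary.json"))
    lines <- c(lines,
               sprintf("Joint top-%g%% thresholds: F_ST >= %.6f, pi-ratio >= %s",
                       100 * as.numeric(th$q), as.numeric(th$fst_threshold),
                       format_ratio(th$ratio_threshold)),
               sprintf("Selected windows: %d -> regions: %d spanning %.2f Mb",
                       sm$n_selected_windows, sm$n_regions,
                       sm$total_region_bp / 1e6),
               sprintf("Mean SNVs per selected window: %.1f",
                       as.numeric(sm$mean_snvs_per_selected_window)),
               if (!is.null(sm$n_genes) && !is.na(sm$n_genes)) {
                 sprintf("Genes in regions: %s", sm$n_genes)
               },
               if (!is.null(sm$precision)) c(
                 "Recovery vs planted sweeps:",
                 sprintf("  precision %.4f recall %.4f jaccard %.4f interval-recall %.4f",
                         as.numeric(sm$precision), as.numeric(sm$recall),
                         as.numeric(sm$jaccard),
                         as.numeric(sm$interval_recall))
               ),
               "")
  } else lines <- c(lines, gap("scan"), "")

  if (file.exists(p("pca_eigenvalues.tsv"))) {
    ev <- readr::read_tsv(p("pca_eigenvalues.tsv"), show_col_types = FALSE)
    lines <- c(lines,
               sprintf("PCA: PC1 %.2f%%, PC2 %.2f%% of variance",
                       100 * ev$variance_explained[1],
                       100 * ev$variance_explained[2]), "")
  } else lines <- c(lines, gap("structure"), "")
  lines
}

format_ratio <- function(x) {
  if (identical(x, "Inf")) "Inf" else sprintf("%.6f", as.numeric(x))
}
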