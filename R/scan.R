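#' Nearest-rank empirical upper-quantile threshold
#'
#' Sorts the values in decreasing order (infinities rank above every finite
#' value) and returns the value at rank `ceiling(q * N)`: the "top q"
#' threshold. Selection downstream uses `value >= threshold`, so when values
#' are distinct exactly the best `ceiling(q * N)` are selected; ties beyond
#' the rank are included (conservative).
#'
#' @param values Numeric vector (NAs dropped; `+Inf` allowed).
#' @param q Upper tail fraction in (0, 0.5), default 0.01 (top 1%).
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, q = 0.01) {
  if (!(q > 0 && q < 0.5)) abort("`q` must lie in (0, 0.5).")
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to threshold.")
  if (length(values) < 1 / q) {
    warn(sprintf("only %d values for a top-%g%% threshold; quantile is coarse.",
                 length(values), 100 * q))
  }
  if (min(values) == max(values)) {
    warn("all values identical: threshold selects every window.")
  }
  sorted <- sort(values, decreasing = TRUE)
  sorted[ceiling(q * length(values))]
}

#' Joint empirical thresholds for a window-statistics table
#'
#' Computes the top-`q` thresholds of the F_ST and diversity-ratio empirical
#' distributions over valid windows only.
#'
#' @param stats A [window_stats()] tibble.
#' @param q Upper tail fraction (default 0.01).
#' @return A list of class `scan_thresholds` with `fst_threshold`,
#'   `ratio_threshold`, `q`, `n_windows`.
#' @export
scan_thresholds <- function(stats, q = 0.01) {
  ok <- stats$valid & !is.na(stats$fst) & !is.na(stats$pi_ratio)
  structure(
    list(fst_threshold = empirical_threshold(stats$fst[ok], q),
         ratio_threshold = empirical_threshold(stats$pi_ratio[ok], q),
         q = q, n_windows = sum(ok)),
    class = "scan_thresholds"
  )
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat(sprintf(
    "<scan_thresholds> top %g%% of %d valid windows: F_ST >= %.6f, pi-ratio >= %.6f\n",
    100 * x$q, x$n_windows, x$fst_threshold, x$ratio_threshold))
  invisible(x)
}

#' Select windows jointly exceeding both thresholds
#'
#' A window is a sweep candidate only when it lies in the top tail of *both*
#' empirical distributions (intersection, not union). Invalid windows are
#' never selected.
#'
#' @param stats A [window_stats()] tibble.
#' @param thresholds A [scan_thresholds()] object.
#' @return `stats` restricted to the selected windows.
#' @export
select_windows <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "scan_thresholds"))
  sel <- stats$valid &
    !is.na(stats$fst) & stats$fst >= thresholds$fst_threshold &
    !is.na(stats$pi_ratio) & stats$pi_ratio >= thresholds$ratio_threshold
  stats[sel, ]
}

#' Merge selected windows into candidate sweep regions
#'
#' Overlapping or book-ended (end == next start) selected windows on the same
#' chromosome are merged into maximal runs; each region records the number of
#' member windows and the maxima of their F_ST and diversity ratio.
#'
#' @param selected A tibble of selected windows (as from [select_windows()]).
#' @return A tibble: `chrom`, `start`, `end`, `n_windows`, `max_fst`,
#'   `max_ratio`, sorted and pairwise disjoint within chromosome.
#' @export
merge_regions <- function(selected) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), max_fst = numeric(),
                  max_ratio = numeric())
  if (nrow(selected) == 0) return(empty)
  selected <- arrange(selected, .data$chrom, .data$start)
  out <- list()
  cur <- NULL
  for (k in seq_len(nrow(selected))) {
    w <- selected[k, ]
    if (is.null(cur) || w$chrom != cur$chrom || w$start > cur$end) {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- tibble(chrom = w$chrom, start = w$start, end = w$end,
                    n_windows = 1L, max_fst = w$fst, max_ratio = w$pi_ratio)
    } else {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
      cur$max_fst <- max(cur$max_fst, w$fst)
      cur$max_ratio <- max(cur$max_ratio, w$pi_ratio)
    }
  }
  out[[length(out) + 1]] <- cur
  bind_rows(out)
}

#' Genes overlapping candidate regions
#'
#' A gene is assigned to a region when its transcript span intersects the
#' region by at least 1 bp (`full_containment = TRUE` requires the whole
#' span inside the region).
#'
#' @param regions A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes A gene-model tibble (see [read_gene_models()]): columns
#'   `gene_id`, `chrom`, `start`, `end` at minimum.
#' @param full_containment Require the gene fully inside the region?
#' @return `regions` with a list-column `genes` of overlapping gene ids and a
#'   column `n_genes`; the deduplicated genome-wide gene list is attached as
#'   attribute `"gene_ids"`.
#' @export
genes_in_regions <- function(regions, genes, full_containment = FALSE) {
  hits <- lapply(seq_len(nrow(regions)), function(k) {
    r <- regions[k, ]
    same <- genes$chrom == r$chrom
    ov <- if (full_containment) {
      same & genes$start >= r$start & genes$end <= r$end
    } else {
      same & genes$start < r$end & genes$end > r$start
    }
    genes$gene_id[ov]
  })
  regions$genes <- hits
  regions$n_genes <- lengths(hits)
  attr(regions, "gene_ids") <- unique(unlist(hits))
  regions
}

#' Overlap of candidate regions with interval features
#'
#' Summarises, per feature class, how many features intersect any candidate
#' region (a QTL-style overlap table).
#'
#' @param regions A tibble with `chrom`, `start`, `end`.
#' @param features A tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and a `class` (or `name`) column.
#' @return A tibble `class`, `n_features`, `n_overlapping`,
#'   `pct_of_overlapping` (share of all overlapping features in this class).
#' @export
feature_overlap <- function(regions, features) {
  if (nrow(features) == 0) {
    return(tibble(class = character(), n_features = integer(),
                  n_overlapping = integer(), pct_of_overlapping = numeric()))
  }
  cls <- features[["class"]] %||% features[["name"]]
  if (is.null(cls)) abort("`features` needs a class or name column.")
  ov <- vapply(seq_len(nrow(features)), function(k) {
    f <- features[k, ]
    any(regions$chrom == f$chrom & regions$start < f$end &
          regions$end > f$start)
  }, logical(1))
  out <- tibble(class = cls, overlapping = ov) |>
    group_by(.data$class) |>
    summarise(n_features = n(), n_overlapping = sum(.data$overlapping),
              .groups = "drop")
  total <- sum(out$n_overlapping)
  out$pct_of_overlapping <- if (total > 0) 100 * out$n_overlapping / total else 0
  out
}

#' Score detected regions against planted-sweep truth
#'
#' Base-pair precision, recall and Jaccard of the detected regions versus the
#' true sweep intervals, plus interval-level recall: a planted sweep counts as
#' recovered when at least `min_coverage` of its span is covered by detected
#' regions.
#'
#' @param regions A tibble with `chrom`, `start`, `end`.
#' @param truth A `sim_truth` object or a tibble of true intervals.
#' @param min_coverage Coverage fraction for interval-level recovery.
#' @return A one-row tibble: `precision`, `recall`, `jaccard`,
#'   `interval_recall`, `n_detected`, `n_truth`, `precision_defined`.
#' @export
score_recovery <- function(regions, truth, min_coverage = 0.5) {
  tr <- if (inherits(truth, "sim_truth")) truth$sweep_intervals else as_tibble(truth)
  det_bp <- sum(regions$end - regions$start)
  truth_bp <- sum(tr$end - tr$start)
  ov_per_truth <- vapply(seq_len(nrow(tr)), function(k) {
    t <- tr[k, ]
    same <- regions$chrom == t$chrom
    sum(pmax(0, pmin(regions$end[same], t$end) -
                pmax(regions$start[same], t$start)))
  }, numeric(1))
  ov <- sum(ov_per_truth)
  precision_defined <- det_bp > 0
  tibble(
    precision = if (precision_defined) ov / det_bp else 0,
    recall = if (truth_bp > 0) ov / truth_bp else NA_real_,
    jaccard = if (det_bp + truth_bp - ov > 0) ov / (det_bp + truth_bp - ov) else NA_real_,
    interval_recall = if (nrow(tr) > 0) {
      mean(ov_per_truth / (tr$end - tr$start) >= min_coverage)
    } else NA_real_,
    n_detected = nrow(regions), n_truth = nrow(tr),
    precision_defined = precision_defined
  )
}

#' Run the joint top-quantile sweep scan
#'
#' Combines [scan_thresholds()], [select_windows()] and [merge_regions()] —
#' and, when gene models or features are supplied, [genes_in_regions()] and
#' [feature_overlap()] — into a single scan result.
#'
#' @param stats A [window_stats()] tibble.
#' @param q Upper tail fraction (default 0.01, the top 1%).
#' @param genes Optional gene-model tibble.
#' @param features Optional feature tibble (BED-style with a class column).
#' @param merge Merge selected windows into maximal regions (default TRUE)?
#'   With `merge = FALSE` every selected window becomes its own region.
#' @return An object of class `sweep_scan` with elements `stats`,
#'   `thresholds`, `selected`, `regions`, `feature_summary`.
#' @export
sweep_scan <- function(stats, q = 0.01, genes = NULL, features = NULL,
                       merge = TRUE) {
  thr <- scan_thresholds(stats, q)
  selected <- select_windows(stats, thr)
  regions <- if (merge) {
    merge_regions(selected)
  } else {
    tibble(chrom = selected$chrom, start = selected$start,
           end = selected$end, n_windows = 1L, max_fst = selected$fst,
           max_ratio = selected$pi_ratio)
  }
  if (!is.null(genes)) regions <- genes_in_regions(regions, genes)
  structure(
    list(stats = stats, thresholds = thr, selected = selected,
         regions = regions,
         feature_summary = if (!is.null(features)) {
           feature_overlap(regions, features)
         } else NULL),
    class = "sweep_scan"
  )
}

#' @export
print.sweep_scan <- function(x, ...) {
  print(x$thresholds)
  cat(sprintf("  %d selected windows -> %d regions spanning %.2f Mb\n",
              nrow(x$selected), nrow(x$regions),
              sum(x$regions$end - x$regions$start) / 1e6))
  if (!is.null(attr(x$regions, "gene_ids"))) {
    cat(sprintf("  %d distinct genes in regions\n",
                length(attr(x$regions, "gene_ids"))))
  }
  invisible(x)
}

#' Tidy a sweep scan into its region table
#'
#' @param x A [sweep_scan()] object.
#' @param ... Unused.
#' @return The region tibble (one row per merged candidate region).
#' @export
tidy.sweep_scan <- function(x, ...) as_tibble(x$regions)

#' One-row summary of a sweep scan
#'
#' @param x A [sweep_scan()] object.
#' @param ... Unused.
#' @return A one-row tibble: thresholds, window and region counts, total
#'   region span, mean SNVs per selected window.
#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(
    q = x$thresholds$q,
    fst_threshold = x$thresholds$fst_threshold,
    ratio_threshold = x$thresholds$ratio_threshold,
    n_valid_windows = x$thresholds$n_windows,
    n_selected_windows = nrow(x$selected),
    n_regions = nrow(x$regions),
    total_region_bp = sum(x$regions$end - x$regions$start),
    mean_snvs_per_selected_window = if (nrow(x$selected)) {
      mean(x$selected$n_snvs)
    } else NA_real_,
    n_genes = if (!is.null(attr(x$regions, "gene_ids"))) {
      length(attr(x$regions, "gene_ids"))
    } else NA_integer_
  )
}
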