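#' Build a sliding-window grid
#'
#' Windows are `[k*step, k*step + window_size)` (0-based half-open) for
#' `k = 0, 1, ...` while the window end fits on the chromosome. A trailing
#' partial window is appended, flagged `partial = TRUE`, when its span is at
#' least half a window; partial windows are excluded from empirical-quantile
#' thresholds by default. Defaults follow the 100-kb window / 10-kb step scan
#' grid.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window span in bp.
#' @param step_size Stride between window starts in bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `partial`.
#' @export
make_windows <- function(chrom_lengths, window_size = 100000,
                         step_size = 10000) {
  if (!(window_size >= step_size && step_size >= 1)) {
    abort("need window_size >= step_size >= 1.")
  }
  if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named.")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < window_size) {
      warn(sprintf("chromosome %s (%d bp) shorter than window size; emitting a single partial window.",
                   ch, as.integer(len)))
      return(tibble(chrom = ch, start = 0, end = len, partial = TRUE))
    }
    starts <- seq(0, len - window_size, by = step_size)
    res <- tibble(chrom = ch, start = starts, end = starts + window_size,
                  partial = FALSE)
    # a trailing partial window only when full windows leave an uncovered
    # tail, and only if it spans at least half a window
    nxt <- max(starts) + step_size
    if (max(starts) + window_size < len && (len - nxt) >= window_size / 2) {
      res <- bind_rows(res, tibble(chrom = ch, start = nxt, end = len,
                                   partial = TRUE))
    }
    res
  })
  bind_rows(out)
}

# (window row index, site index) overlap pairs for a grid and site positions.
# A 1-based site position p lies in [start, end) iff start < p <= end.
window_site_pairs <- function(grid, chrom, pos) {
  win_idx <- integer(0)
  site_idx <- integer(0)
  for (ch in unique(grid$chrom)) {
    wrows <- which(grid$chrom == ch)
    srows <- which(chrom == ch)
    if (length(srows) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[srows], width = 1L),
      IRanges::IRanges(start = grid$start[wrows] + 1L, end = grid$end[wrows])
    )
    win_idx <- c(win_idx, wrows[S4Vectors::subjectHits(hits)])
    site_idx <- c(site_idx, srows[S4Vectors::queryHits(hits)])
  }
  list(win = win_idx, site = site_idx)
}

# Sum per-site values over windows; NA-aware. Returns a length-nrow(grid)
# vector (0 where a window holds no contributing site).
sum_by_window <- function(values, pairs, n_windows) {
  out <- numeric(n_windows)
  keep <- !is.na(values[pairs$site])
  if (!any(keep)) return(out)
  s <- rowsum(values[pairs$site][keep], pairs$win[keep])
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

count_by_window <- function(pairs, n_windows, keep = NULL) {
  w <- pairs$win
  if (!is.null(keep)) w <- w[keep[pairs$site]]
  tab <- table(w)
  out <- integer(n_windows)
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}
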