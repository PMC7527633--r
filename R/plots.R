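#' Genome-wide Manhattan-style plot of a window statistic
#'
#' @param object A [window_stats()] tibble.
#' @param statistic `"fst"` or `"pi_ratio"`.
#' @param thresholds Optional [scan_thresholds()] drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_stats <- function(object, statistic = c("fst", "pi_ratio"),
                                  thresholds = NULL, ...) {
  statistic <- match.arg(statistic)
  df <- as_tibble(object) |>
    filter(.data$valid, is.finite(.data[[statistic]])) |>
    mutate(mid = (.data$start + .data$end) / 2)
  pl <- ggplot(df, aes(x = .data$mid / 1e6, y = .data[[statistic]],
                       colour = .data$chrom)) +
    geom_point(size = 0.4, show.legend = FALSE) +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mb)",
         y = if (statistic == "fst") expression(F[ST]) else
           expression(theta[pi] ~ "ratio")) +
    theme_bw()
  if (!is.null(thresholds)) {
    thr <- if (statistic == "fst") thresholds$fst_threshold else
      thresholds$ratio_threshold
    if (is.finite(thr)) pl <- pl + geom_hline(yintercept = thr,
                                              linetype = "dashed",
                                              colour = "red")
  }
  pl
}

#' Joint distribution of window F_ST and diversity ratio
#'
#' The classic two-statistic sweep-scan scatter: every valid window plotted
#' as diversity ratio versus F_ST, with the two top-quantile thresholds as
#' dashed lines and jointly selected windows highlighted.
#'
#' @param object A [sweep_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  df <- as_tibble(object$stats) |>
    filter(.data$valid, is.finite(.data$pi_ratio), !is.na(.data$fst)) |>
    mutate(selected = .data$fst >= object$thresholds$fst_threshold &
             .data$pi_ratio >= object$thresholds$ratio_threshold)
  pl <- ggplot(df, aes(x = .data$pi_ratio, y = .data$fst,
                       colour = .data$selected)) +
    geom_point(size = 0.5, alpha = 0.6) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    geom_hline(yintercept = object$thresholds$fst_threshold,
               linetype = "dashed") +
    labs(x = expression(theta[pi] ~ "ratio (pop2 / pop1)"),
         y = expression(F[ST]), colour = "selected") +
    theme_bw()
  if (is.finite(object$thresholds$ratio_threshold)) {
    pl <- pl + geom_vline(xintercept = object$thresholds$ratio_threshold,
                          linetype = "dashed")
  }
  pl
}

#' PCA scatter of the first two components
#'
#' @param object A [genotype_pca()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_pca <- function(object, ...) {
  ve <- object$variance_explained
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            colour = .data$population)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    theme_bw()
}

#' LD decay curve plot
#'
#' @param object An [ld_decay()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay <- function(object, ...) {
  df <- filter(as_tibble(object), .data$n_pairs > 0)
  ggplot(df, aes(x = (.data$bin_start + .data$bin_end) / 2e3,
                 y = .data$mean_r2)) +
    geom_line() +
    labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    theme_bw()
}

#' @rdname autoplot.window_stats
#' @param stats A [window_stats()] tibble (data-frame-first alias of the
#'   autoplot method).
#' @export
plot_genome_scan <- function(stats, statistic = c("fst", "pi_ratio"),
                             thresholds = NULL) {
  autoplot.window_stats(stats, statistic, thresholds)
}
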