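#' Configuration for a two-population cohort simulation
#'
#' Defines the study conditions for the synthetic cohort: two panmictic
#' diploid populations diverged under the Balding-Nichols model at a tunable
#' background level, with planted sweep intervals in which the focal
#' ("domestic") population shows elevated differentiation and reduced
#' heterozygosity. The defaults emulate a 20 + 13 diploid resequencing cohort
#' with ~70 SNVs per 100-kb window, five planted 300-kb sweeps on a 150-Mb
#' genome (~1% of the genome), and a genome-wide Ts/Tv of 2.29.
#'
#' @param n_pop1 Number of diploid samples in population 1 (focal/domestic).
#' @param n_pop2 Number of diploid samples in population 2 (wild).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_sites Total number of biallelic SNV sites across the genome.
#' @param background_f Balding-Nichols divergence parameter in (0, 1) applied
#'   to both populations outside sweeps; equals the expected F_ST.
#' @param sweep_intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) giving the planted sweeps, or `NULL` for none.
#' @param sweep_f Divergence parameter used for population 1 inside sweeps;
#'   must exceed `background_f`.
#' @param sweep_diversity_scale Factor in (0, 1] by which population 1's
#'   expected heterozygosity is shrunk inside sweeps (frequencies pushed
#'   toward the nearer of 0/1).
#' @param missing_rate Fraction in [0, 1) of genotypes set to missing.
#' @param tstv_target Target transition/transversion ratio of the emitted
#'   REF/ALT pairs.
#' @param pop_labels Character vector of length 2 naming the populations.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#'
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_pop1 = 20,
                       n_pop2 = 13,
                       chrom_lengths = setNames(rep(30e6, 5),
                                                paste0("chr", 1:5)),
                       n_sites = 105000,
                       background_f = 0.05,
                       sweep_intervals = default_sweep_intervals(chrom_lengths),
                       sweep_f = 0.6,
                       sweep_diversity_scale = 0.1,
                       missing_rate = 0.02,
                       tstv_target = 2.29,
                       pop_labels = c("domestic", "wild"),
                       seed = 1L) {
  cfg <- list(
    n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
    chrom_lengths = chrom_lengths, n_sites = as.integer(n_sites),
    background_f = background_f, sweep_intervals = sweep_intervals,
    sweep_f = sweep_f, sweep_diversity_scale = sweep_diversity_scale,
    missing_rate = missing_rate, tstv_target = tstv_target,
    pop_labels = pop_labels, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default planted-sweep intervals
#'
#' One 300-kb sweep per chromosome, placed one third of the way in.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param sweep_length Sweep length in bp.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
default_sweep_intervals <- function(chrom_lengths, sweep_length = 300000) {
  chrom_lengths <- chrom_lengths[chrom_lengths >= sweep_length]
  if (length(chrom_lengths) == 0) return(tibble(chrom = character(),
                                                start = numeric(),
                                                end = numeric()))
  start <- floor(chrom_lengths / 3)
  tibble(chrom = names(chrom_lengths), start = unname(start),
         end = unname(start) + sweep_length)
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == "")) {
    abort("`chrom_lengths` must be a named vector.")
  }
  if (cfg$n_pop1 < 1 || cfg$n_pop2 < 1) abort("need at least one sample per population.")
  if (cfg$n_sites < 1) abort("`n_sites` must be >= 1.")
  if (!(cfg$background_f > 0 && cfg$background_f < 1)) {
    abort("`background_f` must lie in (0, 1).")
  }
  if (!(cfg$sweep_f > cfg$background_f && cfg$sweep_f < 1)) {
    abort("need 0 < background_f < sweep_f < 1.")
  }
  if (!(cfg$sweep_diversity_scale > 0 && cfg$sweep_diversity_scale <= 1)) {
    abort("`sweep_diversity_scale` must lie in (0, 1].")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (cfg$tstv_target <= 0) abort("`tstv_target` must be positive.")
  if (length(cfg$pop_labels) != 2 || anyDuplicated(cfg$pop_labels)) {
    abort("`pop_labels` must be two distinct labels.")
  }
  sw <- cfg$sweep_intervals
  if (!is.null(sw) && nrow(sw) > 0) {
    sw <- as_tibble(sw)
    if (!all(c("chrom", "start", "end") %in% names(sw))) {
      abort("`sweep_intervals` needs columns chrom, start, end.")
    }
    if (any(!sw$chrom %in% names(cfg$chrom_lengths))) {
      abort("sweep interval on unknown chromosome.")
    }
    if (any(sw$start < 0) || any(sw$end > cfg$chrom_lengths[sw$chrom]) ||
        any(sw$end <= sw$start)) {
      abort("sweep intervals must be non-empty and within chromosome bounds.")
    }
    sw <- arrange(sw, .data$chrom, .data$start)
    by_chrom <- split(sw, sw$chrom)
    overlap <- any(vapply(by_chrom, function(x) {
      nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])
    }, logical(1)))
    if (overlap) abort("sweep intervals must be pairwise disjoint.")
    cfg$sweep_intervals <- sw
  } else {
    cfg$sweep_intervals <- tibble(chrom = character(), start = numeric(),
                                  end = numeric())
  }
  # every chromosome must receive at least one site under proportional allocation
  alloc <- allocate_sites(cfg$chrom_lengths, cfg$n_sites)
  if (any(alloc < 1)) abort("`n_sites` too small: a chromosome would get zero sites.")
  cfg
}

# Largest-remainder allocation of n_sites proportional to chromosome length.
allocate_sites <- function(chrom_lengths, n_sites) {
  w <- chrom_lengths / sum(chrom_lengths)
  base <- floor(w * n_sites)
  rem <- n_sites - sum(base)
  if (rem > 0) {
    frac <- w * n_sites - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(chrom_lengths))
}
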