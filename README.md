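# sweepscan

Selective-sweep detection for two-population diploid genotype data, plus the
population-structure analyses that usually accompany it, in a single tidy R
package.

## What it does, and for whom

When a breed or domesticated population is compared with its wild relative,
regions under positive selection show two joint signatures: unusually high
genetic differentiation (F_ST) and a loss of nucleotide diversity
(&theta;&pi;) in the selected population. sweepscan is for population
geneticists who have a multi-sample VCF with two population labels and want
the classic genome scan for such regions:

* per-site and sliding-window **&theta;&pi;**, **Watterson's &theta;**, and
  **F_ST** (Weir–Cockerham variance components as ratio-of-sums
  `sum(a) / sum(a + b + c)`, or a Hudson-style estimator) on a 100-kb /
  10-kb sliding grid;
* the per-window **diversity ratio** &theta;&pi;(wild) / &theta;&pi;(domestic);
* **joint top-1% empirical thresholding** (nearest-rank quantiles of both
  statistics; a window must be in the top tail of *both*), merging of
  selected windows into candidate regions, gene and BED-feature overlap;
* variant **site filters** (call rate, MAF, missingness, quality) and
  plink-style greedy **LD pruning**;
* **functional annotation** of SNVs against GFF3 gene models (intergenic /
  up/downstream / UTR / splicing / intron / synonymous / non-synonymous,
  translated on the coding strand);
* **structure analyses**: identity-by-state distances, neighbour-joining
  trees (Newick), standardised-genotype PCA with variance explained, LD
  decay curves, Ts/Tv;
* a **synthetic two-population cohort simulator** (Balding–Nichols
  frequencies, planted sweeps with exact truth intervals, tunable
  missingness / MAF spectrum / Ts/Tv) emitting VCF + GFF3 + FASTA + BED, so
  the entire pipeline runs and is tested end-to-end without external data;
* a one-call **pipeline** (`run_pipeline()`) writing plain TSV/BED/JSON
  stage outputs, a manifest with checksums, and a human-readable report,
  with byte-identical re-runs under a fixed seed. A thin CLI wrapper lives
  in `inst/scripts/sweepscan.R`.

Everything user-facing takes a data frame (or the package's
`genotype_matrix`) first and returns tibbles, so results chain with the
pipe; fitted objects have `tidy()` / `glance()` methods and `autoplot()`
figures.

## Worked example

Simulate a 33-sample cohort (20 "domestic" + 13 "wild") on two 5-Mb
chromosomes with one planted 300-kb sweep, then scan for it:

```r
library(sweepscan)

sim <- simulate_cohort(sim_config(
  chrom_lengths = c(chr1 = 5e6, chr2 = 5e6), n_sites = 10000,
  sweep_intervals = tibble::tibble(chrom = "chr1", start = 2e6, end = 2.3e6),
  seed = 1
))
sim$genotypes
#> <genotype_matrix> 33 samples x 10000 sites (domestic: 20, wild: 13)
#>   chromosomes: chr1, chr2
#>   missing genotypes: 2.00%

sc <- sim$genotypes |>
  filter_sites_scan() |>          # call rate >= 0.90, MAF >= 0.05, missing <= 0.20
  window_stats() |>               # 100-kb windows, 10-kb steps, WC F_ST
  sweep_scan(q = 0.01)            # joint top-1% selection + region merging
sc
#> <scan_thresholds> top 1% of 982 valid windows: F_ST >= 0.566297, pi-ratio >= 30.480238
#>   7 selected windows -> 1 regions spanning 0.17 Mb

tidy(sc)                          # one row per merged candidate region
#>   chrom start     end n_windows max_fst max_ratio
#> 1  chr1 2e+06 2170000         7  0.6329      42.6

score_recovery(sc$regions, sim$truth)
#>   precision recall jaccard interval_recall n_detected n_truth
#> 1         1 0.5667  0.5667               1          1       1
```

The thresholds (`F_ST >= 0.566`, ratio `>= 30.5`) are data-set-specific
empirical quantiles, not constants. The single detected region sits at
chr1:2.00–2.17 Mb, inside the planted sweep (precision 1); it covers 57% of
the sweep's span, which counts as recovered at the ≥ 50% interval rule.
`autoplot(sc)` draws the joint F_ST–ratio scatter with both thresholds;
`autoplot(window_stats_result, "fst")` gives the genome-wide view.

On the package's full default cohort (five 30-Mb chromosomes, 105,000
sites, five 300-kb sweeps — see the methods vignette), the joint scan
recovers all five sweeps with base-pair precision ≈ 0.8 across seeds.

## Documentation

* `vignettes/sweep-scan-methods.Rmd` — the model, the simulator's scope and
  limits, numerical choices, and the design decisions behind defaults.
* Function reference — every exported function carries roxygen
  documentation (`?window_stats`, `?sweep_scan`, `?simulate_cohort`, ...).
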