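---
title: "Detecting selective sweeps with joint F_ST / diversity-ratio scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with joint F_ST / diversity-ratio scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
library(dplyr)
```

## The problem and the model

Domestication leaves a characteristic footprint in a genome. When a variant
is driven to (near) fixation in a domesticated population, linked neutral
variation hitchhikes with it: the region loses nucleotide diversity in the
selected population while allele frequencies there drift sharply away from
the wild relative. A sweep region therefore shows *both* an unusually high
fixation index and an unusually strong loss of diversity relative to the
wild population — and requiring both signals jointly is far more specific
than either alone.

sweepscan implements this two-statistic scan for a two-population diploid
cohort (a focal/"domestic" population 1 and a reference/"wild" population
2), genotyped at biallelic SNVs:

* **Nucleotide diversity** $\theta_\pi$. At a single site with $c$ called
  alleles of which $c_{alt}$ are the alternate, the unbiased pairwise
  heterozygosity is $2 c_{ref} c_{alt} / (c(c-1))$ — the fraction of
  differing pairs among all pairs of called alleles. Window diversity is the
  sum over SNVs in the window divided by the window span in bp.
* **Diversity ratio** $\theta_{\pi,2} / \theta_{\pi,1}$ (wild over
  domestic). A sweep in population 1 deflates the denominator, inflating the
  ratio. A window where population 1 has lost all diversity while
  population 2 retains some is assigned $+\infty$, which deliberately sorts
  above every finite ratio; $0/0$ windows are uninformative and dropped.
* **F_ST**. The default estimator is Weir–Cockerham's variance-component
  estimator: per site the among-population ($a$), between-individual ($b$)
  and within-individual ($c$) components are computed from the two sample
  sizes, allele frequencies and observed heterozygosities, and a window
  estimate is the *ratio of sums* $\sum a / \sum (a+b+c)$ — not the mean of
  per-site ratios, which is noise-biased (we measure the bias at roughly
  $-0.03$ for $F = 0.1$ with 20 + 13 diploids). A Hudson-style estimator
  ($1 - \sum h_w / \sum h_b$) is available for sensitivity analysis; it is
  less sensitive to unequal sample sizes. Negative window values are kept:
  clamping would distort the empirical quantiles below.
* **Watterson's** $\theta_W = S / (a_n \cdot \mathrm{span})$ is provided as
  a companion diversity estimator, with $a_n$ the harmonic number of the
  (floored) median called allele count in the window — a robust choice when
  missingness makes the per-site allele count vary.

### Windows

Statistics are computed on a sliding grid of 100-kb windows advancing in
10-kb steps (both configurable). Windows are 0-based half-open. When full
windows leave an uncovered chromosome tail of at least half a window, one
trailing partial window is appended and flagged; partial windows and windows
with fewer than `min_snvs` SNVs (default 10) are excluded from thresholds
and selection, because span-normalised statistics on a handful of SNVs are
dominated by sampling noise.

### Joint top-quantile selection

Thresholds are *empirical*, not parametric: the F_ST threshold is the value
at nearest rank $\lceil qN \rceil$ of the $N$ valid windows sorted
decreasing (default $q = 0.01$, the top 1%), and likewise for the diversity
ratio. A window is a sweep candidate only when it meets **both**
thresholds — the intersection, never the union. With distinct values this
selects exactly the best $\lceil qN \rceil$ windows per statistic; ties at
the threshold are included (conservative). Because the thresholds are
data-set quantiles, their numeric values are properties of each data set,
not constants of the method.

Overlapping or book-ended selected windows merge into maximal regions
(`merge = FALSE` keeps raw windows); a region records its member-window
count and the maxima of both statistics. Genes are attached by any-overlap
(≥ 1 bp) of the transcript span — "harboured" is ambiguous, so strict
containment is available via `full_containment = TRUE` — and BED features
(e.g. QTL classes) are summarised per class.

## The synthetic cohort: what it emulates and what it does not

Real two-population resequencing data at this depth runs to hundreds of GB,
so the package ships a simulator that reproduces the *site-frequency
structure* the scan consumes, at desk scale:

* Ancestral allele frequencies follow the neutral folded spectrum
  ($P(i) \propto 1/i$ over pooled-sample allele counts, truncated to
  $[0.02, 0.98]$).
* Each population's frequency is drawn from the **Balding–Nichols**
  distribution $\mathrm{Beta}(p(1-F)/F,\; (1-p)(1-F)/F)$, whose expected
  F_ST equals $F$ — a closed form that makes calibration testable: at
  `background_f = 0.1` the genome-wide Weir–Cockerham estimate must land
  within ±0.02 of 0.1, and it does.
* Inside planted sweep intervals population 1 uses `sweep_f` instead and its
  frequency is then pushed deterministically toward the nearer of {0, 1} so
  that its expected heterozygosity is scaled by `sweep_diversity_scale`
  (solving $2q'(1-q') = s \cdot 2q(1-q)$ on the near side). Truth intervals
  are therefore exact, which is what recovery scoring needs.
* Genotypes are binomial (2 draws per diploid), missingness is i.i.d.,
  REF/ALT pairs are transitions with probability
  $t/(t+1)$ for a target Ts/Tv of $t$ (default 2.29, a typical mammalian
  genome-wide value), and site qualities are gamma-distributed so the
  quality filter has something to remove.

Defaults are the study conditions the package is tested under: 20 + 13
diploids, five chromosomes of 30 Mb, 105,000 sites (0.7 SNV/kb — about 70
SNVs per 100-kb window), five planted 300-kb sweeps (one per chromosome),
`background_f = 0.05`, `sweep_f = 0.6`, `sweep_diversity_scale = 0.1`,
2% missingness. The genome length is chosen so the 1.5 Mb of planted sweeps
is about 1% of all windows — i.e. within what a top-1% scan *can* recover;
on a much smaller genome the same five sweeps would saturate the quantile
and coverage-based recall would be bounded away from 1 by construction, a
property of the scan, not a defect of the simulator.

Deliberately **not** modelled: linkage (sites are exchangeable draws, so LD
decay curves on simulated data are flat at the finite-sample baseline
$\mathbb{E}[r^2] \approx 1/n$), recombination maps, demography (bottlenecks,
migration, admixture), within-population structure, indels and structural
variation, and sequencing-read error. Passing tests on this cohort
demonstrate the statistics, thresholds and bookkeeping are correct — they do
not demonstrate robustness to demographic confounding, which no
outlier-quantile scan possesses.

```{r simulate}
sim <- simulate_cohort(sim_config(
  chrom_lengths = c(chr1 = 5e6, chr2 = 5e6), n_sites = 10000,
  sweep_intervals = tibble::tibble(chrom = "chr1", start = 2e6, end = 2.3e6),
  seed = 1
))
sim$genotypes
```

## Filtering, annotation and structure analyses

Two filter sets mirror common practice. The scan filter keeps sites with
call rate ≥ 0.90, pooled MAF ≥ 0.05 and missing fraction ≤ 0.20 (the stated
bounds exclude strictly beyond them, so boundary values survive; call-rate
and missingness criteria overlap but are exposed separately so either can be
tightened). The structure filter keeps MAF ≥ 0.05, missing fraction < 0.05
and site quality ≥ 30, followed by plink-style greedy LD pruning
(`window 100 SNVs / step 10 / r²`): within each window the worse member of
the highest-r² pair (lower MAF; ties drop the later position) is removed
until no retained pair exceeds the threshold. MAF is computed pooled across
populations — with 20 + 13 samples a per-population MAF filter would be
dominated by the smaller sample, and pooled matches the common
VCFtools-style default. The pruning threshold 0.01 is the classic
"structure" setting; tree/PCA/LD analyses conventionally use 0.2, which is
the pipeline default for its structure stage.

```{r scan}
g <- filter_sites_scan(sim$genotypes)
ws <- window_stats(g)        # 100-kb / 10-kb grid, WC F_ST
sc <- sweep_scan(ws, q = 0.01)
glance(sc)
score_recovery(sc$regions, sim$truth)
```

Annotation assigns one of nine categories per variant with precedence
coding/splicing > UTR > intron > upstream/downstream > intergenic.
Distances the category names do not pin down are configurable defaults in
the spirit of the usual annotation tools: 1-kb up/downstream flanks and a
2-bp splice window. Coding variants are translated on the coding strand;
a VCF REF that contradicts the reference FASTA is an error naming the site,
and a CDS that is not a codon multiple skips the gene with a warning.
When a variant overlaps several genes the most severe category wins and the
ambiguity is counted. Category counts always partition the variant total.

Structure analyses use identity-by-state distances on dosages
($d = \overline{|d_i - d_j|}/2$ over co-called sites), an in-package
Saitou–Nei neighbour-joining implementation (lexicographic tie-breaks;
negative branch estimates clamped to zero with the deficit moved to the
sibling edge, keeping the joined pair's distance), standardised-genotype PCA
(centred by $2\hat p$, scaled by $\sqrt{2\hat p(1-\hat p)}$, missing values
mean-imputed — defensible because structure-filtered missingness is below
5% — eigenvector signs fixed so the first nonzero loading is positive), and
binned LD-decay curves of dosage $r^2$.

## Numerical choices and degenerate inputs

* $\pi$ is normalised by full window span, not callable sites — downstream
  of a VCF only SNV positions are known. The diversity *ratio* is invariant
  to any normalisation shared by both populations, which is why the scan is
  robust to this choice.
* Sites where a population has fewer than two called alleles contribute
  zero diversity and are skipped for F_ST; windows whose F_ST denominator
  is zero are invalid.
* All-identical threshold inputs select every window, with a warning.
* An empty post-filter matrix is a warning, not an error, so pipelines fail
  at the stage with the real problem.
* Determinism: every stochastic step flows from a single integer seed;
  identical configurations produce byte-identical VCFs, window tables and
  reports (verified by test).

## Problem sizes used by the test-suite and acceptance runs

Tests run the scan end-to-end at reduced scale chosen to keep the full suite
in a couple of minutes while leaving every property measurable: oracle
comparisons on ≤ 6 samples × ≤ 20 sites (exact equality against explicit
enumeration), estimator calibration on 50,000 sites, sweep recovery on the
full default cohort (105,000 sites × 5 seeds), structure checks on
4,000–5,000 sites, and determinism on an 8,000-site two-chromosome run.
`scripts/acceptance.R` re-runs the same computations from scratch against
the installed package and writes the resulting quantities as JSON.

## Known limitations

* Outlier-quantile scans always "select" a top 1% — on a genuinely neutral
  genome the selected windows are false positives by construction. The
  package reports joint-selection counts against each marginal so users can
  see when the intersection carries no extra signal.
* The Balding–Nichols cohort cannot probe haplotype-based statistics (iHS,
  XP-EHH) or the effect of recombination-rate variation on window
  statistics; those are out of scope.
* Both populations are treated as panmictic. Real wild-relative panels are
  often structured; the package makes no attempt to model or correct that.
* One transcript per gene: where a GFF3 carries isoforms the first is used
  and the count of multi-transcript genes is reported.
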