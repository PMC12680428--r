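---
title: "Landscape genomics of clinal SNP panels: models, scans and genomic offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape genomics of clinal SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geaoffset)
```

`geaoffset` implements a complete landscape-genomics workflow for range-wide
diploid SNP panels sampled along environmental gradients — the situation of a
widespread forest tree genotyped across a latitudinal temperature cline. This
vignette explains the statistical models behind each stage, the parameters
that matter, and the choices made where the methods literature leaves the
design open.

## The data model

All analyses start from a `genotype_matrix`: individuals × loci dosages of
the *panel-wide minor allele* (0, 1, 2), with a reserved integer sentinel for
missing calls so the matrix stays integer-typed. Population-level work uses
`pop_allele_freq`, a populations × loci frequency matrix with the observed
allele-copy counts attached, so every downstream regression can weight by
sampling effort.

Dosage signs are only reproducible if the minor allele is defined stably:
the panel-wide count decides, and an exact 50/50 tie goes to the
lexicographically smaller allele character. Re-running an import on permuted
rows therefore yields identical dosages.

## Quality control

`apply_qc_filters()` applies the standard array-QC chain: loci failing the
missingness ceiling (default 10%) or the minor-allele-frequency floor
(default 5%) are removed first, then individuals above the missingness
ceiling (10%), then the MAF filter is re-applied once because removing
individuals shifts allele frequencies. The order (loci → individuals → one
MAF re-pass) mirrors common array practice; every removal is counted in the
`qc_report`, and re-applying the chain to its own output changes nothing.

LD pruning (`ld_prune()`) is greedy and windowed: inside each window
(default 200 loci, stepping by 50) the later-indexed locus of the worst
pair with squared dosage correlation above 0.7 is dropped until no pair
violates the ceiling. The wide default window reflects array designs that
place roughly one SNP per gene, so physical linkage rarely extends past a
few loci. Missing dosages are mean-imputed *within* populations
(`impute_within_population()`), falling back to the global locus mean when a
population has no call at all; imputation within rather than across
populations avoids dragging clinal loci toward the grand mean.

## Diversity, differentiation and isolation tests

`heterozygosity_stats()` reports observed heterozygosity and Nei's unbiased
within-population gene diversity $H_e = 2p(1-p)\,2n/(2n-1)$, with
$F_{IS} = 1 - H_o/H_e$; population values are unweighted means over loci and
overall values unweighted means over populations (a recorded choice — the
alternative, weighting by sample size, is easy to compute from the
per-population table).

`wc_fst()` implements the Weir–Cockerham (1984) variance-component
estimator; the multilocus value is the ratio of summed among-population
components to summed totals, not a mean of per-locus ratios, and negative
pairwise estimates are reported as-is. On Balding–Nichols simulations the
estimator recovers the generating $F$ within ±0.01 (tested at $F = 0.10$,
30 populations × 20 diploids × 1000 loci).

Isolation by distance and by environment are Mantel tests
(`mantel_test()`, via `vegan::mantel`, add-one permutation p-values) of
linearized pairwise $F_{ST}/(1-F_{ST})$ against Vincenty ellipsoid
geodesics (`geodesic_distances()`) and against Mahalanobis distances on the
first two principal components of the standardized environmental table
(`env_distances()`).

## Outlier scans and the consensus panel

Three scans, three error models, one intersection:

* **Trimmed $\chi^2$ $F_{ST}$ scan** (`outflank_scan()`). Per-locus
  uncorrected $F_{ST}$ (weighted among-population variance over
  $\bar p(1-\bar p)$) is modelled as $(\bar F/\mathrm{df})\,\chi^2_{\mathrm{df}}$.
  The two parameters are fitted on the central 90% of the distribution — the
  putatively neutral core — by maximising the *truncated* likelihood, with
  $\bar F$ profiled as the trimmed mean and df found by bounded scalar
  optimisation (tolerance 1e-8). Right-tail p-values for all loci come from
  the fitted distribution; loci with pooled expected heterozygosity below
  0.1 are excluded from both fitting and calling because their $F_{ST}$ is
  dominated by sampling noise.
* **PC Mahalanobis scan** (`pcadapt_scan()`). Dosages are scaled by
  $\sqrt{2\hat p(1-\hat p)}$, individuals decomposed by SVD, each locus
  regressed on the leading $K$ component scores, and the $K$-vector of
  regression z-scores summarised as a Mahalanobis distance (empirical
  covariance by default; minimum-covariance-determinant behind the `robust`
  flag, kept off so default runs are deterministic). The genomic inflation
  factor $\lambda = \mathrm{median}(D^2)/\mathrm{median}(\chi^2_K)$ absorbs
  residual structure before the $\chi^2_K$ tail is read. $K$ defaults to an
  automated Cattell rule: components are retained while the eigenvalue drop
  exceeds 5% of total variance.
* **RDA loading scan** (`rda_outliers()`). Loci whose loading on a retained
  constrained axis lies beyond ±2.5 SD of that axis's loading distribution
  (SD over *all* loci, outliers included — no robust SD) are flagged and
  annotated with the environmental variable most correlated with their
  population frequencies.

Both genomic scans convert p-values to Storey q-values
(`storey_qvalues()`) with the simple tail estimate
$\hat\pi_0 = \min(1, \overline{[p > 0.5]}/0.5)$ — a deliberate, recorded
departure from spline smoothing, which is unstable at a few thousand loci —
and call outliers at $q \le 0.05$. `consensus_outliers()` intersects the
three panels into the potential adaptive variants (PAV) and also reports the
two-of-three union for sensitivity analyses.

## RDA, partial RDA and variance partitioning

`rda_fit()` is a plain multivariate least-squares engine: centred response,
standardized predictors, SVD of the fitted values; eigenvalues are squared
singular values over $n-1$ and adjusted $R^2$ follows Ezekiel,
$1-(1-R^2)(n-1)/(n-p-1)$. Partial RDA residualizes both response and
predictors on the conditioning block first (the standard pCCA
construction); predictors absorbed entirely by the conditioning block are
dropped so numerical noise cannot define canonical axes. The engine is
cross-checked against `vegan::rda` in the test suite (eigenvalues, $R^2$,
adjusted $R^2$, with and without conditioning) but is deliberately not a
wrapper — offset projection needs the regression coefficients and
standardization constants in an open form.

Geography enters as distance-based Moran eigenvector maps
(`dbmem_basis()`): geodesic distances truncated at the longest
minimum-spanning-tree edge (larger distances set to four times the
threshold), Gower-centred, eigen-decomposed, positive-eigenvalue axes
retained. Axes are then filtered by `forward_select()`, classic
two-criterion forward selection: a candidate enters only if its permutation
p-value beats $\alpha = 0.05$ *and* the cumulative adjusted $R^2$ stays at
or below the global model's. When the candidate count reaches $n-1$ the
global adjusted $R^2$ is undefined and the guard is disabled with a
warning. The guard is knife-edged when many uninformative candidates
accompany a single strong one (the noise drags the global adjusted $R^2$
down to the single-predictor value); with many weak spatial predictors —
the dbMEM situation — it behaves as intended.

`variance_partition()` decomposes the combined adjusted $R^2$ into an
environment-exclusive fraction $a$, a geography-exclusive fraction $c$ and
a confounded fraction $b = R^2_{adj}(\text{both}) - a - c$; the three sum
to the combined value exactly by construction, and the partition is
invariant to invertible linear reparameterizations of either block.
Axis significance uses sequential residual permutation
(`anova_axes()`): for axis $k$, rows of the response residuals beyond the
first $k-1$ canonical axes are permuted and the axis-$k$ eigenvalue
recomputed.

## Genomic offset

Two estimators share one calibration (`fit_allele_env_model()`), applied to
the PAV frequencies:

1. **RONA-RDA.** Stage 1 is the RDA of PAV frequencies on the standardized
   environment. Stage 2 maps each locus's stage-1 linear prediction back to
   the observed frequency through a binomial logistic regression weighted
   by observed allele counts, which bounds every projection inside (0, 1).
   A per-locus GLM replaces a smoothing GAM at this stage: with ~39
   populations per locus there is no support for a data-driven smooth, and
   the GLM provides the same bound guarantee. Future environments are
   standardized with the *current-climate* means and SDs stored at
   calibration, preserving the calibration frame. The offset is
   $\frac1n\sum_i |p_i - p_i^{*}|$ per population
   (`rona_offset()`), where $p^{*}$ is the bounded future prediction.
   Loci fixed across all populations cannot be calibrated; they are flagged
   and their predictions fall back to the observed mean frequency, so they
   contribute (approximately) nothing to the offset.
2. **RDA adaptive index.** Per retained axis, a site's index is the
   biplot-score-weighted sum of its standardized environmental values; the
   offset is the Euclidean distance between current and future index
   vectors (`adaptive_index_offset()`), invariant to axis sign flips.

On the default synthetic panel the two estimators rank populations
concordantly (Spearman > 0.7 under the most severe scenario) and both are
zero when the future equals the present and monotone in scenario severity.
`idw_surface()` projects population offsets onto a grid by inverse-distance
weighting (power 2) on an equirectangular planar projection at the mean
latitude; geodesic distances are available behind a flag, and
`offset_classes()` provides the decile binning used for map display —
raw values remain the canonical output.

## Time to close the gap under selection

`generations_to_shift()` iterates the deterministic one-generation response
of a fully dominant favoured allele,
$$\Delta p = \frac{s\,p\,q^2}{1 - s\,q^2}, \qquad q = 1 - p,$$
until the cumulative gain reaches a target (for example, a RONA offset
value), counting completed generations; a zero target needs zero
generations, and targets with $p_0 + \Delta p > 1$ or beyond the iteration
cap are flagged unreachable rather than raising an error. Drift, gene flow,
effective population size and intermediate dominance are deliberately
excluded: every one of them would lengthen, not shorten, the time, so the
count is a lower bound. `simulate_selection_grid()` sweeps starting
frequencies, selection coefficients and targets, and converts generations
to years at 20 or 25 years per generation (25 for headline figures, the
upper end of a long-lived conifer's generation time). For weak selection
($s \le 0.1$) the discrete count agrees with the continuous-time limit
$T \approx \frac1s\left[\ln\frac{p}{1-p} + \frac1{1-p}\right]_{p_0}^{p_0+\Delta p}$
within 15%, which the test suite verifies.

## The synthetic study generator

`simulate_landscape_panel()` emulates the statistical structure the
analyses assume so the whole pipeline is testable without downloads:

* 39 populations on a north–south transect, 5–23 diploids each with median
  10 (sizes drawn as $5 + \mathrm{Bin}(18, 5/18)$);
* a mean-annual-temperature gradient from −2 to 9 °C, plus seven weakly
  correlated bioclimatic/soil covariates;
* neutral loci under the Balding–Nichols model,
  $p \sim \mathrm{Beta}\big(\pi\frac{1-F}{F}, (1-\pi)\frac{1-F}{F}\big)$
  with ancestral $\pi \sim U(0.05, 0.95)$ and $F = 0.017$ — the simplest
  generative model with a tunable $F_{ST}$, chosen over coalescent
  machinery because desk-scale calibration is the goal;
* ~20 adaptive loci with logistic clines in temperature, slope 0.25
  logit/°C and per-locus half-frequency temperatures drawn from the middle
  half of the gradient — this slope puts the per-locus
  frequency–temperature $R^2$ in the 0.5–0.8 band against ~0.06 for
  neutral loci;
* genotypes drawn at Hardy–Weinberg within populations (so $F_{IS}$ is
  centred at zero), 3% of calls set missing uniformly at random.

An optional `fst_distance_decay` mode makes the neutral deviations
spatially autocorrelated along the transect (exponential decay on the logit
scale), producing isolation-by-distance structure. Note what the default
generator does *not* contain: linkage between loci, demographic history,
selection during sampling, non-equilibrium range edges, or genotyping
error beyond random missingness. Passing tests on these panels therefore
demonstrates the estimators' calibration and power under their own
assumptions, not robustness to everything real data can do.

Under the default exchangeable background there is no *neutral* population
structure at all, so structure-recovery properties (e.g. "removing the PAV
panel leaves PC1 unchanged") are evaluated under the distance-decay mode,
where the neutral background actually carries the structure.

## Problem sizes, tolerances and reproducibility

The test suite runs panels of 39 populations × ~10 diploids with 250–2000
neutral loci, 20-seed replicate loops for power/false-positive properties,
and 99–199 permutations where a permutation p-value is only compared
against a threshold — sizes chosen so each property is measured with
adequate replication while the whole suite stays fast. Key numerical
choices: truncated-likelihood tolerance 1e-8; GLM/IRLS tolerance 1e-10,
100 iterations, with boundary fits flagged unconverged; SVD ranks
truncated at 1e-8 of the leading singular value; permutation p-values use
the add-one convention everywhere. All randomness in the pipeline flows
from the single configured seed, and identical seeds give byte-identical
summary artifacts.

## A worked run

```{r example, eval = FALSE}
library(geaoffset)

cfg <- list(synthetic = list(n_neutral = 2000, n_adaptive = 20), seed = 1)
summary <- run_pipeline(cfg, "pine_run")

summary$global_fst            # ~0.017 background differentiation
summary$outlier_counts        # method-wise and consensus PAV counts
summary$variance_partition    # a / b / c adjusted-R^2 fractions
summary$selection_summary     # generations to close the offset gap
```

## Known limitations

* The F_ST scan's uncorrected statistic retains the binomial sampling
  component; the fitted (df, $\bar F$) absorb it, but panels with very
  uneven sample sizes will fit a blunter null than a per-locus
  sample-size-corrected model would.
* Storey's $\hat\pi_0$ uses the single-threshold estimator; with very few
  loci it is noisy (it is capped at 1).
* dbMEM axes are filtered only by eigenvalue positivity before forward
  selection; Moran's-I-based sub-selection is not implemented.
* The offset calibration assumes the genotype–environment relationship is
  transportable to the future climate (the standard, and strong, genomic
  offset assumption); offsets are exposure proxies, not fitness predictions.
* The selection-time recursion is single-locus and deterministic; it is a
  lower bound by design.
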