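---
title: "Methods: federated Chow tests for genotype-stratified expression-imaging scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated Chow tests for genotype-stratified expression-imaging scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedchow)
```

## The model

`fedchow` asks, for one **trio** — a genotype stratifier, one gene's
expression `y`, one imaging biomarker `x` — whether the linear relationship
between `y` and `x` differs across genotype subgroups. Samples are split into
up to G = 3 subgroups by allele count at a SNP (0/1/2 copies of the
alternate allele) or by a precomputed 3-level class such as APOE status.
Within each subgroup g the model is

$$ y = w_0^{(g)} + w_1^{(g)} x + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2) \; \text{i.i.d.} $$

The null hypothesis is that all subgroups share one coefficient pair. With
residual sums of squares $S^{(g)}$ from the per-group fits, $S^{(C)}$ from
the pooled fit, group sizes $N^{(g)}$ and $k = 2$ parameters, the
generalized Chow statistic

$$ F \;=\; \frac{\bigl(S^{(C)} - \sum_g S^{(g)}\bigr) / \bigl((G-1)k\bigr)}
               {\sum_g S^{(g)} / \bigl(\sum_g N^{(g)} - Gk\bigr)} $$

follows, under the null, an F distribution with $(G-1)k$ and
$\sum_g N^{(g)} - Gk$ degrees of freedom; for three groups that is $2k = 4$
numerator degrees of freedom. For G = 2 the statistic reduces to the classic
two-group structural-break test with numerator df $k$.

Assumptions worth keeping in mind: the within-group relationship is linear;
errors are homoscedastic Gaussian with a *common* variance across subgroups;
and the stratifier is exogenous to the noise. Heteroscedasticity across
subgroups inflates the type-I error of any Chow-type test; the scan reports
per-subgroup Pearson correlations alongside F so that diverging group
variances are visible in the output.

**Why k = 2.** The model carries an intercept. Regional brain volumes and
normalized expression values are not mean-zero quantities, and a
through-the-origin line would confound location differences with slope
differences, so the slope-only alternative was rejected at design time.

## The federated protocol

Cohorts sit at I institutions; the coordinator never sees raw `x` or `y`.
One fit of one subgroup proceeds in three phases:

1. **Moments round.** Each site reports `(n, sum_x, sum_x2, sum_y, sum_y2)`
   for its samples in the subgroup. The coordinator broadcasts the pooled
   mean and variance; every site standardizes its local data against these
   *global* moments. Only count-level aggregates move.
2. **Gradient descent.** From `w = 0`, each site computes its local gradient
   $\nabla S_i(w) = X_i^\top (X_i w - y_i)$ on the standardized data, the
   coordinator sums them and broadcasts the total, and every site applies
   the identical update. The coordinator never holds an updated `w` itself:
   at `w = 0` a site's gradient equals $-X_i^\top y_i$, so a coordinator
   that also knew `w` at every round would have the ingredients to
   reconstruct site data; broadcasting only the summed gradient and letting
   sites update locally avoids that.
3. **Residual round.** After convergence each site evaluates its residual
   sum of squares on the original scale and reports the scalar `S_i` and
   count `N_i`. The coordinator sums these into $S^{(g)}, N^{(g)}$, fits the
   pooled model the same way, and computes F and p from the aggregates
   alone.

The whole transcript therefore contains gradients (length-2 vectors),
five-number moment summaries, residual scalars and counts — never a
per-sample value. `federated_chow(log_transcript = TRUE)` records every
message so this can be audited; the test suite asserts the property on full
scans, and `write_transcript()` serializes the log as newline-delimited JSON.

**Step-size conditioning.** The update applies the learning rate to the
*mean-loss* gradient, `w <- w - eta * grad / N`, with `eta = 0.1` by default
on standardized data. On standardized inputs the mean-loss Hessian has
eigenvalues near 1 regardless of cohort size, so a fixed `eta = 0.1`
contracts the error by roughly 0.9 per iteration for any N and any
partition; applying `eta` to the raw summed gradient would instead diverge
once `eta` exceeds 2/N. Dividing by N uses only the sample count the
coordinator already aggregates, so nothing extra is revealed. Coefficients
and residuals are reported back on the original scale via the affine
back-transformation of the standardization.

**Solver parameters.** Defaults: `learning_rate = 0.1` (per-sample step on
standardized data), `tolerance = 1e-8` (stopping rule on the global
mean-loss gradient norm, checked at the coordinator), `max_iterations =
10000`. Typical convergence is under 200 iterations; hitting the cap flags
the fit (`converged = FALSE`, with the achieved gradient norm) rather than
failing, so a genome scan is never aborted by one ill-conditioned gene.

**Partition invariance.** Because gradients, moments and residual sums are
exact sums over sites, every quantity the coordinator computes is invariant
(to floating-point summation order) under re-partitioning of the same
samples — one institution or seven. The tests assert equality of residuals
across partitions into 1, 3, 5 and 7 sites at relative 1e-6 on a
1,000-sample dataset, and agreement of the final coefficients and residuals
with the centralized closed-form solution.

**Batch scanning.** `scan_genes` fits all genes of a panel under one
partition by aggregating each site's standardized crossproducts
($X_i^\top X_i$, $X_i^\top Y_i$) and running a single gradient-descent loop
on a 2 x n_genes coefficient matrix. Site-summed crossproducts reproduce the
summed per-site gradients exactly at every iteration, so this is the same
protocol executed in batch; a test checks per-gene agreement with
`federated_chow` to 1e-7.

## Degenerate data and numerical choices

- A subgroup with fewer than k + 1 = 3 pooled samples, or with a constant
  biomarker, is unfittable and dropped; the pooled model is then fitted on
  the remaining subgroups' samples so that $\sum_g N^{(g)}$ always matches
  the pooled count. With fewer than two fittable subgroups the trio's p is
  reported as missing (`NA`), not an error, so genome-scale scans proceed.
- The Chow numerator can come out negative by floating-point (or
  federated-solver) residue since gradient descent stops at tolerance, not
  at the exact optimum; F is clamped at 0 (p = 1).
- A constant response within a group is legal (slope 0, zero residual); if
  *all* groups fit exactly, the statistic degenerates and is reported as 0
  or infinity according to whether the pooled fit is also exact.
- Missing p-values are excluded from FDR correction and from top-N
  selection, never imputed.
- All rankings break p-value ties lexicographically by identifier, so
  results are byte-stable across runs; equal enrichment overlaps necessarily
  produce equal enrichment p-values and are ordered the same way.
- Sample alignment across genotype, expression and phenotype inputs is by
  intersection of sample identifiers (the dropped count is messaged);
  results are invariant to input row and column order.

## Enrichment and the tail convention

Gene selections (p < alpha, or top-N by p with deterministic tie-breaks) are
evaluated against a reference list by the hypergeometric model: drawing
N genes from a universe of M containing n reference genes,
`hypergeom_enrichment()` reports the probability attached to the observed
overlap k. Three conventions are exposed because published enrichment tables
are not consistent about which number they print: the strict upper tail
P(X > k) (default, and the recommended p-value), the inclusive tail
P(X >= k), and the point probability P(X = k), which matches the values some
published enrichment tables print. All four counts ride along in the result
object so any convention can be recomputed by the reader. The universe
defaults to the set of scanned genes; gene symbols are matched
case-insensitively with no alias resolution.

## The exact Hardy-Weinberg filter

Genotyping artifacts show up as departures from Hardy-Weinberg proportions
in control samples. `hwe_exact_test()` implements the conditional exact
test: given the observed allele counts, the p-value sums the conditional
probabilities of all heterozygote counts no more probable than the observed
one. `filter_hwe()` applies it to a designated control group and removes
SNPs below a configurable threshold (default 1e-6, a conventional
genome-scan choice; the filter is deliberately permissive because the
downstream test conditions on genotype anyway). The test is exact but
discrete, hence conservative: its null p-value distribution is
super-uniform, noticeably so at small counts. The `midp = TRUE` variant
(half weight on the observed outcome) is closer to uniform and is what the
suite's uniformity property uses, at 2,000 samples per replicate where the
support is dense enough for a Kolmogorov-Smirnov check to be meaningful;
the default remains the strictly conservative form, which is what one wants
in a QC filter.

## The synthetic-data generator

The generator exists so every stage is testable without any cohort data. It
emulates exactly the structure the method assumes:

- biallelic genotypes drawn under Hardy-Weinberg proportions
  (p^2, 2pq, q^2) at a configurable alternate-allele frequency, with
  independent missingness (default 2%);
- a Gaussian biomarker (standard normal by default; the biomarker's
  location/scale are configurable and irrelevant to F by affine invariance);
- expression that, for planted causal (SNP, gene) pairs, follows
  `intercept[g] + slope[g] * biomarker + N(0, noise_sd)` with g the sample's
  genotype group at its causal SNP, while all other genes share one common
  slope. Group intercepts default to equal so detected structure is
  attributable to slopes alone; causal gene-SNP assignments are drawn
  without replacement so the truth table is unambiguous;
- random disjoint partitions of samples across 1-7 hypothetical
  institutions.

Defaults: 1,000 samples (the multi-site stability setting), allele
frequency 0.3, slopes (0.5, 0.5, 3.0) with noise sd 0.2 — a strong,
unambiguous planted effect — 200 genes, 20 SNPs. `simulate_grouped_data()`
and `simulate_scan_panel()` generate the same stratified-slope structure
with *exact* per-group sizes for calibration and power studies, since HWE
sampling cannot fix group counts. All generators are seed-deterministic.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, expression covariance between genes, population stratification,
covariate effects (age, sex), or heteroscedastic noise. Passing tests on
synthetic data therefore demonstrate correctness of the statistics and the
protocol, not robustness to those real-data features.

### Effect-size regimes in the two simulation studies

The planted-gene recovery study uses the strong regime (slopes 0.5/0.5/3.0,
noise 0.2, 100 samples per group, 200 genes): there the planted gene's p
separates from the panel by hundreds of orders of magnitude and recovery is
expected in essentially every seed.

The SNP-ranking study deliberately uses a moderated regime (slopes
0.5/0.5/1.0, noise 0.5). The reason is a genuine statistical phenomenon,
not convenience: a gene whose slope is modulated by its causal SNP carries
that heterogeneity into *every* stratifier's scan, because the finite-sample
correlation between two independent genotype vectors (~ 1/sqrt(n)) induces
group-slope differences of order gap/sqrt(n) against a slope standard error
also of order sigma/sqrt(n). The bleed-through t statistic is therefore
independent of sample size and grows with gap/sigma. In the strong regime it
is around 7: reference genes then top the list of every SNP, the top-N
overlap saturates at N for null SNPs too, enrichment p-values tie, and SNPs
become indistinguishable *by the statistic itself*. In the moderated regime
the bleed-through t is about 0.4 while direct detection remains
overwhelming (t near 9), so only causal SNPs detectably modulate
reference-gene slopes — the situation the ranking experiment is meant to
model. Users planting their own benchmarks should keep this trade-off in
mind.

## Problem sizes used by the test suite

The suite runs at desk scale by design: 1,000 samples for partition
invariance; 2,000 replicates of 300 samples for null calibration (expected
rejection 0.05 within 3 binomial standard errors); 100 seeds of a 200-gene,
300-sample panel for planted-gene recovery; a 20-SNP, 200-gene, 300-sample
dataset for SNP ranking; exhaustive enumeration up to a 50-gene universe and
20 alleles for the distributional oracles. A full scan of a 200-gene panel
takes well under a second, so these sizes leave wide margins while
exercising every code path at genome-shaped proportions.

## Known limitations

- The model is bivariate; no covariate adjustment (the intended upstream
  fix is residualizing the biomarker before the scan, e.g. the ICV division
  provided here).
- Exactly one predictor (k = 2) is supported; the Chow machinery is general
  but the federated solver and IO surface are not plumbed for more columns.
- At most three subgroups, matching the biallelic-genotype and
  three-class-haplotype use cases.
- The privacy contract is the message-content restriction described above;
  there is no differential privacy, secure aggregation, or protection
  against a coordinator that colludes with sites, and multi-site execution
  is simulated in-process (message exchange over files is supported, real
  networking is out of scope).
- Multi-allelic VCF records are skipped by default (or naively split per
  alternate allele); no LD-aware handling.
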