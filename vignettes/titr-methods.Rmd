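---
title: "Tissue-refined polygenic risk scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-refined polygenic risk scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titr)
options(titr.verbose = FALSE)
```

## The problem

Polygenic risk scores (PRS) built from European-ancestry GWAS lose
accuracy when applied to genetically distant populations, because the
tagging SNPs that carry the strongest association signal in the training
ancestry need not be in linkage disequilibrium (LD) with the causal
variants elsewhere.  SNPs with strong *functional regulatory* evidence
are more likely to be causal, hence more portable.  This package
implements a complete workflow around that idea:

1. **Partition heritability.**  For each of a catalogue of tissue-specific
   regulatory annotation tracks, stratified LD score regression (S-LDSC)
   regresses per-SNP GWAS chi-square statistics on annotation-stratified
   LD scores.  The per-standardized-annotation effect size
   $\tau^\ast_C = \tau_C \,\mathrm{sd}(a_C)\, M / h^2$ measures the
   proportional change in per-SNP heritability per standard deviation of
   annotation value.  Tissues with $\tau^\ast > 0$ and
   $p < 0.05/n_\text{tissues}$ (Bonferroni) are candidates.
2. **Calculate scores.**  Annotation tracks are quantile-normalized to a
   common distribution, cut into 1000 percentile bins (0.1% resolution),
   and percentile slices are LD-block-sampled: each LD block (from
   PLINK-style greedy clumping at $r^2 \ge 0.2$) contributes at most one
   SNP, preferring the index variant, otherwise the most significant
   member in the slice.  Allelic scores
   $s_i = \sum_j \hat\beta_j \, g_{ij}$ are computed over a grid of 370
   log-uniform p-value thresholds in $[10^{-5}, 1]$, with missing
   genotypes contributing exactly zero (no mean imputation).
3. **Optimize.**  Every candidate (tissue, threshold) model is compared
   with the current model on the training cohort: a nested-model ANOVA F
   test on the first iteration, the Davidson–MacKinnon J test (the
   challenger's fitted values added to the current design) on later
   iterations.  Among significant candidates, the one with the largest
   gain in adjusted $R^2$ over the covariate null model (age, sex, ten
   principal components, and an independently optimized coding-region
   PRS) wins; its SNPs are merged and only its bin cursor advances.
4. **Validate.**  Each accepted iteration's cumulative SNP set is
   re-scored in a target-population cohort and its adjusted-$R^2$ gain
   over the target null model traced per iteration.

The loop stops when no tissue is significantly enriched, no candidate
adds significant information, bins are exhausted, or an iteration cap is
reached.

## The regression machinery

All models are ordinary least squares, for binary traits too: the
accuracy metric is the gain in adjusted $R^2$ on the observed scale, and
a single linear framework keeps nested and non-nested comparisons
coherent.  Adjusted $R^2$ uses the standard
$1 - (1 - R^2)(n-1)/(n-p-1)$.  Because every candidate differs from a
fixed design by one score column, screening across thresholds reduces to
partial-regression algebra on residualized columns; the test suite
asserts that this fast path reproduces the `lm()`-based `anova_nested()`
and `j_test()` to $10^{-10}$.

S-LDSC details: the regression of $\chi^2_j$ on $N_j\,\ell(j,C)$ has a
free intercept; weights follow a two-step scheme,
$w_j = 1/(\max(\ell_j, 1)\,\hat\chi^4_j)$ with $\hat\chi^2_j$ the
prediction of an initial unweighted pass floored at 1 (its minimum under
the model — unfloored weights blow up on SNPs predicted near zero).
Standard errors are delete-one block jackknives over 200 contiguous SNP
blocks (reduced to $\lfloor M/50\rfloor$ for small panels), applied to
$\tau$ and to the enrichment ratio.  LD scores use plain squared Pearson
correlations within a physical window (default 1000 kb; the simulator
has no genetic map, so no cM window is offered).  Two-sided normal
p-values are attached to $\tau^\ast$; the positivity requirement is a
separate filter.

## What the simulator emulates

`simulate_study()` generates both populations from a block
latent-Gaussian haplotype model: within an LD block, latent variables
follow an AR(1) chain with population-specific correlation (training
0.95, target 0.4 by default), thresholded at per-SNP MAF quantiles
(common SNPs only, MAF in [0.05, 0.5]); a dosage is the sum of two
independent haplotypes.  Blocks are heterogeneous in size — this is what
gives LD scores enough variation to identify the regression slope
against the intercept — mutually independent, and separated by 2 Mb so
no LD window spans two blocks.  SNP metadata are shared across
populations; only LD strength differs.

Three design choices deserve emphasis because they create the
portability phenomenon at desk scale:

* **Clustered causal loci.**  Causal SNPs are placed
  `causal_per_locus` (default 3) to an LD block.  Allelic heterogeneity
  is ubiquitous at real trait loci and is what lets a tagging SNP carry
  more association signal than any single causal variant.
* **Concordant within-locus effects.**  Cluster members share an effect
  direction (the sign is drawn per locus; magnitudes stay
  $N(0, h^2/n_\text{causal})$ on standardized genotypes).  A tag in
  strong LD with the whole series aggregates its signal in the
  training population; in the weak-LD target population that aggregate
  collapses, while a causal SNP ports its own effect in full.  With
  independent single causal variants and desk-scale GWAS power, the
  causal SNP almost always *is* the index variant and standard P+T
  barely attenuates — no portability contrast exists to study.
* **Lehmann-tilted annotations.**  In a causal tissue, a causal SNP's
  score quantile is drawn as $U^{1/\kappa}$ with $\kappa$ calibrated so
  the probability of landing in the top 1% bin equals
  `enrichment`×0.01 (capped when the causal mass exceeds the bin).
  Non-causal tissues score independently of causal status, and marginal
  score shape (Beta(1,4)) is irrelevant after quantile normalization.

The phenotype is genetic value (rescaled to variance $h^2$) plus small
fixed age/sex effects plus Gaussian noise of variance $1-h^2$; binary
traits threshold the liability at the configured prevalence and
subsample controls to a 4:1 control:case design.  GWAS summary
statistics are per-SNP marginal least-squares fits with
$\chi^2 = (\hat\beta/\mathrm{se})^2$ and the matching 1-df p-value.

**What passing tests do not show.**  The generator has no demography,
recombination map, admixture, genotyping error or annotation spatial
smoothness, and its enrichment is far *purer* than real regulatory
scores: with a 20-fold top-percentile enrichment and enough causal loci
for S-LDSC power, several percent of a desk-scale genome is causal and
the top decile of a causal tissue's track is causal-dominated.  One
consequence is documented openly: in these conditions the functional
model outperforms standard P+T in the *training* population as well,
whereas with real (low-purity) annotations standard P+T is reported to
keep the within-ancestry advantage.  The target-population superiority
of functional prioritization — the claim the package exists to study —
is insensitive to this purity artifact.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `block_rho_train` / `block_rho_target` | 0.95 / 0.4 | latent AR(1) LD strength per population |
| `h2` | 0.4 | narrow-sense heritability (variance fraction) |
| `n_causal`, `causal_per_locus` | 400, 3 | causal SNP count and clustering |
| `enrichment` | 20 | multiplier on P(causal SNP in top 1% bin) |
| `n_tissues` | 51 | annotation tracks (2 causal by default) |
| `bin_resolution` | 0.001 | percentile bin width (1000 bins) |
| `clump_r2`, `clump_window_kb` | 0.2, 250 | clumping threshold and window |
| `n_thresholds`, `p_min`, `p_max` | 370, 1e-5, 1 | threshold grid |
| `alpha` | 0.05 | per-iteration selection level (ANOVA / J test) |
| `max_iterations` | 200 | refinement cap |

Numerical choices: ties in quantile normalization take average ranks;
bin and top-fraction boundaries break ties by SNP id so results are
order-independent; clumping ties in p break by position then SNP id;
principal components use an exact SVD for small problems and a
deterministic randomized subspace iteration otherwise, with a
sign convention making the largest-magnitude loading positive; the
coding PRS and every profile treat missing dosages as exact zeros.
Degenerate inputs (constant covariate columns such as an all-zero
coding PRS, empty partitions after block sampling, monomorphic SNPs)
are dropped or skipped with logged counts rather than propagated as
errors.

## A worked run

```{r run, eval = FALSE}
config <- sim_config(seed = 7, n_snps = 6000, n_blocks = 300,
                     n_gwas = 8000, n_train = 5000, n_valid = 1800,
                     n_panel = 500, h2 = 0.4, n_causal = 480,
                     causal_per_locus = 4, n_tissues = 12,
                     causal_tissues = c("tissue01", "tissue02"))
res <- run_portability_study(config,
                             titr_config(max_iterations = 30,
                                         n_jackknife_blocks = 120),
                             keep_objects = TRUE)
round(res$metrics, 3)
plot(res$state)   # per-iteration target-cohort accuracy trace
```

The same conditions (20 replicate seeds) back the package's acceptance
properties; the test suite and `scripts/acceptance.R` state the problem
sizes they use — 6,000 SNPs in 300 blocks, GWAS n = 8,000, training
n = 5,000, target n = 1,800 — which were chosen once, from pilot power
analysis of the candidate-tissue gate, as the smallest study in which
the S-LDSC Bonferroni gate is reliable.

## Known limitations

* Observed-scale $R^2$ throughout; no liability-scale conversion and no
  logistic models for binary traits.
* The candidate tissue set is estimated once (iteration 1) and reused;
  per-iteration refitting on residual SNPs is configurable but
  undocumented territory.
* LD windows are physical (kb), not genetic (cM).
* Effect sizes are used as estimated; no shrinkage or effect-size
  re-scaling is applied to improve transferability further.
* The J test is asymptotic; at very small cohort sizes its per-iteration
  size can drift from `alpha`.
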