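---
title: "Mixed-model association and feature-informed genomic prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model association and feature-informed genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sturgeonGP)
```

## Scope

`sturgeonGP` implements the analysis chain used in aquaculture breeding
studies that combine a dense-SNP genome-wide association scan with genomic
prediction of breeding values: marker quality control, VanRaden genomic
relationships, LD pruning and decay summaries, REML variance components,
a mixed-linear-model (MLM) association scan, candidate-gene windows, and
GBLUP-family prediction with replicated cross-validation. A calibrated
simulator generates genotypes and phenotypes with known architecture so
that every stage is testable without access to proprietary breeding data.

Upstream steps (sequencing, alignment, variant calling, imputation) are out
of scope; the package consumes their output formats (VCF or a dosage
table). Functional enrichment of candidate genes is also out of scope; gene
windows are intersected with a user-supplied GFF3 instead.

## Quality control

Markers are filtered on minor allele frequency (default: remove MAF
strictly below 0.05, keep equality) and then on an exact Hardy-Weinberg
test (default: remove p < 1e-7). MAF is tested first, so the two removal
categories of the `QCReport` are disjoint and sum to the input count. The
HWE test enumerates the conditional distribution of heterozygote counts
given allele counts via a stable ratio recurrence and sums the
probabilities not exceeding that of the observed count; a chi-square
variant is available. With full-sib family structure (as in the simulated
population: 26 families) genotype frequencies genuinely depart from
Hardy-Weinberg proportions, so a few percent of markers failing at 1e-7 is
expected, not a defect.

Missing genotypes are mean-imputed per marker and the imputed fraction
recorded; the imputation happens before frequency computation, which makes
the frequency equal to the mean observed dosage over two. Real studies
typically impute with a dedicated tool beforehand; the built-in rule is a
deliberately simple, auditable fallback.

## Genomic relationships

`build_grm()` uses VanRaden's first method with in-sample allele
frequencies: `G = W W' / (2 * sum p_j (1 - p_j))` with `W` the dosage
matrix centred by `2 p_j`. In-sample frequencies are the default of the
mainstream REML software this emulates. Markers monomorphic in-sample are
excluded from the scaling sum. No leave-one-chromosome-out variant is
provided: the association model deliberately uses one G from all markers,
which mirrors common practice but can shrink very large marker effects
(proximal contamination); this caveat is documented rather than patched.

For genomic-feature BLUP, `partition_feature_grm()` builds a feature matrix
`G_f` and a background matrix `G_r`, each scaled by its own subset's
`2 * sum p(1-p)` (the convention of the genomic-feature BLUP literature).
Because `denom_f * G_f + denom_r * G_r = denom_all * G`, the two-component
model strictly generalises the single-G model.

## REML

`reml_fit()` maximises the restricted likelihood of
`y = X b + sum_i u_i + e`, `u_i ~ N(0, K_i s2_i)`, by average-information
updates with two safeguards:

* an EM fallback whenever the AI step leaves the parameter space or
  decreases the restricted likelihood (the EM step cannot decrease it);
* an active-set rule: components sitting at the lower bound with a negative
  score are pinned while the remaining components move jointly, and a
  clamp-to-bound candidate is evaluated each iteration. EM alone approaches
  a zero component only geometrically; the clamp makes boundary solutions
  (e.g. a null genetic variance) converge in a handful of iterations.

Variances are constrained to at least `1e-6 * var(y)`; convergence is a
restricted log-likelihood change below `1e-6` (both exposed as arguments).
Fixed effects default to an intercept, matching models whose only fixed
effect is the overall mean. The ordinal colour score is analysed as a
continuous variable in all models — a single linear model for every trait —
because that is how such scores are handled in the study design this
package reproduces; a threshold-model extension is a known limitation.
Correctness is tested against a brute-force grid search of the restricted
likelihood on small problems and by parameter recovery on simulated data.

## The association scan

`fit_null()` estimates the polygenic and residual variances once under the
null (no marker term) and caches the spectral decomposition of G. Each
marker is then tested by generalized least squares of `y` on `[1, x]` under
`V = s2_a G + s2_e I` through the cached rotation, with a Wald test of
`b/se` against the standard normal. Keeping the null variances fixed across
markers is the standard MLM-association compromise: it controls relatedness
and stratification at a per-marker cost of one weighted 2x2 solve, and it
yields a single genomic-inflation factor per trait. λ is the median
association chi-square divided by 0.4549, the median of a 1-df chi-square.

Significance classes use 5e-8 (genome-wide) and 5e-6 (suggestive), strict
inequalities, both configurable. Feature selection for prediction uses
Benjamini-Hochberg FDR at q = 0.05 over the scan of the training data only.

## Candidate regions

Significant and suggestive SNPs on one chromosome are merged into a region
when within `merge_gap` of each other (default 40 kb, i.e. two flanks, so
SNPs with touching windows share a region — the merge rule is this
package's own, chosen so that multi-SNP windows behave sensibly). Regions
are extended by a 20 kb flank on both sides, floored at position 1, and
intersected with gene records from a GFF3; overlap is 1-based inclusive on
both boundaries and strand-agnostic.

## Genomic prediction and cross-validation

`gblup_predict()` estimates variance components on the training samples
only, then computes GEBVs for all samples as
`g_hat = s2_g G[, train] V_train^-1 (y_train - mu_hat)`; validation
phenotypes are never read. `gfblup_predict()` does the same with two
components and returns `f_hat + r_hat`. A relative ridge of `1e-6` times
the mean covariance diagonal stabilises the training solve.

`crossvalidate()` implements three strategies over one shared fold plan:

* **gblup** — G from all markers;
* **gldblup** — G from an LD-pruned subset of about `prune_target` markers,
  fixed once for all folds (pruning touches no phenotypes, so there is no
  leakage either way; fixing it once is cheaper and reproducible);
* **gfblup** — the feature set is re-selected *inside every training fold*
  by a reference-only GWAS plus FDR, so no validation information can reach
  the feature choice; the background set is the pruned subset minus the
  features. A fold whose training scan yields no FDR-significant marker
  falls back to GBLUP on the background matrix and the event is counted.

Variance components are re-estimated within every training fold (a
conservative reading of "the reference population predicts the validation
population"). Folds partition the samples exactly once per replicate with
sizes differing by at most one; for 673 samples and k = 10 the sizes are
67 and 68. The replicate-level metric is the mean over the k folds, and the
report aggregates means and SDs over replicates; per-fold values are kept.

Metrics: accuracy is Pearson r(y, GEBV) on the validation samples;
dispersion bias is |1 - b| with b the slope of y regressed on GEBV (1 means
correctly scaled predictions); MSE and MAE are computed after mean-centring
both vectors, so they measure dispersion mismatch rather than location.

## The simulator

`simulate_genotypes()` draws haplotypes from a latent Gaussian process
along each chromosome and thresholds it at each marker's allele-frequency
quantile; two independent haplotypes are summed per individual. A
coalescent simulator would be more realistic but is deliberately avoided:
the Gaussian-copula engine is fast, dependency-free, and directly
calibratable to a target LD decay.

The target decay is `r^2(d) = r2_adjacent * exp(-d / L)`. The latent
correlation needed for a given *genotype* correlation depends on both
allele frequencies, so the inverse calibration is tabulated by quadrature
of the bivariate normal orthant probability on a 0.05 frequency grid
(memoised) and applied per adjacent pair on the minor-allele scale, with
the major/minor coding carried as a sign into the latent chain. Population
genetics bounds r^2 for frequency-mismatched pairs; the simulator clamps at
the attainable correlation rather than distorting frequencies, so panels
with a wide MAF spectrum realise somewhat less adjacent LD than a
frequency-matched target would suggest.

Defaults emulate the study population this package was built around: 673
individuals, MAF >= 0.05, and `r2_adjacent = 0.25` with `L = 20000/ln 5 ≈
12.4 kb`, which places the `r^2 = 0.05` crossing at 20 kb. The study's two
published LD summaries (mean adjacent-pair r^2 of 0.049 at ~10-million-SNP
density, and decay to 0.05 at 20 kb) cannot both hold at a 5,000-marker
desk scale — mean adjacent r^2 rises as marker spacing shrinks — so the
defaults are calibrated to the decay point, which is the quantity the
candidate-gene windows depend on. Family mode recombines founder
haplotypes (about one crossover per chromosome) within full-sib families,
reproducing the block relatedness of a hatchery design.

`simulate_phenotypes()` samples QTLs without replacement, draws standard
normal effects, and rescales genetic values and residuals — residualising
the noise against the genetic values in-sample — so that the realised
in-sample heritability equals the target exactly. This gives recovery tests
an exact target instead of an expectation. Ordinal traits cut the liability
at the quantiles implied by the category probabilities; the sturgeon
preset uses probabilities (0.10, 0.45, 0.35, 0.10), giving a 1-4 score with
mean near 2.45. No fixed effects beyond the overall mean are simulated,
matching models that contain only μ.

What passing simulation tests does *not* show: robustness to genotyping
error, imputation artefacts, selection, non-additive architecture, or
environmental covariates — none of which the generator emulates.

## Numerical choices and degenerate inputs

* GRM inversion inside solvers adds the relative ridge `1e-6`; GRM
  construction itself does not.
* `prune_to_target()` bisects the pruning threshold (18 iterations) and
  falls back to uniform physical thinning when even a near-zero threshold
  leaves too many markers (mutually independent markers); it stops within
  ±2% of the target.
* Pairwise r^2 on dosages is undefined for monomorphic markers: an error in
  `pairwise_r2()`, a skip-with-count in the scan.
* Pruning tie-breaks: of a violating pair, the lower-MAF marker is removed;
  at equal MAF the later-positioned one. Deterministic given input order.
* Constant GEBVs make accuracy and bias undefined; `evaluate_prediction()`
  flags the fold instead of erroring, so one degenerate fold cannot abort a
  replicate.
* All randomness flows from one root seed through named substreams
  (`substream_seed`), so adding a stage never reshuffles another stage's
  draws, and identical configurations reproduce byte-identical tables.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` run the full chain on the simulated
673-fish population (5,000 markers) with 10-fold cross-validation and three
replicates; the package's acceptance checks use n = 800 (heritability
recovery, 10 seeds), n = 400 (scan calibration under a polygenic null, 10
seeds) and n = 500 with k = 5 and five replicates (the three-method
comparison with 10 planted QTLs). These sizes were chosen so the whole
suite runs comfortably on a laptop while leaving each statistical claim
testable; the full published design (10-fold, 20 replicates) is a parameter
change, not a code change.

## Known limitations

* Ordinal traits are modelled linearly; no threshold/probit model.
* No covariates in the scan (age, tank, sex) — the design this reproduces
  fits only μ; the REML layer accepts a fixed-effect design matrix, so the
  extension is mechanical.
* No leave-one-chromosome-out G; large-effect loci can be partially
  absorbed by the polygenic term.
* The simulator's LD is Markovian along the chromosome: long-range
  admixture LD and structural-variant LD are not represented.
* Single-trait models only; no multi-trait REML or Bayesian alphabet.
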