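---
title: "Metabolic marker-assisted genomic prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic marker-assisted genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hybrid breeding programs must pick a handful of crosses from tens of
thousands of possible parent combinations. Genomic prediction (GP) ranks
untested crosses from genome-wide markers of the parents, but genome-wide
SNPs do not capture everything between genotype and phenotype. Parental
metabolite levels sit downstream of the genome and can carry additional,
partly non-genetic, trait-relevant signal. `mmgp` implements a workflow
that (i) screens the parental metabolome for trait-associated metabolites
("metabolic markers") with a metabolome-wide association scan (MWAS),
(ii) codes hybrid-level metabolite features from the two parents, and
(iii) combines genome and metabolic markers in a multi-kernel mixed model
(or a gradient-boosted tree ensemble) to predict hybrid phenotypes.

Five model configurations are compared throughout: `GP` (genome only),
`MP` (full metabolome), `MMP` (selected markers only), `M_GP` (genome +
full metabolome) and `MM_GP` (genome + selected markers).

## The mixed model

For hybrids with phenotypes $y$ the kernel engine fits

$$ y = X\beta + Z_G\gamma_G + A_M\gamma_{Ma} + D_M\gamma_{Md} +
\varepsilon $$

where $Z_G$ holds hybrid genotype codes inferred as parental midpoints
(inbred parents coded $-1/+1$, so heterozygous hybrids land on 0), and
the metabolite codings are built from the female ($M$) and male ($F$)
parental metabolite matrices as $A_M = \tfrac12(M+F)$ and
$D_M = \tfrac12|M-F|$. Both codings are symmetric in the parents, so a
reciprocal cross shares the same feature row. Random effects are
Gaussian with variances $\phi^2_G/g$, $\phi^2_{Ma}/m$, $\phi^2_{Md}/m$
per coefficient, giving

$$ \mathrm{var}(y) = \tfrac1g Z_GZ_G'\,\phi^2_G +
\tfrac1m A_MA_M'\,\phi^2_{Ma} + \tfrac1m D_MD_M'\,\phi^2_{Md} +
I\sigma^2_\varepsilon. $$

Kernels are deliberately *not* trace-normalized: the $1/g$, $1/m$
scaling above is kept as stated. Fixed effects default to an intercept.

**REML.** Variance components maximize the restricted log-likelihood
with a bounded quasi-Newton search (L-BFGS-B) on log-variances using
analytic gradients; single-kernel models use an exact spectral
reparameterization (one eigendecomposition, then $O(n)$ likelihood
evaluations). Convergence is declared at a relative likelihood change
below $10^{-8}$ (at most 500 iterations); components that end at the
lower bound ($10^{-10}\times$ the phenotypic variance) are reported as 0
with a boundary flag. A failed Cholesky adds a single jitter of
$10^{-8}\times$ the mean diagonal. Untested hybrids are predicted from
the partitioned joint Gaussian,
$\hat y_2 = X_2\hat\beta + (\sum_k \hat\phi^2_k K_{21,k})
V_{11}^{-1}(y_1 - X_1\hat\beta)$, with the training factorization reused
across all crosses so a full diallel (20k+ crosses) ranks in seconds.

**Identifiability caveat.** The dominance metabolite kernel
$\tfrac1m D_MD_M'$ has non-centered features: as $m$ grows it approaches
a constant matrix plus a multiple of the identity, both of which are
absorbed by the intercept and the residual. $\phi^2_{Md}$ is therefore
weakly identified in panels where most hybrids are unrelated. The
variance-component recovery test accordingly uses a *dense* partial
diallel (40 parents, 300 hybrids, 30 metabolites) in which shared
parents give the dominance kernel exploitable structure; in the sparse
default world the same estimator shows large sampling spread on
$\phi^2_{Md}$ — a property of the design, not of the optimizer, which is
pinned separately by a closed-form balanced-ANOVA check, a brute-force
likelihood grid, and an independent EM-REML.

## MWAS: first-entry lasso p-values

The scan regresses a parental-line trait (never hybrid phenotypes) on
all metabolites along the full lasso path, both standardized to zero
mean and unit population variance. The statistic for each metabolite is
the largest penalty $\lambda$ at which its coefficient first becomes
nonzero; on the standardized scale this is the correlation between the
metabolite and the model residual at the moment of entry. The path is
computed by glmnet on a 100-point grid down to $0.02\,\lambda_{max}$,
with the entry point refined as the geometric mean of the bracketing
grid values.

Turning $\lambda_{entry}$ into a p-value requires the null distribution
of the first-entry statistic for a trait-independent predictor. A pure
marginal-correlation null (the Pearson null with $n-2$ degrees of
freedom) is exact for the first entrant but badly mis-calibrated for
late entrants: under a permuted trait a null predictor re-enters the
path almost surely near its bottom, a saturation no marginal null can
reproduce (we measured Kolmogorov–Smirnov distances near 0.29 against
the permutation oracle). The default `analytic` backend therefore uses
the *competition null*: the p-value of a metabolite is the rank of its
entry $\lambda$ among all $m$ predictors' entry values,
$p = (1 + \#\{\lambda_{j'} \ge \lambda_j\})/(m+1)$, which is exactly
uniform under a global null and reproduces the permutation saturation;
below the rank resolution $1/(m+1)$ it switches to the Pearson tail of
the entry correlation, restoring continuous deep-tail p-values for
strong signals. Measured against the trait-permutation oracle
(n = 200, 200 null metabolites) this hybrid attains KS $D < 0.08$, a
null type-I error of ≈ 0.045 at $\alpha = 0.05$, and power 0.8 at a
planted marginal $r^2$ of 0.05. Both alternatives remain available:
`method = "pearson"` (closed form only) and `method = "permutation"`
(B trait permutations; the ground-truth backend). The competition null
assumes $m$ is reasonably large (tens or more); for very small panels
use the Pearson or permutation backend.

Markers are declared significant at raw $p < 0.05$ (strict inequality,
no multiplicity correction — the screen feeds a predictive model, not a
discovery list; a smaller $\alpha$ is one argument away). Per-marker
explained variance is reported as the marginal squared correlation.

## Cross-validated evaluation

Predictive ability is the determination coefficient — the squared
Pearson correlation between observed and predicted phenotypes. Each
repeat of 10-fold cross-validation predicts every hybrid exactly once;
the per-repeat ability is computed on those pooled out-of-fold
predictions, and the final figure averages 20 repeats (fold-level
abilities are retained for diagnostics). Pooling matters: fold-level
$r^2$ on ~20-hybrid folds carries an intercept artifact of order
$1/(\text{fold size})$, which would swamp a null signal.

Fold partitions derive deterministically from (seed, repeat). Marker
selection for `MMP`/`MM_GP` defaults to the strict protocol: the MWAS
is re-run inside every training fold using only the parents of
training-fold hybrids, so no choice made by the pipeline ever sees a
test-fold hybrid (a canary test perturbs test-fold phenotypes and
verifies bitwise-identical predictions). Because the scan uses parental
phenotypes, a `global` once-per-dataset selection — the apparent design
of the original study — is also supported, as is a `fixed` list, which
powers the random-metabolite control: matched-size random draws re-run
through the identical CV to show the markers' contribution is not
explained by their count.

Model comparisons use paired two-sided t-tests on repeat-level
abilities (folds within a repeat are dependent; repeats are the
exchangeable unit) with a compact-letter display at $\alpha = 0.05$.

## Boosted-tree engine

The alternative engine fits the concatenated feature vector
$[Z_G\,|\,A_M\,|\,D_M]$ with gradient-boosted regression trees under
squared loss: each tree fits the current residuals by exact greedy
search, leaf values carry an L2 penalty
($w = \sum r_i/(n_{leaf} + \lambda)$), and rows/columns are subsampled
per round. Because the pre-installed R stack has no xgboost, the
learner is implemented in compiled code inside the package with the
same regularization semantics; fits are bitwise reproducible from the
seed. Hyperparameters (learning rate, depth, rounds, subsampling,
minimum child size, $\lambda$) are tuned by a tree-structured Parzen
estimator over inner-CV RMSE — the standard dimension-wise TPE with a
good/bad split at $\gamma = 0.25$, kernel-density models, and candidate
scoring by density ratio. The search space is a documented default and
fully overridable; tuning nests inside each outer training fold when
enabled to avoid leakage.

## The synthetic world

The generator emulates the statistical structure the method assumes,
not any real crop: 150 fully inbred parents (the parent:hybrid
proportion of the published maize panel at our 300-hybrid scale), 1000
SNPs with allele frequencies U(0.1, 0.9), 200 metabolites measured in
two replicates with technical noise (SD 0.3 of the line-level signal),
half of them genetically controlled (5 QTL each, line-level
heritability 0.6), and a trait with $h^2 = 0.6$ whose genetic variance
splits 50/15/35 among additive SNP effects, dominance
(heterozygosity-coded), and ten causal metabolites acting through the
$A_M/D_M$ codings — half of those causal metabolites drawn from the
non-genetic pool, so part of the metabolite signal is invisible to the
SNP kernel by construction. That last choice is what makes the central
qualitative claim *testable*: with it, `MM_GP` must beat `GP` on
simulated truth, and matched random metabolite draws must lag the
MWAS-selected markers.

What a green test does establish: the estimators, codings, selection
logic and CV protocol do what they claim on data with known truth.
What it does not: anything about real maize or rice — the generator has
no linkage disequilibrium, no population structure, no batch effects,
no metabolite annotation structure, and its intensity distributions are
Gaussian rather than the heavy-tailed intensities of real LC–MS data.
Published real-data predictive abilities are not reproducible here
because the underlying datasets are not deposited with accessions.

## Numerical choices and degenerate inputs

* SNP QC uses strict inequalities (MAF `< 0.05` or missing rate
  `> 0.1` removed), so boundary markers are kept; residual missing
  genotypes are mean-imputed per marker.
* Metabolite normalization is a per-metabolite z-score with the
  population (n-denominator) variance; `log-zscore` (log1p first) is
  available for skewed intensities. Constant metabolites normalize to
  zero with a warning. CVs are computed on raw replicate-averaged
  intensities with the sample (n−1) SD.
* Replicate concordance uses a paired two-sided t-test across lines;
  identical replicates give p = 1 (kept), a pure systematic offset
  gives p = 0 (removed).
* Constant traits, constant metabolites, all-missing markers, empty
  marker selections and rank-deficient fixed-effect designs all raise
  immediate, specific errors rather than propagating NaNs.
* Selection gains are reported against two baselines (population mean
  and bottom-k mean) because percent gains are baseline-sensitive; the
  uncertainty attached to a top-k mean is the SD of the top-k predicted
  values.

## Known limitations

Single-trait models only; no genotype-by-environment terms; no sparse
or low-rank kernel algebra (n is assumed to be at most a few thousand);
the boosted engine is exact-greedy and single-threaded, so very wide
feature sets (>10⁴ columns) are slow with large round counts; and the
competition-null MWAS p-values are slightly conservative (type-I ≈
0.045 at 0.05), which costs a little power near the threshold.
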