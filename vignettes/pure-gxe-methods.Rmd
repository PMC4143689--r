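---
title: "Detecting pure gene-environment interactions: models and methods"
author: "puregxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pure gene-environment interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puregxe)
```

## The problem

A SNP can influence a quantitative trait jointly with an environmental
covariate while showing little or no marginal association with it. Standard
single-marker scans miss such loci, and regression models that include a
`G + E + G:E` term report an interaction coefficient whose evidence is
entangled with the main-effect fit. `puregxe` addresses the narrower,
cleaner question: *after the main effects of the genotype and of the
environment have been removed as aggressively as possible, is there any
joint structure left?* Whatever survives that removal is, by construction,
a pure interaction (plus noise).

The package works on unrelated individuals, biallelic SNPs coded as
additive alt-allele counts 0/1/2, quantitative traits (blood pressure in
mmHg is the motivating case), and environments that are binary (smoking,
medication use) or continuous (age in years).

## Step 1: main-effect removal by residualization

The main-effect surface is modelled additively with projection pursuit
regression ridge terms,

$$ y = \sum_{m=1}^{M} S_{\alpha_m}(\alpha_m \cdot x) + \epsilon, $$

where each $S_{\alpha_m}$ is a one-dimensional smooth of a linear
projection of the predictors. Because the smooths are nonparametric, both
linear and nonlinear main effects are removed. `residualize_stepwise()`
residualizes the trait on the environment first and then on the genotype —
never on their joint levels — and then backfits the two single-predictor
smooths (alternating re-fits on partial residuals) until the additive
surface converges.

The backfitting matters. A single pass (remove $E$, then remove $G$ from
the result) leaves a residual whose genotype-level means are zero but whose
environment-level means are perturbed again whenever $E$ and $G$ are
correlated in the sample, as they always are at finite $n$. Alternating the
two fits is the standard additive-model solution; for discrete predictors
it converges geometrically to the projection orthogonal to both level
spaces, so the residual has zero mean within every environment level *and*
every genotype level (the test suite asserts this to 1e-10). A pure
interaction term — one with vanishing marginal means in both variables — is
orthogonal to both level spaces and passes through unchanged; the test
suite checks that too.

Smoother choices:

* **Discrete predictors** (binary E, 0/1/2 genotypes): the fitted smooth is
  the per-level response mean. This is exact, deterministic, and removes
  the main effect completely — no tuning parameter.
* **Continuous predictors** (age): Friedman's supersmoother (default) or a
  GCV smoothing spline, fitted via `stats::ppr`, the reference
  implementation of projection pursuit regression. With a single predictor
  the projection direction is trivially fixed and the fit reduces to 1-D
  smoothing. The package deliberately wraps `stats::ppr` rather than
  re-deriving the Friedman–Stuetzle algorithm: it is the canonical, widely
  exercised implementation, and an independent grid-search oracle
  (directions enumerated on the unit circle, running-mean smoother) guards
  its behaviour in the test suite.

Degenerate inputs are absorbed, not raised: a constant trait yields an
all-zero residual; a monomorphic genotype yields a centered residual
flagged `no-genotype-variation`; a constant environment reduces to grand-
mean centering. Backfitting stops when the largest within-level residual
mean falls below 1e-12 (discrete) or the relative change in residual sum of
squares falls below 1e-8 (continuous), with iteration caps of 100 and 10
respectively; the continuous cap is lower because each iteration refits a
smoother, and in practice the fit stabilizes in two or three passes.

Step 1 uses the *continuous* age, not its dichotomized version: removing
the smooth age trend is the more aggressive removal, and the dichotomy is
needed only where a partition is (Step 2). This is a deliberate choice; the
alternative (residualizing on the binary age indicator) would leave
within-stratum age trends in the residual for the interaction score to pick
up spuriously.

## Step 2: the partition-based influence measure

For one SNP and one binary (or dichotomized) environment, each sample falls
into one of at most $3 \times 2 = 6$ cells. The influence measure on a
response $Y$ (here, the Step-1 residual) is

$$ I = \frac{1}{n} \sum_i n_i^2 (\bar{Y}_i - \bar{Y})^2 , $$

summing over non-empty cells $i$ with size $n_i$ and local mean
$\bar{Y}_i$. Cell-mean deviations are weighted by $n_i^2$, which rewards
consistent displacement of well-populated cells; the statistic is powerful
for joint effects even when both marginals are weak. Empty cells contribute
zero — the measure is well defined without any cell-merging rule.

Responses are standardized to unit variance by default, which makes $I$
scale-free. Under the null of no association, the expected standardized
score for a partition with cell shares $p_i$ is close to
$1 - \sum_i p_i^2$, approaching 1 as cells multiply; this is the "expected
I-score is 1" reference level quoted for many-cell partitions, and the
acceptance suite verifies it by Monte Carlo on a 27-cell partition
(n = 1000, 500 replicates, mean within 5% of 1). A zero-variance response
scores 0 by convention.

### Permutation significance

`permutation_p()` shuffles the response over samples with the partition
fixed and uses the add-one estimator
$p = (1 + \#\{I_{perm} \ge I_{obs}\})/(1 + B)$, so $p$ is never exactly
zero and ties count conservatively. Cell sizes are invariant under the
shuffle, so each permutation costs one grouped-sum pass; permutations are
processed in fixed-size chunks, which keeps memory constant for budgets up
to the $10^7$ used in reference analyses.

For the two-step scan a subtlety arises: the observed residual is
orthogonal to the genotype and environment margins *by construction*, while
a plain shuffle of it is not. Scoring raw shuffles against the constrained
observed statistic makes the null stochastically too large and the test
severely conservative (empirical rejection near zero). Instead,
`permutation_p_centered()` re-projects every shuffled copy onto the
margin-orthogonal space — the same alternating per-level mean sweeps that
Step 1 applies — before scoring, in the spirit of Freedman–Lane residual
permutation. Observed and permuted statistics then obey identical
constraints and only the interaction contrast is compared; the test suite
confirms empirical rejection at 0.05 lies in [0.03, 0.07] on fully null
scans. The exact alternative — permuting the raw phenotype and re-running
Step 1 per permutation — is available via
`scan_pure_gxe(refit_permutations = TRUE)` at roughly `n_perm`-fold cost.

## Dichotomizing a continuous environment

`two_means_dichotomize()` performs one-dimensional 2-means clustering
*exactly*: the optimal 2-clustering in 1-D is a split of the sorted values,
so the within-cluster sum of squares is evaluated at every breakpoint
between distinct consecutive values (prefix sums make this O(n log n) in
the sort) and the minimizer taken. No random initialization, no seed, no
local optima; ties between equal-WSS splits break toward the lower cutoff.
The reported cutoff is the largest value of the lower cluster, so the
labelling rule is `value > cutoff -> 1` — with an age cutoff of 55 years,
ages over 55 are coded 1. A property test verifies the exact split is never
beaten by Lloyd's algorithm started from any breakpoint.

## Scans and the subgroup overlap analysis

`scan_pure_gxe()` runs Steps 1–2 for every SNP: pairwise deletion of
missing genotypes, residualization, genotype-by-environment partition,
I-score, centered permutation p-value. SNPs with fewer than
`min_cell_total` (default 20) usable samples or a single observed genotype
level are flagged and skipped rather than scored. Rows keep the input SNP
order with rank as an annotation, so output joins back to the VCF
deterministically; each SNP draws its permutations from a sub-seed derived
by counter from the scan seed, so results are independent of scan order.

`scan_g_only()` scores the (standardized) trait on the genotype-only
partition within a sample subgroup — an age stratum, say — and reports the
all-sample score alongside, the side-by-side layout used to ask whether
genetic association is uniform across age. `tally_significance()` counts
SNPs below nested p-value thresholds.

`compare_subgroups()` quantifies how surprising disjoint top lists from two
strata would be if both strata shared one set of $T$ truly associated
SNPs:

1. the implied FDR at the $k$-th ranked permutation p-value inverts the
   Benjamini–Hochberg inequality $p_k \le (k/m)q^*$ to
   $\hat q = p_k m / k$ (capped at 1);
2. the expected true positives are $(1-\hat q) \cdot k$, rounded half away
   from zero;
3. the probability that the two true-positive sets share nothing is the
   hypergeometric $\binom{T-t_1}{t_2} / \binom{T}{t_2}$, evaluated through
   log-gamma so large $T$ cannot overflow, zero by pigeonhole when
   $t_1 + t_2 > T$.

$T$ is a user assumption, not an estimate; sensitivity to it should be
reported (it enters steeply — the probability is non-decreasing in $T$).
The "first overlap" between two rankings is defined by scanning the joint
rank frontier: the smallest $r$ such that the top-$r$ lists intersect,
reported as the shared SNP's rank pair. This convention is ours; rank pairs
are not self-defining and other scan orders would give other pairs.

## The synthetic cohort generator

`simulate_cohort()` emulates the shape of a small unrelated-subject
blood-pressure GWAS so that every stage of the pipeline is testable without
external data. Defaults (all configurable via `sim_config()`):

* **n = 130** unrelated samples, 200 SNPs — the scale of an unrelated-
  subject subset of a family study, deliberately small;
* **genotypes**: per-SNP MAF uniform on (0.05, 0.5), Hardy–Weinberg
  proportions, no linkage disequilibrium;
* **age**: two-component normal mixture, means 42 and 65 years, sds 8,
  younger-component weight 0.58 — bimodal enough that the two-means cut
  lands near the component boundary (mid-50s), mimicking a cohort with
  distinct younger and older strata of roughly 58/42 split;
* **binary exposures**: smoking prevalence 0.25, medication 0.30;
* **trait**: intercept 120 mmHg, age slope 0.5 mmHg/year, smoking +4,
  medication −5, Gaussian noise sd 10 mmHg.

Causal genetic effects come in three kinds. A *main* effect adds
$\beta g$. A *pure interaction* adds
$\beta(g - E[g])(z - E[z])$ with $z$ the old-age indicator and both
expectations taken under the population model ($2 \cdot$MAF and the
mixture tail probability above the age threshold), so the marginal
association with $g$ and with $z$ vanishes in expectation — sample
marginals are only near zero, and tests use tolerance bands accordingly. A
*regime-switch* effect adds $\beta g$ only within one age stratum,
the mechanism that produces disjoint top-SNP lists between age subgroups.

`study_config()` freezes three reference designs. The pure-interaction
design plants one G×age SNP at $\beta = 25$ mmHg per allele-by-stratum
unit — calibrated once by an oracle power simulation so that the planted
SNP reaches the top 5 of 200 in roughly 90% of cohorts at n = 130 (the
power grid ran 10/15/20/25/30 → 0.50/0.65/0.80/0.90/0.95) — plus one
main-effect-only SNP at 6 mmHg/allele (about 13% of trait variance) as the
suppression control. The regime-switch design plants ten young-active and
ten old-active SNPs at 15 mmHg/allele. These effect sizes are large by
GWAS standards; that is the price of an n = 130 design, and the generator
should be read as a method-validation rig, not an effect-size prior.

What the generator does *not* emulate: linkage disequilibrium (each SNP is
independent, so "top-5 rank" is cleaner than it would be in real data where
associated SNPs arrive in LD blocks), pedigree structure, longitudinal
measurements, genotyping error, population stratification, and
non-Gaussian trait noise. Passing tests therefore demonstrate correctness
of the machinery and qualitative reproduction of the method's behaviour,
not field performance on real cohorts.

## Statistical checks, and how they are framed

Two checks deserve a note on framing, because naive readings of them would
be miscalibrated:

* *Main-effect suppression.* A fully suppressed main-effect SNP behaves
  exactly like a null SNP, so its score exceeds a null 95% band in about 1
  replicate in 20 by construction; demanding it "never" exceed the band
  would fail correct implementations most of the time. The test therefore
  bounds the exceedance count binomially: at most 3 of 20 replicates
  (P(X > 3) ≈ 0.016 under Bin(20, 0.05)).
* *Subgroup versus overall scores.* An old-regime effect is active in ~41%
  of all samples, so the all-sample I-score of a causal SNP is itself
  somewhat elevated (diluted slope, but 2.4× the sample size), and per-SNP
  exceedance of the subgroup score over the overall score is noisy at
  n = 130. The check asserts the aggregate pattern: disjoint top-10 lists
  between strata, mean top-10 subgroup score at least 1.5× the same SNPs'
  overall scores, and a majority of rows individually exceeding.

Problem sizes used by the test and acceptance suites — 200 SNPs, 2000
permutations, 500 Monte-Carlo replicates, 20 recovery replicates — were
chosen as the smallest designs at which the bands above are statistically
meaningful; all seeds are fixed in the test code.

## Known limitations

* The I-score partition limits each test to one SNP and one binary
  environment (≤ 6 cells); joint G×G or multi-environment partitions are
  out of scope.
* Fixed-fit (centered) permutation is a conditional approximation; the
  exact refit mode is provided but costly.
* Per-SNP missing genotypes are deleted pairwise within each test, which
  assumes missingness unrelated to trait and environment.
* The overlap analysis treats the selected counts and $T$ as known;
  no uncertainty is propagated through the FDR estimate, mirroring its
  back-of-envelope character.
* At n = 130, two-means age cutoffs and subgroup rankings are themselves
  noisy; the package reports them deterministically but stability across
  cohorts should not be assumed.
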