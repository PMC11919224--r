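---
title: "Methods: familial versus population polygenic risk with famprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial versus population polygenic risk with famprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprs)
```

## The question and the design

Families with several cases of a complex disease such as multiple
sclerosis are rare. One candidate explanation is that such families carry
an unusually heavy burden of the common risk alleles found by GWAS. The
analysis famprs implements asks that question directly: build a weighted
polygenic risk score (wPRS) from published GWAS effect sizes, score a
large population case-control cohort and a handful of multicase families
on the *same* harmonized variant panel, and compare the familial groups
(cases and unaffected relatives separately) against population cases and
controls.

The per-individual score is

$$\mathrm{wPRS} = \sum_{i=1}^{n} G_i W_i,$$

where $G_i \in [0, 2]$ is the individual's dosage of the risk allele at
panel variant $i$ (fractional for imputed genotypes) and
$W_i = \ln(\mathrm{OR}_i)$ is that variant's log odds ratio. Three
comparison engines then operate on the score tables:

1. **Welch tests and ROC/AUC** for the population case-control contrast.
2. **Iterative subsampling**: the familial groups number ~10 people
   against thousands of cohort members, so the cohort is repeatedly
   subsampled (default 100 draws of 500, without replacement within a
   draw, independent across draws) and each subsample is Welch-tested
   against the full familial vector; the minimum and maximum p-value
   across draws summarise the comparison.
3. **A kinship-aware linear mixed model**: relatives are not independent,
   so the pooled, rank-based inverse-normal-transformed score is modelled
   as $y = X\beta + g + e$ with $\mathrm{cov}(g) = \sigma_g^2 \Phi_2$
   (twice the pedigree kinship matrix) and
   $\mathrm{cov}(e) = \sigma_e^2 I$, with a group indicator and sex as
   fixed effects. Because the trait is inverse-normalised, the group
   coefficient is read in standard-deviation units.

## Panel harmonization

Risk panels come from summary statistics; genotypes come from arrays and
imputation. `build_panel()` intersects the summary variants with those
available in *both* genotyped datasets, removes strand-ambiguous SNPs
(A/T and C/G pairs, whose orientation cannot be inferred from alleles),
and checks that each remaining variant's alleles can be reconciled with
each dataset directly, after swapping, or after reverse complementing
(`harmonize_variant()`). Variants reported with OR < 1 are flipped to the
other allele with the OR inverted, so every panel weight is
$\ln(\mathrm{OR}) \ge 0$; dosages are complemented accordingly at scoring
time, which leaves the score's ordering of individuals unchanged. HLA
alleles enter as biallelic presence/absence pseudo-markers (alleles
`P`/`A`) that bypass nucleotide strand logic, since an imputed classical
allele contributes to the score exactly like a SNP. Every exclusion is
counted in the panel's provenance attribute so that the final panel size
is auditable against the inputs.

Missing genotypes are carried explicitly (`NA`, never silently zero) and
resolved only at scoring time. The default policy sums over observed
variants and reports `n_variants_used` per individual; an optional
mean-imputation policy substitutes the Hardy–Weinberg expectation
$2f_i$ when allele frequencies are supplied. The default is the
least-assumption option; users can filter on `n_variants_used`.

## Kinship and the mixed model

`kinship_matrix()` implements the standard recursion in founders-first
order: $\phi(i,i) = \tfrac12(1 + \phi(f_i, m_i))$ and
$\phi(i,j) = \tfrac12(\phi(f_i, j) + \phi(m_i, j))$, with founders
mutually unrelated. Monozygotic co-twins are genetically identical:
$\phi(\mathrm{twin}_a, \mathrm{twin}_b) = \phi(a,a)$, applied before any
twin descendant is processed so it propagates. Inbreeding is handled by
the recursion itself (the diagonal exceeds 0.5). The implementation is
validated in the test suite against textbook coefficients and against an
independent gene-dropping Monte Carlo oracle (founder alleles uniquely
labelled, Mendelian transmission simulated, identity-by-descent counted).

`fit_polygenic_model()` fits the variance-component model by maximum
likelihood. The relationship matrix is eigendecomposed once; in the
rotated basis the covariance is diagonal in the heritability ratio
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$, so the profile likelihood
is a smooth one-dimensional function of $h^2$ optimised over $[0, 1)$
with a closed-form GLS solve at each evaluation; the $h^2 = 0$ boundary
is always evaluated explicitly and the model therefore never falls below
the OLS likelihood. ML (not REML) is used because the group effect is
tested by a likelihood ratio between nested fixed-effect models
($\chi^2_1$); a Wald test from the profiled information is reported
alongside. No half-chi-square boundary mixture is applied to the
fixed-effect test: the boundary constraint affects the variance
component, not $\beta$. Population members enter the relationship matrix
as an identity block.

The inverse normal transform uses the Blom offset: the value at rank $r$
maps to $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, ties sharing average
ranks. Blom is the common default in genetics software; no particular
variant was mandated by the analysis this package reproduces.

## The synthetic study

Because the original cohort and family genotypes are not public, famprs
ships a generator that reproduces the *statistical structure* the
analysis assumes, and the whole pipeline is exercised end to end on it.

- **Panel**: 167 variants, 26 of them HLA-like pseudo-markers, exactly
  one large-effect allele at OR 2.9 (frequency 0.15, the European
  frequency scale of the major MS HLA allele), remaining ORs uniform on
  [1.05, 1.6] — the published range of the non-HLA effects — with risk
  allele frequencies uniform on [0.05, 0.5].
- **Disease**: a liability-threshold model. Liability is the panel score
  plus Gaussian noise scaled so the score explains a fixed share of
  liability variance; disease status is liability above the threshold
  implied by prevalence. The polygenic share defaults to 0.21,
  calibrated once so that the simulated case-control wPRS AUC centres on
  the published 0.75 (a sweep over 0.16–0.22 gave mean AUCs 0.725–0.759);
  it is not adjusted per run. Prevalence defaults to 0.10 — far above the
  real MS prevalence — purely so that 500 cases and multicase families
  are reachable by direct rejection sampling at simulation sizes that run
  in seconds; the AUC calibration absorbs this choice.
- **Families**: gene dropping down a three-generation template (two
  founders, six offspring including an optional MZ pair, one offspring
  married into a founder spouse with two children, shaped after the
  published pedigrees). Families are ascertained by rejection sampling
  until at least three members are affected, mirroring multicase
  recruitment; the empirical acceptance rate is recorded.
- **Cohort**: 500 cases and 900 controls by default, a scaled-down
  case-control design with the same imbalance direction as the original
  cohort.

What the simulation deliberately omits: linkage disequilibrium (the real
HLA region is strongly structured), rare or family-private risk
variants, gene-environment effects, and any ancestry structure. Passing
tests on the simulation therefore demonstrate that the *pipeline's
machinery* is correct and that polygenic enrichment plus ascertainment
alone reproduce the qualitative familial pattern — they do not
demonstrate anything about real-data effect sizes beyond the calibrated
AUC.

Under these defaults the simulated study reproduces the published
pattern: familial cases score significantly above population controls,
unaffected relatives also score above controls, and familial cases are
not systematically separable from population cases. That last point is
the analysis's substantive conclusion — elevated common-variant burden
in multicase families, but no more than in sporadic cases, so polygenic
load alone does not explain familial clustering.

## Numerical choices and degenerate inputs

- Welch tests delegate to `stats::t.test`; ROC/AUC and DeLong confidence
  intervals delegate to pROC (AUC equals the Mann–Whitney statistic with
  ties counted ½). A stratified bootstrap CI is available as an option.
- p-values are stored at machine precision everywhere; the conventional
  "< 2.2e-16" floor is applied only in printed output.
- Subsampling uses one master seed that spawns per-iteration substreams,
  so extending the number of iterations preserves earlier draws.
- The relationship matrix is accepted if its smallest eigenvalue exceeds
  −1e−8 (tiny negatives are clamped to zero); genuinely non-PSD input is
  an error.
- Degenerate inputs fail loudly: all-missing dosage vectors, constant
  vectors passed to the inverse normal transform, single-class ROC
  labels, singular design matrices, pedigree cycles, one-parent records
  and mixed-sex MZ groups are all rejected with specific messages.
- Group summaries use the sample standard deviation (n − 1); this is
  what reproduces the published familial dispersion values from the
  bundled per-individual fixture. One known discrepancy is documented:
  the third family's affected pair {23.13, 22.91} yields SD 0.156, which
  the published table prints as 0.15 (the package's 2-dp rendering gives
  0.16); the package reports full precision and leaves the rendering
  question open.

## Problem sizes used in the validation suite

The shipped tests validate the statistical engines at sizes chosen to
give stable Monte Carlo estimates while keeping the whole suite fast:
size and power of the resampling and mixed-model tests use 1,000 null
replicates and 200 power replicates at the study's group sizes (about 10
familial members against 500 cohort members); heritability recovery uses
200 replicates of 50 six-sib sibships (n = 300, true h² = 0.6, mean
estimate required within ±0.1); kinship is checked against a 10⁶-drop
gene-dropping oracle on five randomly generated pedigrees; and the
end-to-end pattern check runs the full pipeline over 20 seeds with 100
subsampling iterations each.

## Known limitations

- Variant matching is by identifier (with chromosome/position as the
  practical fallback when building inputs); no liftover between genome
  builds is provided.
- The mixed model is univariate with a single additive variance
  component: no dominance, household, or X-linked components.
- Imputation quality filtering is assumed done upstream; the pipeline
  consumes dosages as given.
- The simulator's families all share one template; real multicase
  families differ in structure, and the bundled three-family pedigree is
  a synthetic reconstruction wherever the published diagrams do not pin
  the structure down.
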