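---
title: "Methods: epigenetic Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenome-wide association studies (EWAS) report hundreds of CpG sites where
DNA methylation tracks a lifestyle exposure, but an EWAS association alone
cannot say whether those methylation differences have downstream consequences.
`epimr` implements a summary-statistic pipeline that treats methylation at an
exposure-associated CpG as an exposure in its own right: cis-acting
methylation quantitative trait loci (mQTL) serve as instrumental variables,
two-sample Mendelian randomization (2SMR) estimates the effect of methylation
on complex traits across a phenome of GWAS outcomes, three-trait Bayesian
colocalization asks whether methylation, nearby gene expression and the trait
share one causal variant, and a set of orientation analyses (Steiger
directionality tests, reverse MR, sign chaining with the EWAS effect) orders
the chain exposure → methylation → expression → trait.

Everything runs from per-variant summary statistics (beta, SE, p, effect
allele, frequency, sample size) plus a genotype reference panel in VCF used
for linkage disequilibrium (LD) and allele frequencies. No individual-level
cohort data are required, which is the point: the molecular and outcome
associations typically come from non-overlapping samples.

## Instrument selection

Candidate instruments for a CpG are mQTL records with `p < 1e-7` strictly and
position strictly within 1 Mb of the CpG. Trans-mQTLs are never used: a
variant acting on a distant CpG is more plausibly pleiotropic, and with a
single instrument per CpG the downstream analyses could not detect that.

Conditional independence among candidates is established by a stepwise
approximate conditional-and-joint selection from summary statistics: the
model is seeded with the smallest marginal p-value, and at each step the
joint model of the selected set plus each remaining candidate is fitted by
rebuilding the normal equations from the panel — LD correlations `r_jk`
scaled by genotype standard deviations `sqrt(2 f_j (1 - f_j))`, phenotypic
variance taken as 1 for standardized traits. The candidate with the smallest
joint p-value is added while that p-value stays below the selection threshold
and its squared panel correlation with every selected variant stays below the
collinearity cutoff (default r² = 0.9, the conventional default; candidates
that make the LD submatrix singular are dropped with a warning). Forward
selection only; with the handful of conditionally independent cis-mQTLs
typical of a single CpG, backward elimination has nothing to remove.

When an instrument is absent from an outcome dataset, a proxy is sought among
outcome variants within ±500 kb with panel r² > 0.8; the allele map follows
the sign of the dosage correlation, so the harmonized effect direction is
invariant to which of the two variants carries the estimate. Harmonization
aligns the outcome record to the exposure's effect allele (swaps negate the
beta, opposite-strand records are complemented); palindromic A/T and C/G
variants are dropped when either allele frequency is missing or falls in
[0.42, 0.58], and otherwise oriented by frequency concordance.

## MR estimation

With one instrument the causal estimate is the Wald ratio
\(\hat\beta = \hat\Gamma / \hat\gamma\) (variant-outcome over
variant-exposure association) with first-order delta-method standard error
\(\sigma_Y / |\hat\gamma|\). This ignores exposure-side uncertainty and is
documented as anti-conservative for weak instruments; at the instrument
strengths the selection threshold enforces (|z| > 5.3) the approximation
error is below a few percent, and the test suite checks it against a
Monte-Carlo propagation oracle. With several instruments the fixed-effect
inverse-variance-weighted (IVW) combination is used, with weights
\(w_j = \hat\gamma_j^2 \sigma_{Y_j}^{-2}\):

\[\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j},\qquad
  se = \Big(\sum_j w_j\Big)^{-1/2}.\]

A single instrument reduces IVW to the Wald ratio exactly, and `k` identical
instruments shrink the SE by exactly \(1/\sqrt{k}\). P-values are two-sided
normal (summary-data asymptotics). MR-Egger and median/mode estimators are
out of scope: CpGs here carry one or two instruments, below what those
methods need.

A phenome scan over `n_cpgs × n_traits` pairs is flagged against the
Bonferroni threshold `alpha / (n_cpgs × n_traits)` with a strict `<`.
Power for planning is the two-sided asymptotic power of the Wald test,
\(\Phi(-z_{1-\alpha/2} + |\beta|\sqrt{n r^2_{gx}}) +
  \Phi(-z_{1-\alpha/2} - |\beta|\sqrt{n r^2_{gx}})\).

## Three-trait colocalization

Per variant and trait, evidence for association is the Wakefield log
approximate Bayes factor computed from the beta/SE pair with prior effect
variance `W = 0.04` (SD 0.2 on standardized effects, the conventional choice
for continuous traits; configurable per analysis). For three traits there are
exactly 15 configuration classes: each trait is unassociated or assigned to a
causal-variant group, groups share one variant, distinct groups have distinct
variants. Class evidence sums, over all assignments of distinct variants to
groups, the product of group ABFs; it is evaluated in closed form from
group-wise log-sum-exp accumulators with inclusion–exclusion corrections for
coincident assignments, entirely in log space (z² terms overflow otherwise).
The test suite checks every class against a naive exhaustive-loop oracle on
small regions to 1e-9.

Class priors are the product over groups of per-variant priors `p1 = 1e-4`
(one trait), `p2 = 1e-6` (two traits sharing), `p3 = 1e-7` (all three); these
are the published defaults of the multi-trait colocalization literature — the
source analysis does not print its priors, so posterior values are matched
qualitatively (threshold behaviour), never numerically. `ppa_abc` is the
posterior of the single class in which one variant drives all three traits;
partial-sharing classes such as `ab.c` are reported but do not count toward
the 0.8 decision threshold. No multiple-testing correction is applied to
posteriors.

The regional scan runs colocalization for every gene whose annotated interval
lies within 100 kb of the CpG (distance to the nearest interval edge — the
most inclusive defensible reading), on the intersection of the three variant
grids with panel MAF ≥ 5%, and only when at least 50 variants remain. When a
CpG is associated with several correlated traits, only the trait with the
highest `ppa_abc` is taken forward (ties: smaller MR p, then trait id).

## Orientation

The Steiger-style directionality test compares the variance the instruments
explain in two traits, `r² = z²/(z² + n − 2)` per record (summed over
independent instruments), via a two-sample Fisher-z test on `atanh(|r|)`.
The two-sample form is deliberate: exposure and outcome r² come from
non-overlapping cohorts, so dependent-correlation corrections do not apply.
The direction goes to the larger r² when the test rejects at 0.05
(configurable), otherwise "indeterminate". The test is applied three times
per association (methylation–expression, expression–trait,
methylation–trait).

Reverse MR swaps the roles: genome-wide-significant trait variants
(p < 5e-8), LD-pruned at panel r² < 0.1 within each chromosome, instrument
the trait with methylation as the outcome. Sign chaining multiplies the EWAS
exposure→methylation beta with the MR methylation→trait beta; a negative
product reads "the exposure putatively lowers the trait". The wording is
produced mechanically from the sign — no phenotype knowledge is embedded.
Cross-sample comparison reports sign concordance and a two-sample
heterogeneity z for the same pair estimated in two cohorts, timepoints or
strata.

The pipeline gates strictly: only MR-significant pairs reach colocalization,
only pairs with `ppa_abc ≥ 0.8` reach orientation, and per-pair failures are
recorded as machine-readable skip reasons without aborting the run.

## The simulator: what it emulates and what it does not

Every stage is testable without cohort access through `simulate_region()` /
`simulate_study()`. The population model is a variant grid with MAFs drawn
smoothly along the region (an AR(1) latent on the quantile scale — variants
in strong LD necessarily have similar frequencies) and haplotypes from a
thresholded AR(1) Gaussian copula. Thresholding attenuates correlation, so
the latent parameter of each adjacent pair is calibrated through the
bivariate normal orthant probability to make the *genotype* correlation equal
`ld_rho`; genotype r therefore decays approximately as `ld_rho^distance`.
Each cohort (panel, mQTL, eQTL, GWAS) is an independent draw from this
population — the two-sample assumption — and all randomness flows from one
master seed through deterministic sub-streams, so emissions are bit-identical
across runs.

Phenotypes are built to unit population variance with effects in SD units
(no empirical rescaling, so regression calibration is exact). Scenarios:
`shared` (one variant drives methylation; expression and trait are downstream
of methylation through `beta_me`, `beta_mt`), `distinct` (three separate
causal variants chosen with mutual panel r² ≤ 0.3), `null` (methylation
genetic, expression/trait noise), `methylation_only` (no expression
mediation) and `trait_causal` (trait genetic, methylation downstream — the
reverse-causation architecture). `trait_causal` exists because reverse MR
cannot be tested honestly inside a single shared-causal region: there the
only genome-wide-significant trait variant *is* the methylation-causal
variant. Reverse-MR tests therefore instrument the trait from an unlinked
trait-driven region, mirroring real genome-wide trait instruments that are
not cis-mQTLs.

Summary statistics are exact univariate OLS per variant (beta, SE, two-sided
t p-value floored at 1e-300, EAF from dosages), which makes the identity
`z²/(z²+n−2) = r²(g, y)` hold to numerical precision — the consistency the
Steiger stage relies on. Monomorphic variants are emitted with a missing
beta and rejected downstream; a noiseless fit keeps `se > 0` through a
residual floor at numerical-noise scale.

The simulator does not model 450K array measurement error, cell-composition
or batch structure, allele-frequency misspecification between panel and
cohorts, sample overlap between exposure and outcome studies, or horizontal
pleiotropy. Passing tests therefore demonstrate correctness of the
estimators and decision rules under the stated causal architectures, not
robustness to those real-data complications. mQTL effect sizes are
controlled by `causal_r2` (defaults in the 0.1–0.2 range across tests,
chosen for test power at desk-scale cohort sizes rather than as an empirical
claim about any mQTL resource).

## Numerical and design choices

- Coordinates are 1-based inclusive (VCF convention); window arithmetic in bp.
- Strict inequalities at every printed threshold (`P < 1e-7`, `< 1 MB`,
  Bonferroni `<`, proxy `r² > 0.8`).
- Column maps for summary tables are configurable with documented defaults
  (SNP, CHR, BP, EA, OA, EAF, BETA, SE, P, N); rejected rows are counted and
  logged, never fatal; missing EAF is tolerated at read time and resolved at
  harmonization (palindromes with missing EAF are dropped).
- Log-space accumulation with max-shift everywhere in colocalization; class
  evidences that are combinatorially impossible (more groups than variants)
  are exact zeros (`-Inf` in log space).
- COJO-style selection ties are broken by p-value then variant id, making
  selection invariant to input row order.
- Test and example problem sizes (cohorts of 300–10 000, regions of 8–60
  variants, 50–500 seed replicates) were chosen so the full suite exercises
  every decision rule at adequate simulated power on a single CPU; the same
  settings are used by `scripts/acceptance.R`.

## Known limitations

- The Wald SE ignores exposure-side uncertainty (anti-conservative for weak
  instruments); the selection threshold keeps instruments strong.
- Only ≤ 3 traits are supported in colocalization and one causal variant per
  trait per region is assumed (no fine-mapping of allelic series).
- "Mixed population" eligibility is taken at face value from metadata; the
  source criteria do not define how it was operationalized.
- Printed per-association p-values from rounded beta/SE pairs are not
  reproduced beyond sign and order of magnitude, and published posterior
  probabilities are matched only in threshold behaviour because the original
  priors are not printed.
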