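---
title: "Methods: multi-trait pleiotropy scanning and mediation in pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait pleiotropy scanning and mediation in pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pleioscan` detects genetic variants shared between inflammation (CRP) and
adiposity (BMI, sex-stratified waist-to-hip ratio) and dissects whether the
sharing is biologic (direct effects on both trait families) or mediated
(one trait transmits the effect to the other). This vignette documents the
statistical models, the tunable parameters, the synthetic-data generator
that drives testing, and the numerical and design choices — in enough
detail that a reader can judge what the test suite does and does not
establish.

## 1. Phenotype preparation

The four analysis traits are CRP, BMI, WHR in men and WHR in women, with
WHR defined as `100 * waist / hip`. Preparation order is fixed and tested:

1. *Transform*: natural log of CRP (its distribution is strongly right
   skewed; BMI and WHR are used untransformed).
2. *Outlier exclusion*: a single, non-iterative pass removes observations
   beyond `k` SD of the mean — `k = 3` for log-CRP, `k = 4` for BMI and
   WHR. The pass is deliberately single: re-flagging after exclusion would
   make the retained set depend on iteration order and count, and the
   convention in large consortium GWAS is one pass. A constant vector
   (SD = 0) flags nothing.
3. *Residualization*: ordinary least squares on age, age², sex and
   age-by-sex (where sex varies — WHR strata are single-sex), BMI (for the
   WHR traits only), and center/study indicator columns with the first
   level (alphabetically) as reference. Collinear columns are dropped with
   a warning rather than erroring, because indicator rosters routinely
   alias in small strata. Ancestry PCs are *not* residualized here — they
   enter the association model itself, mirroring the two-stage practice of
   residualize-then-test.
4. *Inverse-normal transform (INT)*: ranks map to normal quantiles via the
   rankit offset, `qnorm((r - 0.5) / n)`, with average ranks for ties. The
   rankit offset avoids infinite quantiles at the extremes and is the
   common GWAS choice; the Blom offset (3/8) is available via
   `offset = "blom"`. Ties share the averaged-rank quantile, so the map is
   rank-preserving but not injective under ties.

The exclusion-before-residualization order matters: outliers would
otherwise leverage the covariate fit. Exclusions are audited per trait.

## 2. Univariate association and meta-analysis

For each SNP, the model is `INT-trait ~ dosage + 10 PCs` with an
independence working correlation, and the variance of the dosage
coefficient is the cluster-robust sandwich over family clusters — the GEE
arrangement for related individuals. With singleton clusters this is
exactly HC0. The implementation partials both trait and dosage on the
covariates (Frisch–Waugh) and accumulates per-cluster score sums, which
reproduces the dosage element of the full-model sandwich exactly; the test
suite asserts equality with `sandwich::vcovCL(type = "HC0",
cadjust = FALSE)` to machine precision. The test is Wald
(`z = beta / se`); score and Wald are asymptotically equivalent here and
Wald keeps the summary-statistic contract simple (`p = 2 * pnorm(-|z|)`).

SNP-level QC drops records with imputation `info < 0.4`, effective sample
size `n_eff < 30` or MAF `< 0.05`, all strict inequalities so boundary
values survive. The effective-sample-size convention is
`n_eff = 2 * eaf * (1 - eaf) * n * info`, the standard information-content
adjustment for imputed dosage GWAS; the source analysis defers its exact
formula to an appendix that is not part of the main text, so the formula
is configurable (`effective_n(formula = ...)`).

Studies are pooled by fixed-effect inverse-variance weighting
(`beta = sum(w * b) / sum(w)`, `se = 1 / sqrt(sum(w))`, `w = 1 / se^2`),
which is order-invariant and satisfies `se_meta = se / sqrt(k)` for `k`
identical studies — both asserted exactly in tests. Genomic calibration is
monitored with `lambda = median(chisq) / 0.4549`.

## 3. The adaptive Sum of Powered Score test

For a SNP with trait Z-scores `z = (z_1, ..., z_K)`,
`SPU(gamma) = sum_p z_p^gamma`. Small `gamma` pools dense, same-direction
signal; large `gamma` concentrates on the strongest trait; `gamma` in
`1..8` (the published ladder) covers the spectrum, and the sup-norm
variant (`gamma = Inf`) is available behind `include_inf = TRUE` but
excluded by default to match the published ladder. Comparisons use
`|SPU|`: the sign of a Z-score is an allele-coding artifact, so a
two-sided rule is the only orientation-invariant choice for odd powers.

Monte-Carlo machinery: draws `b = 1..B` from `MVN(0, R)` give
`p_gamma = (1 + #{|SPU_b| >= |SPU_obs|}) / (B + 1)` (the add-one estimator,
so p is never zero). The adaptive statistic is `min_gamma p_gamma`; its
p-value ranks each draw's own minimum per-draw p against the observed
minimum. Per-draw p-values are obtained by ranking each draw among all `B`
draws (`O(B log B)`), and the suite proves the rank trick identical to a
naive `O(B^2)` re-ranking oracle at `B = 2000`.

The null correlation `R` is estimated from the genome-wide Z matrix:
pairwise-complete Pearson correlation over SNPs with `|z| < 2` on every
available trait, thinned 1-in-100 by position (LD thinning; synthetic
panels without LD can use `thin = 1`). Truncation at `|z| < 2` biases the
estimate toward zero — the suite quantifies the bias against a brute-force
truncated-MVN oracle — and the bias is accepted as conservative for the
null model. Non-positive-definite estimates are ridge-repaired with a
logged warning.

**Staged escalation.** Published genome-scale analyses quote on the order
of 10^11 iterations; a desktop re-implementation cannot spend that per
SNP, and does not need to: resolution matters only for SNPs near or below
the significance threshold. Every SNP is evaluated at `B = schedule[1]`
(default 10^4); SNPs with `p_aspu <= c / B` (default `c = 100`) escalate
to the next stage. The default deep schedule ends at 10^8, where the
Monte-Carlo floor `1/(B+1) ≈ 1e-8` lies below the 1.25e-8 candidate
threshold. Stages above 2^24 draws switch to a chunked two-pass
evaluation: pass one accumulates exceedance counts and retains the top
2×10^5 null statistics per gamma; pass two regenerates the same chunks and
counts per-draw minima exactly from the retained tails. The chunked path
is definitionally identical to the in-memory rank trick (asserted in
tests) and bounds memory at roughly the chunk size, independent of `B`.

Null draws are generated once per (stage, availability-mask) group and
shared by the SNPs in that group; stream seeds derive deterministically
from the master seed and the group key, so results are independent of SNP
processing order. Sharing trades a little between-SNP independence for a
large constant-factor saving; one consequence, documented because it
surfaced in calibration testing, is that an empirical type-I rate computed
against a single shared table inherits the table's quantile noise on top
of binomial noise. The calibration check therefore averages five
independent replicates of the 2000-SNP condition, which sharpens the
Monte-Carlo spread of the measured rate without widening the acceptance
band. SNPs with missing traits use the matching sub-vector and `R`
submatrix, which is the aSPU accommodation for differing per-trait sample
sizes.

## 4. Locus selection, replication, harmonization

Clumping is greedy: the best remaining SNP by `p_aspu` leads a locus and
absorbs all SNPs within a 1 Mb window at dosage `r^2 >= 0.1`. The window
default bounds compute; the `r^2` rule is the published one. An
exhaustive oracle clumper in the test suite asserts identical partitions
on block fixtures.

Candidate rule: `p_aspu < 1.25e-8` (5e-8 genome-wide level divided by 4
traits), nominal (< 0.05) univariate CRP *and* at least one adiposity
trait, and presence in the pooled genotyping panel (a boolean column in
this implementation). Replication rule: `p_aspu < 0.05`, nominal CRP and
at least one anthropometric trait, and concordant effect direction between
discovery and replication — applied to the traits counted toward the
nominal-support criterion (CRP plus the nominally significant adiposity
traits), since direction of a trait with no replication signal is noise.
Decisions are pure functions returning per-criterion reasons whose
conjunction is the verdict.

Allele harmonization flips swapped effect/other alleles (negating beta),
resolves strand flips by complement, and orients strand-ambiguous A/T and
C/G SNPs by effect-allele-frequency proximity, dropping them when neither
orientation brings frequencies within 0.2.

## 5. Causal mediation

For a replicated SNP, prior trait knowledge fixes the direction: an
inflammation-prior SNP is analyzed with CRP as mediator and adiposity as
outcome, and conversely. Two least-squares fits on complete cases — the
mediator model and the outcome model, both with HC0 sandwich covariance,
no genotype-by-mediator interaction — feed a quasi-Bayesian simulation:
`n_sims = 1000` parameter draws from `MVN(estimate, robust vcov)` per
model, with per-draw `ACME = a*b`, `ADE = c'`, `total = ACME + ADE`. The
product-of-coefficients form of ACME is exact for linear, no-interaction
models. Point estimates are medians of draws (the quasi-Bayesian
convention), intervals are 2.5/97.5 percentiles, and p-values are
two-sided Monte-Carlo sign tests (`2 * min(P(<0), P(>0))`, capped at 1;
the p-value construction is a design choice, as the source does not state
one). Draw-wise additivity `total = ACME + ADE` holds exactly, draw by
draw, and is asserted as an identity.

Sensitivity to sequential-ignorability violation uses the linear
structural-equation identity
`ACME(rho) = beta_m (sigma_1/sigma_2) (rho~ - rho sqrt((1-rho~^2)/(1-rho^2)))`,
with `rho~` the correlation between total-effect-model and mediator-model
residuals; `ACME(0)` is the product-of-coefficients estimate and the curve
crosses zero exactly at `rho = rho~`. Because the reported point estimate
is a draw median while the identity anchors at the analytic product, the
curve is rescaled by their ratio (a factor within Monte-Carlo error of
one) so that `ACME(0)` equals the reported estimate exactly; rescaling
does not move the zero crossing. Sensitivity is implemented for the
linear/linear case only — both mediation analyses in scope are
continuous-on-continuous.

## 6. The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes:

- **Genotypes**: Binomial(2, maf) per individual (Hardy–Weinberg), MAF in
  (0, 0.5]. Pairwise LD is available through a latent bivariate-Gaussian
  threshold construction (`simulate_ld_pair`), used to test clumping;
  panels are otherwise LD-free.
- **Phenotypes**: latent standardized traits (log-CRP, BMI, WHR) are
  linear in covariates, genotypes, a family random intercept and
  correlated errors; CRP is then exponentiated (log-normal, floored at
  1e-4 for assay detection limits) and traits are rescaled to the
  descriptive units of the discovery roster (CRP mean ≈ 4.2 mg/dL, BMI
  29.2 ± 6.0, WHR 86.6 ± 8.4 in women and 95.6 ± 6.8 in men). Waist and
  hip are constructed so `100 * waist / hip` reproduces the WHR value.
- **Trait-error correlation** is specified as a 3×3 matrix over the latent
  traits (log-CRP, BMI, WHR) rather than 4×4 over analysis traits: an
  individual belongs to one WHR stratum, so the per-individual error
  vector is three-dimensional and the four-trait structure arises from
  sex stratification. The default has 0.45 between the adiposity latents
  and 0.20–0.25 with log-CRP, a moderate phenotypic interrelation.
- **Effect classes** make ground truth explicit per SNP: `pleiotropic`
  (direct `beta_crp` and `beta_adip`), `mediated` (one direct beta; the
  downstream trait receives `mediation_coeff ×` the standardized mediator,
  so the marginal effect is the product of path coefficients),
  `single_trait`, `null`. The mediation direction is declared per SNP
  rather than inferred, so tests always know the truth; both directions in
  one cohort are rejected to keep the structural model acyclic.
- **Covariates**: age ~ Uniform(18, 80), sex ~ Bernoulli(0.63) (the
  discovery female fraction), standard-normal PCs, a small number of
  centers — documented placeholders, not demographic models. Families are
  drawn from a size distribution (default 70% singletons, 20% pairs, 10%
  trios) with a shared Gaussian intercept of variance 0.1 (10% of unit
  residual variance) — the related-individuals adjustment is part of the
  analysis contract, but no generative family model is published, so this
  is the package's own minimal choice.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: realistic allele-frequency spectra and LD
beyond pairwise blocks, imputation uncertainty beyond an info-score
column, cross-cohort CRP assay heterogeneity (synthetic CRP is one scale;
the published analyses harmonized assays), population stratification
(PCs are noise covariates here, not confounders), and self-report
measurement error.

## 7. Numerical choices and degenerate inputs

- Monte-Carlo p-values use the add-one estimator; every reported p is in
  `[1/(B+1), 1]`.
- Tie handling is explicit everywhere ranks appear: average ranks in the
  INT, `>=` comparisons with max/min tie ranks in the aSPU machinery
  (exactness against the naive oracle covers ties), average-rank-free
  strict counting in `findInterval` form.
- Monomorphic SNPs yield a flagged record (`beta = 0`, `se = NA`) rather
  than an error mid-scan, and are excluded from meta-analysis.
- Correlation matrices are ridge-repaired to positive definite with a
  warning; hard failures are reserved for genuinely non-PD user inputs.
- All randomness flows from explicit seeds; per-group stream seeds are
  derived by integer hashing (kept below 2^31), so outputs are
  independent of processing order and bit-reproducible — the pipeline
  manifest records md5 checksums and two same-seed runs are asserted
  byte-identical.

## 8. Problem sizes in the test and acceptance runs

The suite exercises: calibration on 5 × 2000 null SNPs at `B = 1e4`;
SPU(2) against the χ²₄ survival function at `B = 1e6`; oracle equivalence
at `B = 2000`; mediation recovery and coverage over 200 replicates at
`n = 5000`; and an end-to-end run with two discovery studies of
`n = 2000`, a replication cohort of `n = 1000`, and 5014 SNPs (4
pleiotropic, 10 single-trait, 5000 null) with the deep schedule
`(1e4, 1e6, 1e8)`. These sizes were chosen so each property is measured
with useful precision while the whole suite runs on a single CPU in
minutes; they are scaled-down study conditions, not reproductions of
genome-scale results. Screening of single-trait variants is asserted as a
count bound (at most 3 of 10 evading) because a single-trait variant
escapes the inflammation-nominal criterion exactly when the univariate
CRP test false-positives at the 5% level — an event whose probability does
not shrink with effect size.

## 9. Known limitations

- The GEE is independence-working-correlation only; no exchangeable or
  kinship-structured alternatives, and no mixed-model GWAS.
- aSPU here operates on summary-statistic Z-vectors; individual-level
  score-based aSPU and pathway variants are out of scope.
- Mediation handles continuous mediator and outcome, a single mediator,
  and no interaction; binary traits and multiple-mediator decompositions
  are not supported.
- The `present_in_pool` criterion is a user-supplied boolean, abstracting
  a cohort-specific genotyping-panel membership question.
- X-chromosome dosage conventions and genotype imputation itself are out
  of scope.
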