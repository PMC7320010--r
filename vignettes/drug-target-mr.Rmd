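---
title: "Drug-target Mendelian randomisation with correlated cis variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomisation with correlated cis variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The model

Drug-target (cis) Mendelian randomisation asks whether perturbing a protein
drug target changes disease risk, using genetic variants in and around the
encoding gene as instruments. cismr models the causal chain

> variant **G** → mRNA expression **E** → protein **P** → biomarker **X** → disease **D**,

with a shared (possibly unmeasured) confounder **U** of P, X and D, a direct
variant-to-disease path `phi_G` (horizontal, pre-translational pleiotropy), a
direct protein-to-disease path `phi_P`, and the biomarker-mediated path
`mu * theta`. The estimand is the total effect of perturbing the protein,

    omega = phi_P + mu * theta.

Because the protein is the proximal effector, post-translational pathways
(`phi_P` versus `mu * theta`) are *vertical* pleiotropy and do not bias the
analysis; only the pre-translational path `phi_G` does. When the protein
itself is not measured, the same null hypothesis `omega = 0` can be tested
with alternative weightings, whose estimands differ by known factors:

* biomarker-weighted: `omega_bw = omega / mu`;
* expression-weighted: `omega_ew = delta_EP * omega`,

where `delta_EP` is the expression-to-protein effect. A biomarker-weighted
test stays valid even when the biomarker has no causal effect on disease
(`theta = 0`) so long as the protein acts directly (`phi_P != 0`) and the
protein-biomarker link is strong (`mu != 0`) — the regime in which a
downstream lipid can proxy a target like CETP.

## Estimation with correlated variants

All estimators consume a `harmonized_input`: exposure and outcome
associations on a common variant set and allele orientation plus a *signed*
LD matrix (Pearson r between effect-allele dosages; signs matter because the
GLS covariance uses them, while clumping uses r²).

`gls_ivw()` regresses outcome betas on exposure betas through the origin by
generalised least squares with covariance
`Omega[j,k] = se_y[j] se_y[k] r[j,k]`:

    estimate = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by .

With a single variant this is the Wald ratio; with identity LD it is the
classic inverse-variance-weighted estimate. `gls_egger()` frees the
intercept after orienting every exposure beta non-negative (flipping the
paired outcome betas and LD signs jointly); the intercept estimates average
directional pleiotropy under the INSIDE assumption and the slope is the
corrected causal effect.

Design choices a user should know:

* **Weighting uses outcome-side uncertainty only.** Exposure-side noise is
  ignored in `Omega`, as is conventional for summary-statistic MR; under the
  two-sample design the resulting weak-instrument bias is towards the null.
  The model-based standard error is therefore approximately correct only
  when instruments are strong and the exposure statistics are not much
  noisier than the outcome statistics; the simulation presets (below) sit in
  that regime deliberately.
* **Fixed versus random effects.** Fixed effects use the model se; random
  effects multiply it by `max(1, sqrt(RSS_gls / df))`, so excess dispersion
  widens intervals but can never narrow them. The square-root form is used
  for unit consistency.
* **Inference is normal-theory throughout** (not t), matching the
  convention for GWAS summary statistics and 95% interval presentation.
* **No silent pseudo-inverses.** If the weight matrix fails a Cholesky
  factorisation the estimator raises a multicollinearity error pointing to
  `collinearity_screen()`; GLS failures from near-duplicate variants are a
  real phenomenon and should be visible, not papered over.

## Heterogeneity and outliers

`heterogeneity()` whitens residuals by the symmetric inverse square root of
`Omega`. The resulting Q is a sum of squared whitened residuals whose
per-variant components sum to Q exactly and which reduces to Cochran's Q
under identity LD — the natural generalisation, since the paper-standard Q
is undefined for correlated instruments. Leverage is the hat diagonal in the
whitened space; Cook's distances are computed there too. Defaults for
`remove_outliers()` — per-variant Q component p below `0.05/J`, Cook's above
`4/J`, leverage above `2p/J` — are the usual regression rules of thumb, all
configurable, since no canonical thresholds exist for this setting.

## Instrument selection

`clump()` is the greedy sentinel algorithm: repeatedly take the
smallest-p unassigned variant and absorb everything with `r² >=` the
threshold. Ties on p break by position then id, so output is deterministic.
`grid_search_r2()` runs clump → screen → estimate across thresholds
(default grid 0.1–0.9 in steps of 0.1; the flank grid defaults to
2.5 kB and 1 MB, the two conventional regimes). Per-point failures are
flagged rows, not exceptions — a threshold at which the model collapses is
itself a finding. `select_threshold()` makes the "compare threshold l with
l − 1" rule operational: choose the largest unflagged threshold whose
estimate moved at most `stability_tol` (default 0.5) standard errors from
the previous point.

`random_subset_experiment()` quantifies how much an analyst's arbitrary
choice of a handful of instruments matters, by repeatedly sampling (default
500 draws of 4) from the MAF- and LD-filtered candidate pool and
re-estimating with full LD each time. The declared `expected_sign` is a user
input (e.g. from trial evidence), never inferred. One master seed drives
per-iteration counter-derived seeds, so any single iteration can be
reproduced in isolation. `stratify_by_annotation()` groups iterations by the
most severe functional consequence present (the standard variant-effect
severity ranking ships as a data file and can be overridden) and drops
categories seen fewer than 5 times.

`prune_nontarget()` addresses LD-based horizontal pleiotropy: a cis variant
may tag a neighbouring gene's causal variant. Given a table of variant ×
non-target-gene association p-values (neighbours within ±1 MB by default),
it removes, at each threshold in `1e-8 … 1e-3`, every variant whose minimum
non-target p falls below the threshold, then re-clumps, re-screens and
re-estimates. Pruning precedes re-clumping so sentinels are re-chosen among
survivors; retention is monotone across thresholds and asserted on every
run.

## The simulation engine

`simulate_study()` draws three disjoint samples — exposure GWAS, outcome
GWAS, and an external LD panel — to honour the two-sample design. Genotypes
come from a latent multivariate Gaussian (AR(1) by default) thresholded at
the allele-frequency quantile per haplotype and summed over two haplotypes;
realised dosage LD is the tetrachorically attenuated target, which is what a
hard-call reference panel would show. Phenotypes follow the causal chain
above with unit residual standard deviations unless stated; marginal
per-variant regressions (linear, or logistic for case-control outcomes with
a ~30% baseline rate) produce the summary statistics. All three exposure
weightings are computed on the same draws, so the `omega`, `omega / mu` and
`delta_EP * omega` identities can be checked replicate by replicate.

What the generator emulates: LD-structured dosages, marginal-versus-joint
effect smearing, two-sample independence, panel-estimated LD noise,
confounding of the phenotype chain. What it does not: haplotype-level
realism (recombination maps, empirical MAF spectra), allele-frequency
differences between samples, imputation error, or sample overlap. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to those unmodelled features.

### Scenario presets and why their magnitudes are what they are

`scenario()` ships the regimes used by the package's own validation, with
magnitudes chosen once as declared constants:

* `protein_causal` (and the `biomarker_proxy` / `expression_proxy` views of
  the same truth): 30 variants, AR(1) 0.6, n = 20,000/20,000/2,000,
  `omega = 0.3` split as `phi_P = 0.1` plus `mu * theta = 2 × 0.1`,
  `delta_EP = 0.8`. The disease residual sd is 3, so the locus explains
  about 1% of liability variance — a realistic single-locus share. This
  matters: with an implausibly strong locus, exposure-side noise (which the
  GLS se ignores by design) becomes a visible share of the estimator's
  sampling variance and intervals undercover.
* `null`: the same architecture with `omega = 0` and a biomarker exposure
  (`mu = 2`), n = 5,000 per GWAS — the calibration regime.
* `post_translational_pleiotropy`: `theta = 0`, `phi_P = 0.3`, `mu = 2`,
  biomarker-weighted — the validity-despite-non-causal-proxy regime.
* `directional_pleiotropy`: independent variants, constant `phi_G = 0.05`
  drawn independently of instrument strength (INSIDE holds), exposure
  GWAS of 200,000 (biomarker-consortium scale) with per-allele effects
  spread over 0.1–0.7 SD. The large exposure sample and wide effect spread
  keep the no-measurement-error (NOME) condition effectively satisfied;
  with weak instruments the Egger slope shows ordinary regression dilution,
  which is a property of the regime, not of the estimator.
* `neighbour_gene_pleiotropy`: a 12-variant locus whose last variant drives
  a neighbouring gene (no effect on the target protein, direct effect 0.4
  on disease) and sits in LD with the locus; the matching non-target
  association table is emitted for `prune_nontarget()`.

Logistic outcomes carry mild non-collapsibility, so odds-ratio-scale
recovery is only expected to about 10%; tests use that widened tolerance.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and closed; BED input is converted on read.
* Palindromic (A/T, C/G) variants are dropped only when the minor allele
  frequency is at or above 0.42 (configurable) or missing — frequency can
  otherwise resolve the strand, and discarding all palindromes wastes power.
* Variants are matched by id, falling back to chromosome:position with a
  compatible allele set; ambiguous position matches are dropped and logged.
* p-values equal to zero (underflow in source files) are clamped to the
  smallest positive double; they rank clumping only.
* The condition-number limit for `collinearity_screen()` is 1e8, the
  removal loop prefers lower-MAF variants among near-ties (panel LD is least
  stable there) and refuses to remove more than half the variants.
* Clumping at threshold 1 retains all variants unless perfect proxies
  exist; `beta_exposure = 0` ties in the Egger orientation are oriented
  positive.
* The reference panel's ancestry is a label: sensitivity to the panel is
  explored by re-running with another `ld_matrix`, not modelled.

## Validation problem sizes

The packaged checks run the estimand-recovery design at 200 replicates of
n = 20,000/20,000/2,000 with 30 variants; calibration at 1,000 replicates of
n = 5,000; post-translational power at 300 replicates; and the Egger regime
at 150 replicates. These sizes put Monte-Carlo error well below the
tolerances being asserted while keeping a full run in a few minutes.

## Known limitations

* No liftover, no dbSNP resolution, no GWAS-VCF output, no shrinkage LD
  estimators, no colocalisation or multivariable MR, no weighted
  median/mode estimators — the scope is the GLS family with its selection
  and diagnostic machinery.
* The Q statistic's null distribution under estimated LD is approximate;
  with small panels its quantiles are optimistic.
* Building non-target association tables from raw eQTL archives is out of
  scope; the table is an input.

## A minimal worked example

```{r, eval = FALSE}
st <- scenario("protein_causal", seed = 1)
input <- as_harmonized(st)
gls_ivw(input)
gls_egger(input)
heterogeneity(input, gls_ivw(input))
```
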