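# cismr

Drug-target (cis) Mendelian randomisation from GWAS summary statistics, for
statistical geneticists and drug-development scientists who want to test
whether perturbing a protein drug target changes disease risk using variants
in and around the encoding gene.

## The problem and the model

Genome-wide MR of a distal risk factor is vulnerable to horizontal
pleiotropy. When the exposure is a *protein*, restricting instruments to the
encoding locus changes the picture: in the causal chain

```
G --delta_GE--> E --delta_EP--> P --mu--> X --theta--> D
 \------------------phi_G------------------------------^
                    P --phi_P--------------------------^
```

(G variant, E mRNA, P protein, X downstream biomarker, D disease, with a
shared confounder U of P/X/D), the drug-target estimand is

    omega = phi_P + mu * theta

— the total effect of perturbing the protein. Any split between the direct
path `phi_P` and the biomarker path `mu * theta` is *vertical* pleiotropy
and harmless; only the pre-translational path `phi_G` biases the analysis.
If the protein is unmeasured, weighting by a downstream biomarker estimates
`omega / mu` and weighting by mRNA expression estimates `delta_EP * omega`:
different numbers, but each a valid test of `omega = 0`.

Estimation is generalised least squares over the locus's variants with
covariance `Omega[j,k] = se_y[j] se_y[k] r[j,k]` built from the outcome
standard errors and the signed LD `r`, so partially correlated variants all
contribute:

    estimate = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by        (GLS-IVW)

with an optional free intercept after orienting exposure betas non-negative
(GLS-Egger; the intercept absorbs average directional pleiotropy under the
INSIDE assumption). Around the estimators sit the selection and robustness
machinery: greedy LD clumping with grid searches over clumping thresholds
and region sizes, multicollinearity screening, whitened-residual
heterogeneity (reducing to Cochran's Q under identity LD), leverage and
Cook's diagnostics with iterative outlier removal, sequential pruning of
variants associated with non-target neighbour genes, random-subset
instrument-selection experiments with functional-annotation stratification,
and a simulation engine for the full causal chain with known estimands.

## Worked example

Simulate a locus with a known drug-target effect `omega = 0.3` (30 variants,
AR(1) LD 0.6, two GWAS of 20,000 plus a 2,000-sample LD panel), then
estimate:

```r
library(cismr)
st <- scenario("protein_causal", seed = 1)
input <- as_harmonized(st)
gls_ivw(input)
#> gls_ivw (fixed effects), 30 variant(s)
#>   estimate 0.2995 (se 0.0159), 95% CI [0.2683, 0.3307], p = 4.18e-79
gls_egger(input)
#> gls_egger (fixed effects), 30 variant(s)
#>   estimate 0.3248 (se 0.0556), 95% CI [0.2158, 0.4338], p = 5.19e-09
#>   intercept -0.0170 (se 0.0357), p = 0.635
heterogeneity(input, gls_ivw(input))
#> heterogeneity (gls_ivw): Q = 28.999 on 29 df, p = 0.465
```

The IVW estimate recovers the simulated `omega` with a tight interval; the
Egger intercept is indistinguishable from zero (no directional pleiotropy
was simulated) at the cost of a wider slope interval; Q shows no excess
heterogeneity. A clumping grid search shows the estimate is stable while
precision saturates, and picks the most liberal stable threshold:

```r
g <- select_threshold(grid_search_r2(input, thresholds = seq(0.2, 0.8, by = 0.2)))
g$points[, c("axis_value", "n_variants", "estimate", "se")]
#>   axis_value n_variants  estimate         se
#> 1        0.2         29 0.3005249 0.01604897
#> 2        0.4         30 0.2995081 0.01590473
#> 3        0.6         30 0.2995081 0.01590473
#> 4        0.8         30 0.2995081 0.01590473
g$points$axis_value[g$chosen_index]
#> [1] 0.8
```

Real data enter through `read_summary_stats()` (configurable column
dialects), `read_ld_tsv()` / `read_panel_vcf()` / `ld_from_genotypes()`,
`extract_region()` and `harmonize()`; config-driven single-target runs and
multi-outcome scans are `run_target()` / `run_scan()`, also exposed as the
`cismr` command-line tool (subcommands `simulate`, `clump`, `estimate`,
`grid`, `prune`, `subset-experiment`, `run-target`, `run-scan`).

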