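# colliderbias

Instrumental-variable correction of collider bias in genetic association
studies that condition or stratify on a heritable covariate.

## The problem

GWAS frequently analyse an outcome *conditional on* another trait:
waist–hip ratio adjusted for BMI, smoking cessation among people who ever
initiated, disease progression among cases. The conditioning variable X is
a collider — it is caused both by SNPs and by non-genetic confounders U of
X and the outcome Y — so conditioning on it opens a path G → X ← U → Y and
distorts every SNP's association with Y. Under a linear structural model
the distortion is proportional to the SNP's effect on X:

```
beta_GYC = beta_GY + b * beta_GX
```

where `beta_GYC` is the biased conditional effect, `beta_GY` the direct
effect of interest, and `b` a single genome-wide bias slope. Regressing
conditional outcome effects on covariate effects across many SNPs
identifies `b`, and `beta_GY = beta_GYC - b * beta_GX` recovers the direct
effects — an exact analogue of two-sample Mendelian randomisation with the
roles of the nuisance and target parameters swapped.

Genome-wide SNP panels are dominated by *weak instruments*: the sampling
error in `beta_GX` attenuates the naive regression slope toward zero by the
factor `var(beta_GX) / (var(beta_GX) + mean(se_GX^2))`, leaving the
conditional effects under-corrected. The package's central estimator,
**corrected weighted least squares (CWLS)**, removes this attenuation by
subtracting the weighted mean squared standard error of the covariate
effects from the regression denominator. For the zero-intercept model with
weights `w_i` summing to one:

```
b_cor = sum(w_i bx_i by_i) / ( sum(w_i bx_i^2) - sum(w_i se_xi^2) )
```

with a sandwich (heteroscedasticity-robust) standard error whose bread uses
the same corrected denominator. The zero-intercept form is invariant to
allele coding; the free-intercept form is also provided, together with a
demonstration of why coding alleles "positive on X" from the analysed
sample breaks the weak-instrument correction.

Alongside CWLS the package implements:

* the uncorrected IVW slope (standard MR estimator, for comparison);
* a two-component bivariate-normal mixture estimator (slope-hunter style)
  that isolates the cluster of valid instruments under a
  zero-modal-residual assumption, with EM fitting and bootstrap SEs;
* the mtCOJO-style total-effect path: subtract `beta_GX * beta_XY` with
  `beta_XY` estimated by IVW Mendelian randomisation;
* a Heckman two-step probit selection correction for individual-level data
  (probit first stage, inverse-Mills-ratio second stage), which motivates
  the summary-level treatment of within-stratum effects;
* a calibrated simulator of two-trait GWAS (summary-statistic and
  individual-level modes) with experiment drivers for Type-1 error, power,
  FDR, slope recovery and sign-change studies.

## Worked example

Simulate a desk-scale two-trait GWAS (20,000 independent SNPs, 1,000 each
affecting X only / Y only / both; 50% heritability per trait, a shared
confounder explaining 40% of variance; n = 20,000), harmonise the two
summary-statistic tables, and estimate the bias slope:

```r
library(colliderbias)

cfg <- scale_genome(sim_config(rho_shared = 0), 5)   # 20,000 SNPs, n = 20,000
sim <- simulate_summary(cfg, seed = 1)

pairs <- harmonise(sim$x_stats, sim$y_stats) |>
  default_weights()

fit <- cwls_zero_intercept(pairs)
fit
#> Collider-bias slope estimate (cwls_zero)
#>   b = -0.39742 (SE 0.02732), n_snps = 20000
#>   denominator: 0.00022423 uncorrected, 7.55843e-05 corrected

glance(ivw_slope(pairs))[, c("method", "b", "se_b")]
#> # A tibble: 1 × 3
#>   method      b    se_b
#>   <chr>   <dbl>   <dbl>
#> 1 ivw    -0.134 0.00923
```

The analytic slope implied by this variance partition is
`implied_bias_slope(cfg)` = −0.4. CWLS recovers it (−0.397 ± 0.027); the
uncorrected IVW slope is attenuated to −0.134 because roughly two thirds of
the weighted second moment of the estimated covariate effects is sampling
noise (compare the corrected and uncorrected denominators printed above).
Adjusting the conditional effects propagates all three uncertainty sources
into the direct-effect SEs:

```r
adjusted <- adjust_conditional(pairs, fit)
head(adjusted, 3)
#> # A tibble: 3 × 6
#>   snp_id beta_direct se_direct     z pvalue source
#>   <chr>        <dbl>     <dbl> <dbl>  <dbl> <chr>
#> 1 snp1       0.0142     0.0145 0.978  0.328 conditional
#> 2 snp2       0.00854    0.0128 0.668  0.504 conditional
#> 3 snp3       0.00650    0.0111 0.587  0.557 conditional
```

Replicate studies (`run_error_rate_experiment()`, `run_slope_experiment()`,
`run_signchange_experiment()`) wrap this pipeline and aggregate rates with
Monte-Carlo standard errors; `autoplot()` methods visualise each report.
Real summary-statistic files are read with `read_sumstats()` (configurable
column maps covering PLINK/GCTA/consortium dialects) and harmonised the
same way. A thin command-line front end lives at
`inst/cli/colliderbias.R` (subcommands `simulate`, `fit`, `adjust`,
`experiment`).

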