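---
title: "Correcting collider bias in conditional GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting collider bias in conditional GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colliderbias)
```

## The structural model

Write G for a SNP of interest, Z for an instrument, X for the conditioning
covariate (an incidence trait, a stratifying event, an adjusted-for
phenotype), Y for the outcome, and U for an unmeasured confounder of X and
Y. The package works under the linear structural equations

$$
X = Z\beta_{ZX} + G\beta_{GX} + U\beta_{UX} + \varepsilon_X,\qquad
Y = X\beta_{XY} + G\beta_{GY} + U\beta_{UY} + \varepsilon_Y .
$$

Conditioning the outcome regression on X opens the path
$G \to X \leftarrow U \to Y$, so the estimated *conditional* effect of G is
not the direct effect $\beta_{GY}$ but

$$
\beta_{GY}^{C} \;=\; \beta_{GY} + b\,\beta_{GX},
$$

with a single bias slope $b$ shared by all SNPs as long as per-SNP effects
are small. When there is no causal path $X \to Y$, $b$ equals minus the
non-direct covariance of X and Y over $\mathrm{var}(X)$: conditioning
projects out of Y everything that travels with X. `implied_bias_slope()`
evaluates this for a simulation configuration,

$$
b \;=\; -\,\frac{c_{\mathrm{conf}} +
  \rho\,\sqrt{(h^2_x/2)(h^2_y/2)}}{\mathrm{var}(X)},\qquad
\mathrm{var}(X)=1,
$$

where $c_{\mathrm{conf}}$ is the confounder's variance share and the
second term is the genetic covariance contributed by SNPs affecting both
traits (they carry half of each trait's heritability, see below). At the
default shares this gives $-0.4$, $-0.5125$ and $-0.2875$ for
$\rho \in \{0, 0.45, -0.45\}$.

Estimating $b$ by regressing estimated conditional outcome effects on
estimated covariate effects across a genome-wide SNP panel, and then
subtracting $\hat b\,\hat\beta_{GX}$ from each conditional effect, is the
package's core procedure. The identifying assumption for the
free-intercept regression is that direct effects are linearly uncorrelated
with covariate effects under the chosen allele coding; the zero-intercept
form additionally assumes the direct effects have mean zero under some
coding, and in exchange is completely invariant to coding.

## Weak instruments and the CWLS correction

With weights $w_i \propto 1/\mathrm{se}^2_{y,i}$ normalised to sum to one,
the naive weighted zero-intercept slope is
$\sum w_i \hat\beta_{GX,i}\hat\beta^{C}_{GY,i} \big/ \sum w_i
\hat\beta_{GX,i}^2$ — the IVW estimator of two-sample MR. Its denominator
contains the sampling noise of the covariate effects, so it is attenuated
by the errors-in-variables factor
$\mathrm{var}(\beta_{GX})/(\mathrm{var}(\beta_{GX}) +
\overline{\sigma^2_{GX}})$. In genome-wide panels, where most SNPs are
individually weak, this factor is far from one, and the attenuated slope
under-corrects the conditional effects.

Corrected weighted least squares subtracts the known noise contribution
from the denominator. Zero-intercept form:

$$
\hat b_{\mathrm{cor}} \;=\;
\frac{\sum_i w_i\,\hat\beta_{GX,i}\,\hat\beta^{C}_{GY,i}}
     {\sum_i w_i\,\hat\beta_{GX,i}^2 - \sum_i w_i\,\sigma^2_{GX,i}} ,
$$

and the analogous free-intercept form subtracts the same term from the
weighted variance. `cwls_zero_intercept()` and `cwls_free_intercept()`
implement these exactly; `ivw_slope()` keeps the uncorrected denominator
for comparison. Three numerical policies are attached to the estimators:

* **Weights.** Inverse variance of the conditional outcome effect,
  normalised to sum to one, is the default (`default_weights()`). It is
  the conventional choice but not the efficient one — the regression
  residual also contains the spread of true direct effects, which this
  weighting ignores — so an equal-weights scheme is exposed as an option.
* **Negative corrected denominator.** If
  $\sum w\hat\beta_{GX}^2 \le \sum w\sigma_{GX}^2$, the instruments carry
  no detectable signal beyond noise; the fit stops with an error rather
  than silently falling back to the uncorrected slope. One deliberate
  exception exists, described under allele coding below.
* **Sandwich standard error.** The residual of the slope regression mixes
  sampling error with the direct effects themselves, so it is
  heteroscedastic by construction and a model-based SE would be wrong. We
  use an HC0-type estimator whose bread is the *corrected* denominator:
  $V(\hat b) = D^{-2}\sum w_i^2(\hat\beta_{GX,i}-\bar\beta_x)^2 r_i^2$,
  with $r_i$ the weighted-fit residual and $\bar\beta_x$ the weighted mean
  of the covariate effects (zero in the zero-intercept model). When all
  $\sigma_{GX,i}=0$ this reduces exactly to the textbook robust variance
  of a weighted regression, which is how the tests pin it down against an
  independent implementation. The SE does not account for the sampling
  noise of the correction term itself, so at very low instrument
  signal-to-noise it can drift from the replicate-to-replicate spread;
  the Monte-Carlo calibration test bounds this at the scales the package
  targets.

## Allele coding

Flipping which allele of a SNP is "the" effect allele negates
$(\hat\beta_{GX}, \hat\beta^{C}_{GY})$ jointly. The zero-intercept
estimators are exactly invariant under any such flips (term-wise products
are unchanged), and the test suite asserts bit-identical slopes under
random subset negation.

A common convention codes every allele to have a *positive estimated*
effect on X before running the free-intercept regression. Because the signs
are chosen from the same noisy estimates the regression uses, the sampling
errors of the recoded effects no longer have mean zero: folding a
mean-zero noise distribution transfers about $2/\pi$ of its second moment
into the squared mean, which the free-intercept fit subtracts out. The
weak-instrument correction then overshoots — under the package's study
conditions the corrected denominator actually becomes negative — and the
resulting slope is small and wrong-signed, leaving the conditional effects
essentially unadjusted and the Type-1 error inflated. Because demonstrating
this failure mode is part of the simulation study,
`cwls_free_intercept(allow_negative_denominator = TRUE)` computes the
ratio regardless; only the experiment driver's positive-coding arm uses
it. `recode_positive_on_x()` performs the coding itself (it is idempotent
and harmless for strongly associated SNP sets, which is why it remains a
useful export for MR-style analyses of genome-wide-significant
instruments).

## Mixture estimator (valid-instrument clustering)

When many SNPs have direct effects on the outcome, the regression backbone
formed by the SNPs acting only through X can still identify $b$ if it is
the single most common pattern (a zero-modal-residual assumption).
`fit_slopehunter()` models the thresholded pairs
$(\hat\beta_{GX}, \hat\beta^{C}_{GY})$ as a two-component zero-mean
bivariate normal mixture: component A constrains
$\hat\beta^{C}_{GY} = b\,\hat\beta_{GX} + \text{noise}$; component B is an
unconstrained zero-mean bivariate normal absorbing everything else.
Zero-mean components keep the whole fit sign-symmetric, matching the
coding invariance of the zero-intercept regression.

Design choices, made once:

* **Fitting.** Plain expectation-maximisation with moment M-steps — these
  are the exact M-steps of the Gaussian model, so the observed-data
  log-likelihood is non-decreasing (asserted by a test). Running the
  weak-instrument correction *inside* the M-step would break that
  guarantee, so the correction is instead applied once at convergence: the
  reported slope is the responsibility-weighted corrected least-squares
  slope $\sum r_iw_i\hat\beta_x\hat\beta_y / (\sum r_iw_i\hat\beta_x^2 -
  \sum r_iw_i\sigma_x^2)$, with $r_i$ the posterior probability of the
  proportional component.
* **Initialisation.** k-means on the ratios
  $\hat\beta_y/\hat\beta_x$ among SNPs with $|\hat\beta_x|$ above its
  median seeds the first run; 24 further restarts draw the starting slope
  from random ratio quantiles; the best log-likelihood wins. Variance
  parameters are floored at $10^{-12}$ and the free covariance gets a
  $10^{-8}$ ridge so exactly-collinear clusters (noise-free fixtures)
  remain fittable.
* **Uncertainty.** Bootstrap over SNPs (default B = 200), refitting each
  resample warm-started from the full-data solution. A `pi0` argument can
  freeze the mixing proportion; at `pi0 = 1` the estimator reduces exactly
  to zero-intercept CWLS on the thresholded SNPs, a useful consistency
  anchor.
* **Thresholding.** Default p-value threshold on the X association is
  $10^{-3}$; it is a tuning parameter, exposed everywhere.

## Adjustment and its standard errors

`adjust_conditional()` returns $\hat\beta_{GY} = \hat\beta^{C}_{GY} -
\hat b\,\hat\beta_{GX}$ with delta-method variance

$$
\mathrm{se}^2 \;=\; \mathrm{se}_y^2 + \hat b^2\,\mathrm{se}_x^2 +
\hat\beta_{GX}^2\,\mathrm{se}_b^2 ,
$$

treating the three inputs as independent. The neglected sampling
covariance between $\hat\beta^{C}_{GY}$ and $\hat\beta_{GX}$ is
approximately zero once the outcome regression conditions on X, and sample
overlap between the two GWAS does not reintroduce it (the overlap-induced
covariance travels through the confounder term that the slope explicitly
removes). The genome-wide $\mathrm{se}_b$ is applied to every SNP; the
per-SNP contribution of any single SNP to the genome-wide fit is
$O(1/m)$ and ignored. Adjusted SEs therefore always exceed the unadjusted
ones when $\hat\beta_{GX}\ne 0$ — the price of the correction is power.

`adjust_total_mtcojo()` implements the total-effect path: subtract
$\hat\beta_{XY}\hat\beta_{GX}$ from *marginal* outcome effects, with
$\hat\beta_{XY}$ from `estimate_beta_xy_ivw()` (fixed-effect IVW over
instruments). The two paths estimate the same direct effects from
different inputs; on one simulated dataset at consortium-scale sample size
the acceptance suite checks their adjusted effects correlate above 0.95
among index SNPs, mirroring the near-unit correlation seen in real
two-path analyses.

## Within-stratum effects: the Heckman two-step

When Y is only observed in a stratum of a binary X (cases, initiators,
respondents), the package provides the classical selection correction on
individual-level data. Stage one fits
$\Pr(X=1\mid G,Z) = \Phi(v)$, $v = \alpha + Z\beta_{ZX} + G\beta_{GX}$, by
maximum-likelihood probit (`stats::glm`; quasi-perfect separation is
detected and refused). Stage two regresses Y among the selected on G and
the truncated-normal mean correction.

One sign convention deserves care. With selection occurring when
$v + e > 0$ for a standard-normal latent error $e$ (so that
$\Pr(X{=}1)=\Phi(v)$), the mean of $e$ among the selected is
$\phi(v)/\Phi(v)$ — a *decreasing* function of the index: individuals
whose observables already guarantee selection carry no information about
$e$. The inverse Mills ratio as conventionally written,
$\lambda(v)=\phi(v)/(1-\Phi(v))$, is this same function evaluated at
$-v$; taken literally at $+v$ it grows like $v$ and cannot be the
regressor. `inverse_mills()` implements $\lambda(\cdot)$ exactly as
defined (stably, on the log scale, so it is accurate for $|v|$ in the
hundreds), and `heckman_second_stage()` feeds it the negated fitted
index. The coefficient $\gamma$ on this term absorbs the
selection-on-unobservables link; with `gamma_zero = TRUE` the stage
reduces exactly to the naive within-stratum regression. Second-stage SEs
are conventional least-squares SEs — they ignore the first-stage
uncertainty — because the model serves here as motivation and as a
cross-check of the summary-level methods, not as the headline estimator.

For small SNP effects a first-order expansion of the Mills term makes the
within-stratum coefficient of G linear in $\beta_{GX}$ — the same form as
the conditional-effect bias — which licenses applying the summary-level
slope machinery to within-stratum GWAS. The test suite verifies this
linearity on a grid of selection effects (common random numbers across
the grid isolate the deterministic trend) and checks that per-SNP Heckman
estimates agree closely with CWLS-adjusted summary effects on data drawn
from the probit selection model.

## The synthetic-data generator

`sim_config()` encodes the study conditions: independent biallelic SNPs in
Hardy–Weinberg equilibrium, MAF uniform on (0.01, 0.49); disjoint causal
classes affecting X only, Y only, or both (5,000 each in a 100,000-SNP
genome at full scale); per-allele effects normal, rescaled so each class
explains exactly its heritability share; both traits with 50%
heritability, a shared confounder at 40%, residual 10%; no causal
$X \to Y$ path, so the entire X-association of conditional effects is
collider bias. Decisions the configuration fixes:

* **Heritability split.** The trait-only and shared classes split each
  trait's heritability equally (0.25 + 0.25). This is the only split
  consistent with the three analytic true slopes above, which anchor the
  whole design.
* **Shared-effect correlation.** `rho_shared` is the correlation between
  the shared SNPs' effects on X and on Y (not a genome-wide genetic
  correlation); effects are drawn jointly and rescaled, so the realised
  correlation fluctuates by $\approx 1/\sqrt{m_{\text{shared}}}$ around
  the target.
* **Sample size.** n is not part of the published variance partition; the
  default is 20,000 per GWAS. Two observations support it: it produces
  realistic per-SNP power at desk scale, and the degree of unadjusted
  Type-1 inflation it implies is consistent with the operating
  characteristics the corrected estimators are benchmarked against.
  Quantities that depend on n — power, the magnitude of unadjusted
  inflation, sign-change rates — are treated as directional throughout;
  nominal Type-1 error of corrected tests and slope recovery are
  n-robust and treated quantitatively.

Two generation modes share the same truth draw. **Summary mode** draws
effect estimates directly: $\hat\beta_{GX}\sim N(\beta_{GX},
1/(n\cdot 2pq))$ and $\hat\beta^{C}_{GY}\sim N(\beta_{GY}+b\beta_{GX},
\mathrm{var}(Y|X)/(n\cdot 2pq))$ with $\mathrm{var}(Y|X) = 1 -
\mathrm{cov}(X,Y)^2$, sampling errors independent (justified because the
outcome regression conditions on X), reported SEs equal to the true
sampling SDs. **Individual mode** builds genotypes and traits from the
structural equations and runs the actual per-SNP regressions (Y on G and
X jointly; X on G), in closed form from cross-products; it is the
reference implementation, and a Kolmogorov–Smirnov test in the suite
confirms the two modes agree in distribution on matched truths. Individual
mode refuses genotype matrices beyond a memory budget (2×10⁸ entries)
rather than paging; summary mode covers genome scale.

What the generator does **not** emulate: linkage disequilibrium (inputs
are assumed LD-pruned, as in real applications of these methods),
population structure, binary/liability-scale traits at genome scale,
winner's-curse selection of instruments from the same data, and
platform-level allele-strand mess (the harmoniser's ambiguity filter
exists for real files but simulated alleles are clean). Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to LD or stratification.

## Experiment drivers and reproducibility

`run_error_rate_experiment()` repeats simulate → fit → adjust → test and
aggregates Type-1 error (X-only SNPs), power (shared SNPs) and FDR
(Type-1/(Type-1+power), the two classes being equally sized) with
Monte-Carlo SEs; `run_slope_experiment()` sweeps the shared-effect
correlation grid and reports mean slope, empirical SD and mean estimated
SE against the analytic truth; `run_signchange_experiment()` estimates how
often adjustment flips a nominally significant estimate toward or away
from the true direction, among SNPs with true outcome effects significant
*after* adjustment (the both-analyses denominator is logged alongside).
Replicate seeds derive from the master seed by a single
`sample.int(.Machine$integer.max - 1, reps)` draw; identical seed and
configuration give bit-identical results.

The default problem sizes used by the tests and the acceptance script are
a proportional 5-fold shrink of the full design — 20,000 SNPs with 1,000
per causal class, n = 20,000, 200 replicates. Rate and slope estimands are
invariant to proportional genome scaling, which is what makes the shrink
legitimate; the mixture estimator joins error-rate runs on a reduced
replicate count because of its EM cost.

## Known limitations

* The delta-method SE of adjusted effects ignores the
  $\hat b$–$\hat\beta_{GX}$ covariance contributed by the tested SNP
  itself ($O(1/m)$) and any covariance between the two input GWAS beyond
  what conditioning removes.
* The CWLS sandwich SE does not propagate the uncertainty of the
  weak-instrument correction term; at instrument signal-to-noise well
  below the tested range it will understate the spread.
* The mixture estimator's unconstrained component is a single zero-mean
  Gaussian; strongly non-Gaussian direct-effect distributions (e.g. a few
  huge effects) are handled only insofar as the proportional cluster stays
  modal.
* Heckman second-stage SEs are conventional, not the fully corrected
  two-step covariance.
* No LD handling anywhere: inputs must be pruned.
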