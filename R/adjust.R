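#' Adjust conditional effects for collider bias
#'
#' Converts collider-biased conditional outcome effects into direct-effect
#' estimates: `beta_direct = beta_y - b * beta_x`, where `b` is the fitted
#' bias slope. Standard errors propagate the uncertainty of all three
#' inputs by the delta method,
#' `se^2 = se_y^2 + b^2 se_x^2 + beta_x^2 se_b^2`,
#' neglecting the sampling covariance between the conditional outcome
#' effect and the covariate effect (small once the outcome regression
#' conditions on X, and unaffected by sample overlap). The genome-wide
#' `se_b` is applied to every SNP.
#'
#' @param pairs A harmonised pair tibble whose `beta_y` holds the
#'   *conditional* outcome effects.
#' @param slope A `slope_estimate` (any method).
#' @return A tibble: `snp_id`, `beta_direct`, `se_direct`, `z`, `pvalue`,
#'   `source = "conditional"`.
#' @export
adjust_conditional <- function(pairs, slope) {
  b <- if (inherits(slope, "slope_estimate")) slope$b else as.numeric(slope)
  se_b <- if (inherits(slope, "slope_estimate")) slope$se_b else 0
  if (!is.finite(b)) stop("slope estimate is not finite", call. = FALSE)
  if (is.na(se_b)) se_b <- 0
  adjust_table(pairs, b, se_b, source = "conditional")
}

#' Adjust total effects via a Mendelian-randomisation estimate (mtCOJO path)
#'
#' Subtracts the covariate-mediated component from *total* SNP effects on
#' the outcome: `beta_direct = beta_y - beta_xy * beta_x`, where `beta_xy`
#' is the causal effect of X on Y estimated by Mendelian randomisation.
#' Standard-error propagation follows [adjust_conditional()] with the MR
#' estimate playing the role of the slope.
#'
#' @param total_pairs A harmonised pair tibble whose `beta_y` holds total
#'   (marginal) outcome effects.
#' @param mr An `mr_estimate` from [estimate_beta_xy_ivw()], or a number.
#' @return A tibble as in [adjust_conditional()], `source = "total"`.
#' @export
adjust_total_mtcojo <- function(total_pairs, mr) {
  bxy <- if (inherits(mr, "mr_estimate")) mr$beta_xy else as.numeric(mr)
  se <- if (inherits(mr, "mr_estimate")) mr$se else 0
  if (is.na(se)) se <- 0
  adjust_table(total_pairs, bxy, se, source = "total")
}

adjust_table <- function(pairs, coef, se_coef, source) {
  beta_direct <- pairs$beta_y - coef * pairs$beta_x
  se_direct <- sqrt(pairs$se_y^2 + coef^2 * pairs$se_x^2 +
                      pairs$beta_x^2 * se_coef^2)
  z <- beta_direct / se_direct
  tibble::tibble(
    snp_id = pairs$snp_id,
    beta_direct = beta_direct,
    se_direct = se_direct,
    z = z,
    pvalue = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    source = source
  )
}

#' Inverse-variance-weighted MR estimate of the X-on-Y causal effect
#'
#' Fixed-effect IVW estimator over instruments for X: with `beta_y` here
#' holding each instrument's *total* effect on the outcome,
#' `beta_xy = sum(w bx by) / sum(w bx^2)` with `w = 1/se_y^2`, and
#' fixed-effect standard error `1 / sqrt(sum(bx^2 / se_y^2))`.
#'
#' @param instruments A harmonised pair tibble of instruments (typically
#'   genome-wide-significant X SNPs) with total-effect `beta_y`.
#' @return An object of class `mr_estimate`: `beta_xy`, `se`, `n_snps`,
#'   `method = "ivw"`.
#' @export
estimate_beta_xy_ivw <- function(instruments) {
  if (nrow(instruments) == 0L) stop("no instruments supplied", call. = FALSE)
  w <- 1 / instruments$se_y^2
  denom <- sum(w * instruments$beta_x^2)
  if (denom <= 0) stop("all instrument effects on X are zero", call. = FALSE)
  structure(
    list(beta_xy = sum(w * instruments$beta_x * instruments$beta_y) / denom,
         se = 1 / sqrt(denom),
         n_snps = nrow(instruments),
         method = "ivw"),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("IVW MR estimate: beta_xy = %.5f (SE %.5f), %d instruments\n",
              x$beta_xy, x$se, x$n_snps))
  invisible(x)
}

#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  z <- x$beta_xy / x$se
  tibble::tibble(term = "beta_xy", estimate = x$beta_xy, std.error = x$se,
                 statistic = z,
                 p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
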