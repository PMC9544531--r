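#' Assign default inverse-variance weights to a pair table
#'
#' Weights each SNP by the inverse sampling variance of its conditional
#' outcome effect, normalised to sum to one: `w_i = (1/se_y_i^2) / sum(1/se_y^2)`.
#' This is the conventional weighting for the bias-slope regression. It is
#' not the most efficient choice — the regression residual also carries the
#' variance of the direct effects, which inverse-variance weighting ignores
#' — so `scheme = "equal"` (`w_i = 1/m`) is offered as an alternative.
#'
#' @param pairs A harmonised pair tibble (see [harmonise()]).
#' @param scheme `"invvar"` (default) or `"equal"`.
#' @return `pairs` with a `weight` column summing to 1.
#' @export
default_weights <- function(pairs, scheme = c("invvar", "equal")) {
  scheme <- match.arg(scheme)
  if (scheme == "invvar") {
    if (any(!is.finite(pairs$se_y) | pairs$se_y <= 0)) {
      stop("all se_y must be finite and positive for inverse-variance weights",
           call. = FALSE)
    }
    w <- 1 / pairs$se_y^2
  } else {
    w <- rep(1, nrow(pairs))
  }
  pairs$weight <- w / sum(w)
  pairs
}

new_slope_estimate <- function(b, se_b, intercept, se_intercept, method,
                               n_snps, diagnostics) {
  structure(
    list(b = b, se_b = se_b, intercept = intercept,
         se_intercept = se_intercept, method = method, n_snps = n_snps,
         diagnostics = diagnostics),
    class = "slope_estimate"
  )
}

pair_weights <- function(pairs) {
  if (!"weight" %in% names(pairs)) {
    pairs <- default_weights(pairs)
  }
  if (any(pairs$weight < 0)) stop("weights must be nonnegative", call. = FALSE)
  pairs$weight / sum(pairs$weight)
}

#' Inverse-variance-weighted (uncorrected) bias slope
#'
#' Zero-intercept weighted regression of the conditional outcome effects on
#' the covariate effects: `b = sum(w bx by) / sum(w bx^2)`. This is the
#' standard IVW estimator of two-sample Mendelian randomisation applied to
#' the collider-bias problem; it makes no correction for the sampling error
#' in `beta_x`, so with many weak instruments it is attenuated toward zero
#' by the factor `var(beta_x) / (var(beta_x) + mean(se_x^2))`.
#'
#' @param pairs A harmonised pair tibble; a missing `weight` column is
#'   filled by [default_weights()].
#' @return A `slope_estimate` object; see [tidy.slope_estimate()].
#' @export
ivw_slope <- function(pairs) {
  w <- pair_weights(pairs)
  denom <- sum(w * pairs$beta_x^2)
  if (denom <= 0) {
    stop("degenerate fit: all beta_x are zero", call. = FALSE)
  }
  b <- sum(w * pairs$beta_x * pairs$beta_y) / denom
  est <- new_slope_estimate(
    b = b, se_b = NA_real_, intercept = 0, se_intercept = NA_real_,
    method = "ivw", n_snps = nrow(pairs),
    diagnostics = list(denom_uncorrected = denom, denom_corrected = denom)
  )
  if (nrow(pairs) < 2L) return(est)  # Wald ratio; SE undefined
  sandwich_se(pairs, est)
}

#' Corrected weighted least squares, zero-intercept (CWLS)
#'
#' The weak-instrument-corrected bias-slope estimator under the assumption
#' that direct effects have mean zero under some allele coding:
#' \deqn{\hat b_{cor} = \frac{\sum w_i \hat\beta_{Xi} \hat\beta_{Yi}}
#'   {\sum w_i \hat\beta_{Xi}^2 - \sum w_i \sigma_{Xi}^2}.}
#' The subtraction of the weighted mean squared standard error of the
#' X-effects removes the errors-in-variables attenuation that the IVW
#' estimator suffers. Because no intercept is fitted, the estimate is
#' invariant to the allele coding of every SNP.
#'
#' @inheritParams ivw_slope
#' @return A `slope_estimate` with sandwich standard error.
#' @export
cwls_zero_intercept <- function(pairs) {
  w <- pair_weights(pairs)
  denom_raw <- sum(w * pairs$beta_x^2)
  correction <- sum(w * pairs$se_x^2)
  denom <- denom_raw - correction
  if (denom <= 0) {
    stop("weak-instrument failure: corrected denominator is not positive; ",
         "the instruments carry no signal beyond their sampling noise",
         call. = FALSE)
  }
  b <- sum(w * pairs$beta_x * pairs$beta_y) / denom
  est <- new_slope_estimate(
    b = b, se_b = NA_real_, intercept = 0, se_intercept = NA_real_,
    method = "cwls_zero", n_snps = nrow(pairs),
    diagnostics = list(denom_uncorrected = denom_raw, denom_corrected = denom)
  )
  if (nrow(pairs) < 2L) return(est)
  sandwich_se(pairs, est)
}

#' Corrected weighted least squares with free intercept
#'
#' Weighted errors-in-variables regression of `beta_y` on `beta_x` with an
#' intercept, correcting the denominator for the sampling variance of the
#' X-effects (with weights normalised to sum to 1):
#' \deqn{\hat b_{cor} = \frac{\sum w_i b_{xi} b_{yi} - (\sum w_i b_{xi})(\sum w_i b_{yi})}
#'  {\sum w_i b_{xi}^2 - (\sum w_i b_{xi})^2 - \sum w_i \sigma_{Xi}^2},}
#' with intercept \eqn{\hat\alpha = \sum w_i b_{yi} - \hat b \sum w_i b_{xi}}.
#' Unlike the zero-intercept form this estimator is sensitive to allele
#' coding; coding alleles positive-on-X from the analysed sample biases the
#' sampling errors and invalidates the correction (see
#' [recode_positive_on_x()]).
#'
#' @inheritParams ivw_slope
#' @param allow_negative_denominator Compute the ratio even when the
#'   corrected denominator is not positive, instead of raising an error.
#'   A non-positive denominator means the weak-instrument correction has
#'   removed all apparent signal — the estimate is then meaningless as a
#'   bias slope, but computing it is exactly how the failure mode of
#'   positive-on-X allele coding manifests, so the experiment drivers
#'   enable this for that demonstration arm only.
#' @return A `slope_estimate` with sandwich standard errors for slope and
#'   intercept.
#' @export
cwls_free_intercept <- function(pairs, allow_negative_denominator = FALSE) {
  if (nrow(pairs) < 2L) stop("need at least 2 SNPs for a free-intercept fit",
                             call. = FALSE)
  w <- pair_weights(pairs)
  mx <- sum(w * pairs$beta_x)
  my <- sum(w * pairs$beta_y)
  denom_raw <- sum(w * pairs$beta_x^2) - mx^2
  correction <- sum(w * pairs$se_x^2)
  denom <- denom_raw - correction
  if (denom <= 0 && !allow_negative_denominator) {
    stop("weak-instrument failure: corrected denominator is not positive; ",
         "the instruments carry no signal beyond their sampling noise",
         call. = FALSE)
  }
  b <- (sum(w * pairs$beta_x * pairs$beta_y) - mx * my) / denom
  alpha <- my - b * mx
  est <- new_slope_estimate(
    b = b, se_b = NA_real_, intercept = alpha, se_intercept = NA_real_,
    method = "cwls_free", n_snps = nrow(pairs),
    diagnostics = list(denom_uncorrected = denom_raw, denom_corrected = denom)
  )
  sandwich_se(pairs, est)
}

#' Heteroscedasticity-robust standard error for a slope estimate
#'
#' HC0-type sandwich variance for the weighted bias-slope regression, with
#' the bread term using the weak-instrument-corrected denominator:
#' \deqn{V(\hat b) = D^{-2} \sum w_i^2 (b_{xi} - \bar b_x)^2 r_i^2,}
#' where `D` is the (corrected) denominator of the fit, `r_i` the residual
#' `b_yi - intercept - b * b_xi`, and `bar b_x` the weighted mean of
#' `beta_x` (zero for zero-intercept fits). Robustness matters here because
#' the regression residual mixes per-SNP sampling error with the direct
#' effects themselves, so it is heteroscedastic by construction. The
#' intercept SE (free-intercept fits) uses the analogous robust form.
#'
#' Called automatically by the fitting functions; exposed for refitting
#' after weight changes.
#'
#' @param pairs The pair tibble the estimate was fitted on.
#' @param estimate A `slope_estimate` from one of the fitters.
#' @return The estimate with `se_b` (and `se_intercept`) filled in.
#' @export
sandwich_se <- function(pairs, estimate) {
  if (estimate$n_snps < 2L) {
    stop("standard error undefined with fewer than 2 SNPs", call. = FALSE)
  }
  w <- pair_weights(pairs)
  D <- estimate$diagnostics$denom_corrected
  r <- pairs$beta_y - estimate$intercept - estimate$b * pairs$beta_x
  bx_bar <- if (identical(estimate$method, "cwls_free")) sum(w * pairs$beta_x) else 0
  v <- sum(w^2 * (pairs$beta_x - bx_bar)^2 * r^2) / D^2
  estimate$se_b <- sqrt(v)
  if (identical(estimate$method, "cwls_free")) {
    # robust intercept variance for the weighted fit: alpha = sum w (by - b*bx)
    # so V(alpha) = sum w_i^2 r_i^2 + bx_bar^2 V(b) (cross-term dropped, HC0)
    estimate$se_intercept <- sqrt(sum(w^2 * r^2) + bx_bar^2 * v)
  }
  estimate
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat("Collider-bias slope estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  b = %.5f (SE %.5f), n_snps = %d\n", x$b, x$se_b, x$n_snps))
  if (identical(x$method, "cwls_free")) {
    cat(sprintf("  intercept = %.5f (SE %.5f)\n", x$intercept, x$se_intercept))
  }
  d <- x$diagnostics
  cat(sprintf("  denominator: %.6g uncorrected, %.6g corrected\n",
              d$denom_uncorrected, d$denom_corrected))
  invisible(x)
}

#' Tidy a slope estimate
#'
#' @param x A `slope_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`slope`, and `intercept`
#'   for free-intercept fits): `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy slope_estimate
#' @export
tidy.slope_estimate <- function(x, ...) {
  terms <- tibble::tibble(
    term = "slope", estimate = x$b, std.error = x$se_b
  )
  if (identical(x$method, "cwls_free")) {
    terms <- dplyr::bind_rows(
      terms,
      tibble::tibble(term = "intercept", estimate = x$intercept,
                     std.error = x$se_intercept)
    )
  }
  terms$statistic <- terms$estimate / terms$std.error
  terms$p.value <- 2 * stats::pnorm(abs(terms$statistic), lower.tail = FALSE)
  terms
}

#' One-row summary of a slope estimate
#'
#' @param x A `slope_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_snps`, `b`, `se_b`, `intercept`,
#'   `se_intercept`, `denom_uncorrected`, `denom_corrected`.
#' @method glance slope_estimate
#' @export
glance.slope_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snps = x$n_snps, b = x$b, se_b = x$se_b,
    intercept = x$intercept, se_intercept = x$se_intercept,
    denom_uncorrected = x$diagnostics$denom_uncorrected,
    denom_corrected = x$diagnostics$denom_corrected
  )
}

#' Fit a bias slope by name
#'
#' Dispatch wrapper used by the experiment drivers and the command-line
#' interface.
#'
#' @param pairs A harmonised pair tibble.
#' @param method One of `"ivw"`, `"cwls0"`, `"cwls"` (free intercept) or
#'   `"slopehunter"`.
#' @param ... Passed on to the underlying fitter (e.g. `p_threshold`,
#'   `n_boot`, `seed` for the mixture estimator).
#' @return A `slope_estimate`.
#' @export
fit_slope <- function(pairs, method = c("cwls0", "ivw", "cwls", "slopehunter"),
                      ...) {
  method <- match.arg(method)
  switch(method,
    ivw = ivw_slope(pairs),
    cwls0 = cwls_zero_intercept(pairs),
    cwls = cwls_free_intercept(pairs),
    slopehunter = fit_slopehunter(pairs, ...)$estimate
  )
}
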