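#' Probit first stage of the Heckman selection correction
#'
#' Maximum-likelihood probit regression of a binary selection event (e.g.
#' disease incidence, study inclusion) on a genotype and an instrument:
#' `Pr(X = 1 | G, Z) = pnorm(alpha + bZX * z + bGX * g)`. Fitted by the
#' Newton-type iteratively reweighted least squares of [stats::glm()].
#'
#' @param x Binary 0/1 selection vector; both classes must be present.
#' @param g Genotype (or any exposure) vector.
#' @param z Instrument vector.
#' @return A list: `coefficients` (named `alpha`, `z`, `g`), `se`,
#'   `linear_predictor` (fitted probit index), `converged`, and the
#'   underlying `glm` object as `model`.
#' @export
probit_first_stage <- function(x, g, z) {
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) stop("x must be binary 0/1", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("selection vector has a single class; probit is undefined",
         call. = FALSE)
  }
  dat <- data.frame(x = x, g = g, z = z)
  fit <- suppressWarnings(
    stats::glm(x ~ z + g, family = stats::binomial(link = "probit"),
               data = dat)
  )
  co <- stats::coef(fit)
  co[is.na(co)] <- 0  # rank-deficient (constant) regressors drop out
  if (any(!is.finite(co)) || any(abs(co) > 20)) {
    stop("probit first stage suggests (quasi-)perfect separation: ",
         "coefficients diverged (max |coef| = ",
         format(max(abs(co))), ")", call. = FALSE)
  }
  names(co) <- c("alpha", "z", "g")
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(co)
  list(coefficients = co, se = se,
       linear_predictor = as.numeric(stats::predict(fit, type = "link")),
       converged = fit$converged, model = fit)
}

#' Inverse Mills ratio
#'
#' `phi(v) / (1 - Phi(v))`, the hazard function of the standard normal,
#' evaluated elementwise. Computed on the log scale
#' (`exp(log phi(v) - log(1 - Phi(v)))`) so it remains accurate for large
#' `|v|`, where the naive ratio overflows to `0/0`; for large positive `v`
#' it approaches its asymptote `v + 1/v - 2/v^3 + ...`, and for
#' `v -> -Inf` it vanishes.
#'
#' @param linear_predictor Numeric vector.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' inverse_mills(0)        # sqrt(2/pi)
#' inverse_mills(c(-40, 10))
inverse_mills <- function(linear_predictor) {
  exp(stats::dnorm(linear_predictor, log = TRUE) -
        stats::pnorm(linear_predictor, lower.tail = FALSE, log.p = TRUE))
}

#' Heckman second stage: outcome regression with selection correction
#'
#' Among selected individuals (`x = 1`), regresses the outcome on the
#' genotype and the truncated-normal mean correction from the first stage.
#' With selection `X = 1` occurring when `v + e > 0` for probit index `v`
#' and latent standard-normal error `e`, the mean of `e` among the
#' selected is `phi(v)/Phi(v) = inverse_mills(-v)`; including this term as
#' a regressor with free coefficient `gamma` absorbs the selection-induced
#' dependence between the outcome error and the regressors, so the
#' genotype coefficient estimates the direct effect `beta_GY`. Standard
#' errors are the conventional least-squares ones.
#'
#' @param y Outcome vector, observed for selected individuals only (its
#'   length must equal the number of `x = 1` cases in the first stage, or
#'   the full length with non-selected entries ignored).
#' @param g,z Covariate vectors on the full sample (same length as the
#'   first stage's data).
#' @param first_stage Result of [probit_first_stage()].
#' @param selected Logical/0-1 vector marking the selected individuals.
#' @param gamma_zero Impose `gamma = 0`, i.e. assume no selection on
#'   unobservables; the fit then reduces exactly to the ordinary
#'   within-stratum regression of the outcome on the genotype.
#' @return A list of class `heckman_fit`: `beta_gy`, `se_gy`, `gamma`,
#'   `se_gamma`, `probit_coefs`, and the second-stage `lm` as `model`.
#' @export
heckman_second_stage <- function(y, g, z, first_stage, selected,
                                 gamma_zero = FALSE) {
  sel <- as.logical(selected)
  lp <- first_stage$linear_predictor[sel]
  imr <- inverse_mills(-lp)
  g_sel <- g[sel]
  y_sel <- if (length(y) == length(sel)) y[sel] else y
  if (length(y_sel) != sum(sel)) {
    stop("y must cover the selected individuals", call. = FALSE)
  }
  if (gamma_zero) {
    fit <- stats::lm(y_sel ~ g_sel)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    return(structure(
      list(beta_gy = unname(co["g_sel"]), se_gy = unname(se["g_sel"]),
           gamma = 0, se_gamma = NA_real_,
           probit_coefs = first_stage$coefficients, model = fit),
      class = "heckman_fit"
    ))
  }
  if (stats::sd(imr) < 1e-10 ||
      abs(stats::cor(g_sel, imr)) > 0.999) {
    warning("inverse Mills term (nearly) collinear with genotype; ",
            "selection correction is weakly identified", call. = FALSE)
  }
  fit <- stats::lm(y_sel ~ g_sel + imr)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(beta_gy = unname(co["g_sel"]), se_gy = unname(se["g_sel"]),
         gamma = unname(co["imr"]), se_gamma = unname(se["imr"]),
         probit_coefs = first_stage$coefficients, model = fit),
    class = "heckman_fit"
  )
}

#' Two-step Heckman correction in one call
#'
#' Convenience wrapper running [probit_first_stage()] then
#' [heckman_second_stage()].
#'
#' @param data A data frame (or tibble) with columns `x` (binary
#'   selection), `g`, `z`, and `y` (outcome; values where `x = 0` are
#'   ignored).
#' @return A `heckman_fit`.
#' @export
heckman_two_step <- function(data) {
  fs <- probit_first_stage(data$x, data$g, data$z)
  heckman_second_stage(data$y, data$g, data$z, fs, selected = data$x == 1)
}

#' @export
print.heckman_fit <- function(x, ...) {
  cat("Heckman two-step selection-corrected fit\n")
  cat(sprintf("  beta_GY = %.5f (SE %.5f)\n", x$beta_gy, x$se_gy))
  cat(sprintf("  gamma (inverse-Mills coef) = %.5f (SE %.5f)\n",
              x$gamma, x$se_gamma))
  cat("  probit first stage: ",
      paste(sprintf("%s = %.4f", names(x$probit_coefs), x$probit_coefs),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy heckman_fit
#' @export
tidy.heckman_fit <- function(x, ...) {
  est <- c(x$beta_gy, x$gamma)
  se <- c(x$se_gy, x$se_gamma)
  z <- est / se
  tibble::tibble(term = c("beta_gy", "gamma"), estimate = est,
                 std.error = se, statistic = z,
                 p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' @method glance heckman_fit
#' @export
glance.heckman_fit <- function(x, ...) {
  tibble::tibble(beta_gy = x$beta_gy, se_gy = x$se_gy, gamma = x$gamma,
                 se_gamma = x$se_gamma,
                 n_selected = stats::nobs(x$model))
}
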