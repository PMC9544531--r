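#' Mixture-model bias-slope estimation (slope-hunter style)
#'
#' Identifies the cluster of SNPs that act on the outcome only through the
#' covariate X, by fitting a two-component zero-mean bivariate normal
#' mixture to the pairs (`beta_x`, `beta_y`) of SNPs passing a p-value
#' threshold on X, and estimates the bias slope from that cluster. One
#' component constrains the outcome effect to be proportional to the
#' covariate effect (`beta_y = b * beta_x` plus noise) — the valid
#' instruments; the other is an unconstrained zero-mean bivariate normal
#' absorbing SNPs with direct effects. The underlying assumption is that
#' the most common residual pattern comes from SNPs with no direct effect
#' (a zero-modal-residual assumption), so the proportional cluster pins
#' down `b` even when many SNPs violate instrument validity.
#'
#' Estimation is by expectation-maximisation with multiple restarts (the
#' first initialised by k-means on the ratios `beta_y / beta_x` among SNPs
#' with `|beta_x|` above its median, the rest randomised), keeping the fit
#' with the best observed-data log-likelihood. The reported slope applies
#' the weak-instrument correction to a responsibility-weighted
#' least-squares fit at convergence:
#' `b = sum(r w bx by) / (sum(r w bx^2) - sum(r w se_x^2))`, with `r` the
#' posterior probability of the proportional component. Its standard error
#' is a bootstrap over SNPs (resampling pairs, refitting warm-started from
#' the full-data solution).
#'
#' @param pairs A harmonised pair tibble (see [harmonise()]).
#' @param p_threshold Keep SNPs with X-association p-value at or below
#'   this before clustering. Default `1e-3`.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param n_restarts Number of EM initialisations (first is k-means based).
#' @param n_boot Bootstrap resamples for the slope standard error; `0`
#'   skips the bootstrap (`se_b` is then `NA`).
#' @param seed Integer seed controlling restarts and bootstrap; `NULL`
#'   leaves the RNG state alone.
#' @param pi0 Optional fixed mixing proportion for the proportional
#'   component; `pi0 = 1` reduces the estimator to zero-intercept CWLS on
#'   the thresholded SNPs.
#'
#' @return A list of class `slopehunter_fit` with elements
#'   `estimate` (a `slope_estimate`, method `"slopehunter"`) and `mixture`
#'   (fields `b`, `pi0`, `responsibilities`, `converged`, `n_iter`,
#'   `loglik`, `loglik_trace`).
#' @export
fit_slopehunter <- function(pairs, p_threshold = 1e-3, max_iter = 500,
                            tol = 1e-6, n_restarts = 25, n_boot = 200,
                            seed = NULL, pi0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kept <- threshold_by_x_pvalue(pairs, p_threshold)
  if (nrow(kept) < 10L) {
    stop("fewer than 10 SNPs pass the X p-value threshold ", p_threshold,
         call. = FALSE)
  }
  fit <- sh_em_best(kept$beta_x, kept$beta_y, max_iter = max_iter, tol = tol,
                    n_restarts = n_restarts, pi0_fixed = pi0)
  if (!fit$converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning best fit", call. = FALSE)
  }
  b_hat <- sh_corrected_slope(kept, fit$responsibilities)

  se_b <- NA_real_
  if (n_boot > 0L) {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(kept), replace = TRUE)
      bk <- kept[idx, , drop = FALSE]
      bf <- sh_em(bk$beta_x, bk$beta_y, init = fit$params,
                  max_iter = max(50L, max_iter %/% 4L), tol = tol,
                  pi0_fixed = pi0)
      sh_corrected_slope(bk, bf$responsibilities)
    }, numeric(1))
    se_b <- stats::sd(boot, na.rm = TRUE)
  }

  est <- new_slope_estimate(
    b = b_hat, se_b = se_b, intercept = 0, se_intercept = NA_real_,
    method = "slopehunter", n_snps = nrow(kept),
    diagnostics = list(
      denom_uncorrected = attr(b_hat, "denom_uncorrected"),
      denom_corrected = attr(b_hat, "denom_corrected"),
      pi0 = fit$pi0, n_boot = n_boot
    )
  )
  est$b <- as.numeric(est$b)
  structure(list(estimate = est, mixture = fit), class = "slopehunter_fit")
}

# Corrected responsibility-weighted zero-intercept slope on kept SNPs.
sh_corrected_slope <- function(kept, resp) {
  w <- pair_weights(kept) * resp
  sw <- sum(w)
  if (sw <= 0) stop("empty proportional component", call. = FALSE)
  w <- w / sw
  denom_raw <- sum(w * kept$beta_x^2)
  denom <- denom_raw - sum(w * kept$se_x^2)
  if (denom <= 0) {
    stop("weak-instrument failure in mixture slope: corrected denominator ",
         "is not positive", call. = FALSE)
  }
  structure(sum(w * kept$beta_x * kept$beta_y) / denom,
            denom_uncorrected = denom_raw, denom_corrected = denom)
}

# Best-of-restarts EM. Restart 1 seeds b from k-means on ratios among
# strong-|x| SNPs; the rest draw b from random ratio quantiles.
sh_em_best <- function(x, y, max_iter, tol, n_restarts, pi0_fixed = NULL) {
  strong <- abs(x) >= stats::median(abs(x))
  ratio <- y[strong] / x[strong]
  ratio <- ratio[is.finite(ratio)]
  inits <- vector("list", n_restarts)
  km_b <- tryCatch({
    km <- stats::kmeans(ratio, centers = 2L, nstart = 5L)
    km$centers[which.max(km$size), 1L]
  }, error = function(e) stats::median(ratio))
  inits[[1L]] <- list(b = km_b, pi0 = 0.6)
  if (n_restarts > 1L) {
    for (k in 2:n_restarts) {
      inits[[k]] <- list(
        b = stats::quantile(ratio, stats::runif(1), names = FALSE),
        pi0 = stats::runif(1, 0.2, 0.9)
      )
    }
  }
  fits <- lapply(inits, function(ini) {
    sh_em(x, y, init = sh_init_params(x, y, ini$b, ini$pi0),
          max_iter = max_iter, tol = tol, pi0_fixed = pi0_fixed)
  })
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

# zero-mean second moments keep the initialisation (and hence the whole
# fit) exactly invariant under joint sign flips of any SNP subset
sh_init_params <- function(x, y, b, pi0) {
  r <- y - b * x
  SigB <- matrix(c(mean(x^2), mean(x * y), mean(x * y), mean(y^2)), 2, 2)
  list(pi0 = pi0, b = b, tau2 = mean(x^2),
       sig2 = max(mean(r^2) / 2, 1e-8),
       SigB = SigB + diag(1e-8, 2))
}

# EM for the two-component zero-mean mixture:
#   A (prob pi0): x ~ N(0, tau2), y | x ~ N(b x, sig2)
#   B:            (x, y) ~ N(0, SigB), SigB free SPD
# Plain moment M-steps keep the observed-data log-likelihood monotone.
sh_em <- function(x, y, init, max_iter = 500, tol = 1e-6, pi0_fixed = NULL) {
  m <- length(x)
  p <- init
  if (!is.null(pi0_fixed)) p$pi0 <- pi0_fixed
  eps <- 1e-12
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  resp <- rep(p$pi0, m)

  for (iter in seq_len(max_iter)) {
    la <- log(max(p$pi0, eps)) +
      stats::dnorm(x, 0, sqrt(p$tau2), log = TRUE) +
      stats::dnorm(y, p$b * x, sqrt(p$sig2), log = TRUE)
    lb <- log(max(1 - p$pi0, eps)) + dmvnorm0_log(x, y, p$SigB)
    mx <- pmax(la, lb)
    ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
    trace <- c(trace, ll)
    resp <- 1 / (1 + exp(lb - la))

    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll

    sa <- sum(resp); sb <- m - sa
    if (is.null(pi0_fixed)) p$pi0 <- sa / m
    if (sa > eps) {
      sxx <- sum(resp * x^2)
      p$tau2 <- max(sxx / sa, eps)
      p$b <- if (sxx > eps) sum(resp * x * y) / sxx else p$b
      p$sig2 <- max(sum(resp * (y - p$b * x)^2) / sa, eps)
    }
    if (sb > eps) {
      S <- matrix(c(sum((1 - resp) * x^2), sum((1 - resp) * x * y),
                    sum((1 - resp) * x * y), sum((1 - resp) * y^2)),
                  2, 2) / sb
      p$SigB <- S + diag(eps, 2)
    }
  }
  list(b = p$b, pi0 = p$pi0, responsibilities = resp,
       converged = converged, n_iter = iter, loglik = trace[length(trace)],
       loglik_trace = trace, params = p)
}

# log density of zero-mean bivariate normal at (x, y)
dmvnorm0_log <- function(x, y, Sig) {
  det_s <- Sig[1, 1] * Sig[2, 2] - Sig[1, 2]^2
  det_s <- max(det_s, 1e-300)
  q <- (Sig[2, 2] * x^2 - 2 * Sig[1, 2] * x * y + Sig[1, 1] * y^2) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' @export
print.slopehunter_fit <- function(x, ...) {
  cat("Two-component mixture bias-slope fit\n")
  cat(sprintf("  b = %.5f (bootstrap SE %s), pi0 = %.3f, n_snps = %d\n",
              x$estimate$b,
              ifelse(is.na(x$estimate$se_b), "NA",
                     sprintf("%.5f", x$estimate$se_b)),
              x$mixture$pi0, x$estimate$n_snps))
  cat(sprintf("  EM: %s after %d iterations, loglik %.3f\n",
              if (x$mixture$converged) "converged" else "NOT converged",
              x$mixture$n_iter, x$mixture$loglik))
  invisible(x)
}

#' @method tidy slopehunter_fit
#' @export
tidy.slopehunter_fit <- function(x, ...) tidy(x$estimate, ...)

#' @method glance slopehunter_fit
#' @export
glance.slopehunter_fit <- function(x, ...) {
  dplyr::mutate(glance(x$estimate),
                pi0 = x$mixture$pi0,
                converged = x$mixture$converged,
                loglik = x$mixture$loglik)
}
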