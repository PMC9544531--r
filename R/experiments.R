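#' Replicate study of Type-1 error, power and FDR
#'
#' Repeats the full pipeline — simulate a two-trait GWAS, fit the bias
#' slope, adjust the conditional effects, Wald-test every SNP — and
#' aggregates error rates over replicates, among the SNPs with effects on
#' the conditioning covariate X: Type-1 error is the rejection rate among
#' X-only SNPs (no direct outcome effect), power the rejection rate among
#' shared SNPs, and FDR the ratio of Type-1 error to the sum of Type-1
#' error and power (the two classes being equally sized). Each cell
#' carries a Monte-Carlo standard error (SD of the per-replicate rate over
#' the square root of the replicate count).
#'
#' Replicate seeds are derived from the master seed by one
#' `sample.int(.Machine$integer.max - 1, reps)` draw, so runs are
#' reproducible and each replicate is independent.
#'
#' @param cfg A `sim_config`; summary mode is used.
#' @param methods Character vector from `"unadjusted"`, `"ivw"`,
#'   `"cwls0"`, `"cwls_free"`, `"cwls_free_positive_coding"`,
#'   `"slopehunter"`.
#' @param reps Number of replicates (at least 2).
#' @param alpha Significance level for the Wald tests.
#' @param seed Master seed.
#' @param sh_reps Replicates used for the mixture estimator (EM cost);
#'   defaults to `min(reps, 25)`.
#' @param sh_args Extra arguments for [fit_slopehunter()] (e.g.
#'   `p_threshold`).
#' @return A tibble of class `error_rate_report`: `method`, `type1`,
#'   `power`, `fdr`, `reps`, `mc_se_type1`, `mc_se_power`, `mc_se_fdr`.
#'   The per-replicate slope fits are attached as attribute `"slopes"`
#'   (a tibble: `rep`, `method`, `b`, `se_b`), and the per-replicate
#'   rates as attribute `"per_rep"`.
#' @export
run_error_rate_experiment <- function(cfg,
                                      methods = c("unadjusted", "cwls0"),
                                      reps = 200, alpha = 0.05, seed = 1,
                                      sh_reps = NULL, sh_args = list()) {
  if (reps < 2) stop("need at least 2 replicates", call. = FALSE)
  known <- c("unadjusted", "ivw", "cwls0", "cwls_free",
             "cwls_free_positive_coding", "slopehunter")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "), call. = FALSE)
  }
  if (is.null(sh_reps)) sh_reps <- min(reps, 25L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, reps)

  rows <- vector("list", reps)
  slope_rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    sim <- simulate_summary(cfg)
    pairs <- default_weights(sim_pairs(sim))
    meths <- methods
    if ("slopehunter" %in% meths && r > sh_reps) {
      meths <- setdiff(meths, "slopehunter")
    }
    res <- lapply(meths, function(mm) {
      f <- fit_and_adjust(pairs, mm, sh_args)
      rates <- replicate_rates(f$adj, alpha)
      list(rates = dplyr::mutate(rates, rep = r, method = mm),
           slope = if (is.null(f$slope)) NULL else
             tibble::tibble(rep = r, method = mm, b = f$slope$b,
                            se_b = f$slope$se_b))
    })
    rows[[r]] <- dplyr::bind_rows(lapply(res, `[[`, "rates"))
    slope_rows[[r]] <- dplyr::bind_rows(lapply(res, `[[`, "slope"))
  }
  per_rep <- dplyr::bind_rows(rows)
  agg <- per_rep |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mc_se_type1 = stats::sd(.data$type1) / sqrt(dplyr::n()),
      mc_se_power = stats::sd(.data$power) / sqrt(dplyr::n()),
      mc_se_fdr = stats::sd(.data$type1 / (.data$type1 + .data$power)) /
        sqrt(dplyr::n()),
      type1 = mean(.data$type1), power = mean(.data$power),
      fdr = .data$type1 / (.data$type1 + .data$power),
      reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("method", "type1", "power", "fdr", "reps",
                  dplyr::starts_with("mc_se")) |>
    dplyr::arrange(match(.data$method, known))
  attr(agg, "slopes") <- dplyr::bind_rows(slope_rows)
  attr(agg, "per_rep") <- per_rep
  attr(agg, "alpha") <- alpha
  class(agg) <- c("error_rate_report", class(agg))
  agg
}

# Fit one method on a weighted pair table and adjust the conditional
# effects; "unadjusted" tests the raw conditional effects.
fit_and_adjust <- function(pairs, method, sh_args = list()) {
  if (method == "unadjusted") {
    z <- pairs$beta_y / pairs$se_y
    adj <- tibble::tibble(
      snp_id = pairs$snp_id, beta_direct = pairs$beta_y,
      se_direct = pairs$se_y, z = z,
      pvalue = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      source = "unadjusted"
    )
    adj$class <- pairs$class
    adj$beta_gy_true <- pairs$beta_gy_true
    adj$beta_y_raw <- pairs$beta_y
    return(list(slope = NULL, adj = adj))
  }
  slope <- switch(method,
    ivw = ivw_slope(pairs),
    cwls0 = cwls_zero_intercept(pairs),
    cwls_free = cwls_free_intercept(pairs),
    cwls_free_positive_coding =
      cwls_free_intercept(recode_positive_on_x(pairs),
                          allow_negative_denominator = TRUE),
    slopehunter = do.call(fit_slopehunter,
                          c(list(pairs = pairs, n_boot = 0L), sh_args)
                          )$estimate
  )
  adj <- adjust_conditional(pairs, slope)
  adj$class <- pairs$class
  adj$beta_gy_true <- pairs$beta_gy_true
  adj$beta_y_raw <- pairs$beta_y
  list(slope = slope, adj = adj)
}

replicate_rates <- function(adj, alpha) {
  sig <- adj$pvalue <= alpha
  tibble::tibble(
    type1 = mean(sig[adj$class == "x_only"]),
    power = mean(sig[adj$class == "shared"])
  )
}

#' Replicate study of slope recovery across shared-effect correlations
#'
#' For each value of `rho_grid`, simulates replicate GWAS and fits the
#' requested slope estimators, reporting the mean estimate, the empirical
#' standard deviation over replicates, and the mean of the estimated
#' (sandwich) standard errors, next to the analytic true slope.
#'
#' @param cfg Base `sim_config` (its `rho_shared` is overridden by the
#'   grid).
#' @param methods From `"ivw"`, `"cwls0"`, `"cwls_free"`,
#'   `"cwls_free_positive_coding"`, `"slopehunter"`.
#' @param reps Replicates per grid point.
#' @param seed Master seed.
#' @param rho_grid Correlations of shared-SNP effects to sweep.
#' @param sh_reps,sh_args Mixture-estimator controls as in
#'   [run_error_rate_experiment()].
#' @return A tibble of class `slope_report`: `rho_shared`, `b_true`,
#'   `method`, `mean_b`, `empirical_sd`, `mean_se`, `reps`, `mc_se`.
#' @export
run_slope_experiment <- function(cfg, methods = "cwls0", reps = 200,
                                 seed = 1, rho_grid = c(0, 0.45, -0.45),
                                 sh_reps = NULL, sh_args = list()) {
  out <- purrr::map(rho_grid, function(rho) {
    cfg_r <- cfg
    cfg_r$rho_shared <- rho
    validate_sim_config(cfg_r)
    rep_mth <- setdiff(methods, "unadjusted")
    er <- run_error_rate_experiment(cfg_r, methods = rep_mth, reps = reps,
                                    seed = seed, sh_reps = sh_reps,
                                    sh_args = sh_args)
    attr(er, "slopes") |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        mean_b = mean(.data$b),
        empirical_sd = stats::sd(.data$b),
        mean_se = mean(.data$se_b, na.rm = TRUE),
        reps = dplyr::n(),
        mc_se = stats::sd(.data$b) / sqrt(dplyr::n()),
        .groups = "drop"
      ) |>
      dplyr::mutate(rho_shared = rho,
                    b_true = implied_bias_slope(cfg_r),
                    .before = 1L)
  }) |>
    dplyr::bind_rows()
  class(out) <- c("slope_report", class(out))
  out
}

#' Replicate study of adjustment-induced sign changes
#'
#' Among SNPs with a true direct effect on the outcome whose *adjusted*
#' association is nominally significant, estimates how often adjustment
#' flips the sign of the estimate relative to the unadjusted conditional
#' effect — toward the true direction (correct change) or away from it
#' (incorrect change) — split by causal class (`shared` vs `y_only`).
#' Denominators (significant-after-adjustment counts per class) are
#' attached as attribute `"denominators"`; the alternative both-analyses
#' denominator is recorded alongside.
#'
#' @inheritParams run_error_rate_experiment
#' @return A tibble of class `signchange_report`: `method`, `class`,
#'   `correct_change`, `incorrect_change`, `n_significant`, `reps`.
#' @export
run_signchange_experiment <- function(cfg, methods = "cwls0", reps = 200,
                                      alpha = 0.05, seed = 1,
                                      sh_reps = NULL, sh_args = list()) {
  if (reps < 2) stop("need at least 2 replicates", call. = FALSE)
  if (is.null(sh_reps)) sh_reps <- min(reps, 25L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, reps)

  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    sim <- simulate_summary(cfg)
    pairs <- default_weights(sim_pairs(sim))
    meths <- methods
    if ("slopehunter" %in% meths && r > sh_reps) {
      meths <- setdiff(meths, "slopehunter")
    }
    rows[[r]] <- dplyr::bind_rows(lapply(meths, function(mm) {
      adj <- fit_and_adjust(pairs, mm, sh_args)$adj
      adj |>
        dplyr::filter(.data$class %in% c("shared", "y_only"),
                      .data$beta_gy_true != 0) |>
        dplyr::mutate(
          significant = .data$pvalue <= alpha,
          flipped = sign(.data$beta_direct) != sign(.data$beta_y_raw),
          correct = .data$flipped &
            sign(.data$beta_direct) == sign(.data$beta_gy_true),
          incorrect = .data$flipped &
            sign(.data$beta_direct) != sign(.data$beta_gy_true)
        ) |>
        dplyr::group_by(.data$class) |>
        dplyr::summarise(
          n_significant = sum(.data$significant),
          n_significant_both = sum(.data$significant &
                                     wald_pvalue(.data$beta_y_raw,
                                                 .data$se_direct) <= alpha),
          n_correct = sum(.data$correct & .data$significant),
          n_incorrect = sum(.data$incorrect & .data$significant),
          .groups = "drop"
        ) |>
        dplyr::mutate(method = mm, rep = r)
    }))
  }
  per_rep <- dplyr::bind_rows(rows)
  agg <- per_rep |>
    dplyr::group_by(.data$method, .data$class) |>
    dplyr::summarise(
      correct_change = sum(.data$n_correct) / sum(.data$n_significant),
      incorrect_change = sum(.data$n_incorrect) / sum(.data$n_significant),
      n_significant = sum(.data$n_significant),
      reps = dplyr::n(),
      .groups = "drop"
    )
  attr(agg, "denominators") <- per_rep
  class(agg) <- c("signchange_report", class(agg))
  agg
}
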