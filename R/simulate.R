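#' Configuration for a synthetic two-trait GWAS
#'
#' Describes the generative model used throughout the package's simulation
#' study: `m_total` independent biallelic SNPs in Hardy-Weinberg
#' equilibrium with minor allele frequencies uniform on `maf_range`;
#' disjoint causal sets affecting the covariate X only, the outcome Y
#' only, or both; per-allele effects drawn from normal distributions and
#' scaled so the causal SNPs of each trait explain heritability `h2_x`
#' (resp. `h2_y`), split equally between the trait-only and shared
#' classes; a shared non-genetic confounder contributing variance share
#' `c_conf` to each trait; and residual share `v_resid`, so each trait has
#' unit variance. `rho_shared` is the correlation between the shared SNPs'
#' effects on X and on Y. There is no causal X-to-Y path, so every
#' X-association of the conditional outcome effects is collider bias.
#'
#' The defaults are the genome-scale study conditions (100,000 SNPs with
#' 5,000 per causal class, 50% heritability, 40% confounding, 10%
#' residual). `scale_genome()` shrinks a configuration proportionally for
#' desk-scale replicate studies.
#'
#' @param m_total Total SNP count.
#' @param m_x_only,m_y_only,m_shared Causal-class sizes.
#' @param maf_range Length-2 range for the uniform MAF draw.
#' @param h2_x,h2_y Trait heritabilities.
#' @param c_conf Confounder variance share (per trait).
#' @param v_resid Residual variance share (per trait).
#' @param rho_shared Correlation of shared SNPs' effects on X and Y.
#' @param n GWAS sample size for each trait regression. Not part of the
#'   published study conditions; 20,000 gives realistic per-SNP power at
#'   desk scale.
#' @param mode `"summary"` (sampling-error model on effect estimates) or
#'   `"individual"` (explicit genotypes and per-SNP regressions).
#' @param seed Optional integer seed stored with the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_total = 100000L,
                       m_x_only = 5000L, m_y_only = 5000L, m_shared = 5000L,
                       maf_range = c(0.01, 0.49),
                       h2_x = 0.5, h2_y = 0.5,
                       c_conf = 0.4, v_resid = 0.1,
                       rho_shared = 0,
                       n = 20000L,
                       mode = c("summary", "individual"),
                       seed = NULL) {
  mode <- match.arg(mode)
  cfg <- list(m_total = as.integer(m_total), m_x_only = as.integer(m_x_only),
              m_y_only = as.integer(m_y_only), m_shared = as.integer(m_shared),
              maf_range = maf_range, h2_x = h2_x, h2_y = h2_y,
              c_conf = c_conf, v_resid = v_resid, rho_shared = rho_shared,
              n = as.integer(n), mode = mode, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(cfg$h2_x + cfg$c_conf + cfg$v_resid - 1) > 1e-8 ||
      abs(cfg$h2_y + cfg$c_conf + cfg$v_resid - 1) > 1e-8) {
    stop("variance shares must satisfy h2 + c_conf + v_resid = 1 per trait",
         call. = FALSE)
  }
  if (cfg$m_x_only + cfg$m_y_only + cfg$m_shared > cfg$m_total) {
    stop("causal SNP counts exceed m_total", call. = FALSE)
  }
  if (abs(cfg$rho_shared) > 1) stop("rho_shared must be in [-1, 1]",
                                    call. = FALSE)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] >= 0.5 ||
      cfg$maf_range[1] >= cfg$maf_range[2]) {
    stop("maf_range must lie inside (0, 0.5)", call. = FALSE)
  }
  invisible(cfg)
}

#' Proportionally shrink a simulation configuration
#'
#' Divides the genome size and every causal-class count by `factor`,
#' leaving variance shares (and therefore the implied bias slope and all
#' rate estimands) unchanged.
#'
#' @param cfg A `sim_config`.
#' @param factor Shrink factor (e.g. 5 turns 100,000/5,000 into
#'   20,000/1,000).
#' @return A `sim_config`.
#' @export
scale_genome <- function(cfg, factor) {
  cfg$m_total <- as.integer(round(cfg$m_total / factor))
  cfg$m_x_only <- as.integer(round(cfg$m_x_only / factor))
  cfg$m_y_only <- as.integer(round(cfg$m_y_only / factor))
  cfg$m_shared <- as.integer(round(cfg$m_shared / factor))
  validate_sim_config(cfg)
  cfg
}

#' Analytic collider-bias slope implied by a configuration
#'
#' Under the structural model with no causal X-to-Y path, conditioning the
#' outcome regression on X biases each SNP's conditional effect by
#' `b * beta_GX`, where `b` is minus the non-direct covariance between X
#' and Y over `var(X)`:
#' \deqn{b = -\frac{c_{conf} + \rho\,\sqrt{(h^2_x/2)(h^2_y/2)}}{var(X)},}
#' with `var(X) = 1`. The genetic term is the covariance contributed by
#' the shared SNPs, which carry half of each trait's heritability. At the
#' default shares this gives -0.4 for `rho_shared = 0`, -0.5125 for
#' `0.45` and -0.2875 for `-0.45`.
#'
#' @param cfg A `sim_config`.
#' @return The slope `b` (dimensionless).
#' @export
implied_bias_slope <- function(cfg) {
  h2_shared <- if (cfg$m_shared > 0) sqrt((cfg$h2_x / 2) * (cfg$h2_y / 2)) else 0
  -(cfg$c_conf + cfg$rho_shared * h2_shared)
}

#' Draw per-SNP true effects for a configuration
#'
#' Draws MAFs uniform on `maf_range` and per-allele effects from normal
#' distributions: shared SNPs' (X, Y) effect pairs are bivariate normal
#' with correlation `rho_shared`; each causal class is then rescaled so
#' its variance explained, `sum(2 p (1-p) beta^2)`, equals exactly its
#' heritability share (`h2/2` per class per trait).
#'
#' @param cfg A `sim_config`.
#' @param seed Optional seed; defaults to `cfg$seed`. `NULL` leaves the
#'   RNG state untouched.
#' @return A tibble with one row per SNP: `snp_id`, `maf`, `beta_gx`,
#'   `beta_gy` (direct effects), `class` in
#'   `{"x_only", "y_only", "shared", "null"}`; the implied slope is
#'   attached as attribute `b_true`.
#' @export
draw_true_effects <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- cfg$m_total
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  cls <- rep("null", m)
  idx <- sample.int(m, cfg$m_x_only + cfg$m_y_only + cfg$m_shared)
  i_x <- idx[seq_len(cfg$m_x_only)]
  i_y <- idx[cfg$m_x_only + seq_len(cfg$m_y_only)]
  i_s <- idx[cfg$m_x_only + cfg$m_y_only + seq_len(cfg$m_shared)]
  cls[i_x] <- "x_only"; cls[i_y] <- "y_only"; cls[i_s] <- "shared"

  beta_gx <- numeric(m)
  beta_gy <- numeric(m)
  het <- 2 * maf * (1 - maf)

  scale_to <- function(beta, which, target) {
    if (length(which) == 0L) return(numeric(0))
    v <- sum(het[which] * beta^2)
    if (v <= 0) stop("infeasible variance partition: zero raw variance",
                     call. = FALSE)
    beta * sqrt(target / v)
  }
  beta_gx[i_x] <- scale_to(stats::rnorm(cfg$m_x_only), i_x, cfg$h2_x / 2)
  beta_gy[i_y] <- scale_to(stats::rnorm(cfg$m_y_only), i_y, cfg$h2_y / 2)
  # correlated shared effects: y = rho * x + sqrt(1 - rho^2) * e
  zx <- stats::rnorm(cfg$m_shared)
  zy <- cfg$rho_shared * zx + sqrt(1 - cfg$rho_shared^2) * stats::rnorm(cfg$m_shared)
  beta_gx[i_s] <- scale_to(zx, i_s, cfg$h2_x / 2)
  beta_gy[i_s] <- scale_to(zy, i_s, cfg$h2_y / 2)

  out <- tibble::tibble(
    snp_id = paste0("snp", seq_len(m)),
    maf = maf, beta_gx = beta_gx, beta_gy = beta_gy,
    class = cls
  )
  attr(out, "b_true") <- implied_bias_slope(cfg)
  out
}

#' Simulate summary statistics for the two GWAS
#'
#' Fast generative model operating directly on effect estimates. The
#' X-GWAS estimate of SNP i is
#' `N(beta_gx, 1 / (n * 2 p (1-p)))` (unit trait variance); the
#' conditional outcome estimate is
#' `N(beta_gy + b_true * beta_gx, var(Y|X) / (n * 2 p (1-p)))` with
#' `var(Y|X) = 1 - cov(X,Y)^2` and
#' `cov(X,Y) = c_conf + rho_shared * sqrt((h2_x/2)(h2_y/2))`. Sampling
#' errors of the two estimates are independent, which is justified
#' because the outcome regression conditions on X. Reported standard
#' errors are the true sampling standard deviations.
#'
#' @param cfg A `sim_config` with `mode = "summary"`.
#' @param truth Output of [draw_true_effects()]; drawn afresh when `NULL`.
#' @param seed Optional seed (`NULL`: RNG state untouched).
#' @param include_total Also draw a *total* (unconditional) outcome GWAS,
#'   `N(beta_gy, 1 / (n * 2 p (1-p)))` — with no causal X-to-Y path the
#'   total effect of a SNP equals its direct effect. Used for the
#'   total-effect (mtCOJO-style) adjustment path.
#' @return A list of class `sim_summary`: `x_stats` and `y_stats`
#'   (summary-statistic tibbles in the [read_sumstats()] layout),
#'   `truth`, and `total_y_stats` when requested.
#' @export
simulate_summary <- function(cfg, truth = NULL, seed = NULL,
                             include_total = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- draw_true_effects(cfg, seed = NULL)
  b_true <- implied_bias_slope(cfg)
  het <- 2 * truth$maf * (1 - truth$maf)
  se_x <- sqrt(1 / (cfg$n * het))
  cov_xy <- cfg$c_conf + cfg$rho_shared * sqrt((cfg$h2_x / 2) * (cfg$h2_y / 2))
  se_y <- sqrt((1 - cov_xy^2) / (cfg$n * het))
  m <- nrow(truth)

  beta_x_hat <- truth$beta_gx + stats::rnorm(m, sd = se_x)
  beta_y_hat <- truth$beta_gy + b_true * truth$beta_gx +
    stats::rnorm(m, sd = se_y)

  mk <- function(beta, se) {
    tibble::tibble(
      snp_id = truth$snp_id,
      effect_allele = "A", other_allele = "G",
      beta = beta, se = se,
      pvalue = wald_pvalue(beta, se),
      eaf = truth$maf, n = cfg$n
    )
  }
  out <- list(x_stats = mk(beta_x_hat, se_x),
              y_stats = mk(beta_y_hat, se_y),
              truth = truth)
  if (include_total) {
    se_t <- sqrt(1 / (cfg$n * het))
    out$total_y_stats <- mk(truth$beta_gy + stats::rnorm(m, sd = se_t), se_t)
  }
  structure(out, class = "sim_summary")
}

#' Simulate individual-level data and run the per-SNP regressions
#'
#' Reference-mode generator: genotypes `Binomial(2, maf)` under
#' Hardy-Weinberg equilibrium, traits built from the structural equations
#' `X = G beta_gx + U sqrt(c_conf) + e_x sqrt(v_resid)` and
#' `Y = G beta_gy + U sqrt(c_conf) + e_y sqrt(v_resid)` with a shared
#' standard-normal confounder U and no causal X-to-Y path. The X-GWAS
#' regresses X on each SNP; the outcome GWAS regresses Y on each SNP
#' *and* X jointly, so its per-SNP coefficients are the collider-biased
#' conditional effects. Regressions are computed in closed form from
#' cross-products, so the cost is one pass over the genotype matrix.
#'
#' @param cfg A `sim_config`; `n * m_total` must stay below
#'   `max_cells` (default 2e8 entries, about 1.6 GB of doubles) —
#'   use summary mode beyond that.
#' @param truth Output of [draw_true_effects()]; drawn afresh when `NULL`.
#' @param seed Optional seed.
#' @param max_cells Genotype-matrix size guard.
#' @param keep_genotypes Keep the genotype matrix in the result (off by
#'   default to save memory).
#' @return A list of class `sim_individual`: `x_stats`, `y_stats` (same
#'   layout as [simulate_summary()]), `truth`, and vectors `x`, `y`, `u`
#'   (plus `genotypes` if kept).
#' @export
simulate_individual <- function(cfg, truth = NULL, seed = NULL,
                                max_cells = 2e8, keep_genotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- draw_true_effects(cfg, seed = NULL)
  n <- cfg$n
  m <- nrow(truth)
  if (as.double(n) * m > max_cells) {
    stop("individual-level simulation of ", n, " x ", m,
         " genotypes exceeds the memory budget; use mode = \"summary\"",
         call. = FALSE)
  }
  G <- matrix(stats::rbinom(n * m, 2L, rep(truth$maf, each = n)), n, m)
  G <- sweep(G, 2L, 2 * truth$maf)  # centre; per-allele effects unchanged

  u <- stats::rnorm(n)
  x <- as.numeric(G %*% truth$beta_gx) + sqrt(cfg$c_conf) * u +
    sqrt(cfg$v_resid) * stats::rnorm(n)
  y <- as.numeric(G %*% truth$beta_gy) + sqrt(cfg$c_conf) * u +
    sqrt(cfg$v_resid) * stats::rnorm(n)

  xc <- x - mean(x); yc <- y - mean(y)
  G <- sweep(G, 2L, colMeans(G))
  gg <- colSums(G^2)
  gX <- as.numeric(crossprod(G, xc))
  gY <- as.numeric(crossprod(G, yc))
  XX <- sum(xc^2); XY <- sum(xc * yc); YY <- sum(yc^2)

  # X-GWAS: X ~ 1 + G_i
  beta_x <- gX / gg
  se_x <- sqrt(pmax(XX - beta_x^2 * gg, 0) / (n - 2) / gg)

  # conditional outcome GWAS: Y ~ 1 + G_i + X, via partialling X out
  gpgp <- gg - gX^2 / XX
  gpY <- gY - gX * XY / XX
  beta_y <- gpY / gpgp
  rss <- pmax(YY - XY^2 / XX - beta_y^2 * gpgp, 0)
  se_y <- sqrt(rss / (n - 3) / gpgp)

  mk <- function(beta, se) {
    tibble::tibble(
      snp_id = truth$snp_id,
      effect_allele = "A", other_allele = "G",
      beta = beta, se = se,
      pvalue = wald_pvalue(beta, se),
      eaf = truth$maf, n = n
    )
  }
  out <- list(x_stats = mk(beta_x, se_x), y_stats = mk(beta_y, se_y),
              truth = truth, x = x, y = y, u = u)
  if (keep_genotypes) out$genotypes <- G
  structure(out, class = "sim_individual")
}

#' Harmonised pairs from a simulated dataset
#'
#' Runs [harmonise()] on the two simulated summary-statistic tables and
#' attaches the true causal class of each SNP.
#'
#' @param sim A `sim_summary` or `sim_individual`.
#' @return A harmonised pair tibble with extra columns `class` and
#'   `beta_gy_true`.
#' @export
sim_pairs <- function(sim) {
  pairs <- harmonise(sim$x_stats, sim$y_stats)
  dplyr::left_join(
    pairs,
    dplyr::select(sim$truth, "snp_id", "class", beta_gy_true = "beta_gy"),
    by = "snp_id"
  )
}
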