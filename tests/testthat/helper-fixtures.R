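# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Minimal harmonised-pair tibble with sensible defaults.
make_pairs <- function(beta_x, beta_y, se_x = 0.1, se_y = 1,
                       p_x = NULL, snp_id = NULL) {
  m <- length(beta_x)
  se_x <- rep_len(se_x, m)
  se_y <- rep_len(se_y, m)
  if (is.null(p_x)) p_x <- 2 * stats::pnorm(-abs(beta_x / se_x))
  tibble::tibble(
    snp_id = snp_id %||% paste0("rs", seq_len(m)),
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y, p_x = p_x
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small sumstats file and return its path.
write_sumstats_file <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# Desk-scale study configuration: the genome-scale conditions shrunk 5x
# (20,000 SNPs, 1,000 per causal class), n = 20,000.
desk_config <- function(rho = 0) {
  scale_genome(sim_config(rho_shared = rho), 5)
}

# The replicate study shared by several end-to-end checks is expensive;
# run it once per session and cache.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.acceptance_cache$run)) {
    return(.acceptance_cache$run)
  }
  cfg <- desk_config()
  report <- run_error_rate_experiment(
    cfg,
    methods = c("unadjusted", "ivw", "cwls0", "cwls_free_positive_coding"),
    reps = 200, alpha = 0.05, seed = 20211
  )
  .acceptance_cache$run <- list(cfg = cfg, report = report,
                                slopes = attr(report, "slopes"),
                                per_rep = attr(report, "per_rep"))
  .acceptance_cache$run
}
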