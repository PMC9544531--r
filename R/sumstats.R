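#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated summary-statistic file into a validated
#' tibble of per-SNP association records. Column names are mapped onto the
#' standard roles via `column_map`, so PLINK-, GCTA- and consortium-style
#' headers (`SNP`/`rsid`, `A1`/`EA`, `A2`/`OA`, `BETA`/`b`, `SE`, `P`/`pval`,
#' `EAF`/`freq`, `N`) can all be read without editing the file.
#'
#' Rows with a missing or non-finite effect estimate, a missing or
#' non-positive standard error, identical effect and other alleles, or an
#' allele outside `{A, C, G, T}` are dropped; the number dropped for each
#' reason is recorded in the `"report"` attribute of the result. Duplicate
#' SNP ids keep the first occurrence with a warning. A missing p-value
#' column is filled in from the Wald z statistic under normality.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard roles to the
#'   file's column names. Recognised roles: `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, `eaf`, `n`. Roles omitted from
#'   the map are matched against a built-in dictionary of common dialects.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab versus
#'   comma from the header line.
#'
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pvalue` and, when present in the file, `eaf` and `n`.
#'   The attribute `report` is a named integer vector of drop counts.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tBETA\tSE",
#'              "rs1\tA\tG\t0.10\t0.02",
#'              "rs2\tC\tT\t-0.05\t0.03"), tf)
#' read_sumstats(tf)
read_sumstats <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistic file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  # read everything as character: a lone "T" allele must not become TRUE
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(.default = "c"))
  names(raw) <- trimws(names(raw))

  dialects <- list(
    snp_id        = c("snp_id", "SNP", "snp", "rsid", "RSID", "ID", "MarkerName", "variant_id"),
    effect_allele = c("effect_allele", "EA", "A1", "ALT", "Allele1", "effect_allele"),
    other_allele  = c("other_allele", "OA", "A2", "REF", "Allele2", "ref_allele"),
    beta          = c("beta", "BETA", "b", "B", "Effect", "effect", "beta_hat", "LogOR"),
    se            = c("se", "SE", "StdErr", "stderr", "standard_error"),
    pvalue        = c("pvalue", "P", "p", "pval", "P-value", "p_value", "PVAL"),
    eaf           = c("eaf", "EAF", "freq", "FREQ", "AF", "MAF", "effect_allele_frequency"),
    n             = c("n", "N", "n_samples", "Neff", "sample_size")
  )
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")

  resolve <- function(role) {
    if (!is.null(column_map) && role %in% names(column_map)) {
      nm <- unname(column_map[[role]])
      if (!nm %in% names(raw)) {
        stop("column_map names '", nm, "' for role '", role,
             "' but the file has no such column", call. = FALSE)
      }
      return(nm)
    }
    hit <- intersect(dialects[[role]], names(raw))
    if (length(hit)) hit[[1L]] else NA_character_
  }
  cols <- vapply(names(dialects), resolve, character(1))
  missing_roles <- names(cols)[is.na(cols) & names(cols) %in% mandatory]
  if (length(missing_roles)) {
    stop("mandatory column(s) not found: ", paste(missing_roles, collapse = ", "),
         "; supply a column_map", call. = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    snp_id        = as.character(raw[[cols["snp_id"]]]),
    effect_allele = toupper(as.character(raw[[cols["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[cols["other_allele"]]])),
    beta          = num(raw[[cols["beta"]]]),
    se            = num(raw[[cols["se"]]])
  )
  if (!is.na(cols["pvalue"])) out$pvalue <- num(raw[[cols["pvalue"]]])
  if (!is.na(cols["eaf"]))    out$eaf   <- num(raw[[cols["eaf"]]])
  if (!is.na(cols["n"]))      out$n     <- num(raw[[cols["n"]]])

  bases <- c("A", "C", "G", "T")
  bad_beta   <- !is.finite(out$beta)
  bad_se     <- !bad_beta & (!is.finite(out$se) | out$se <= 0)
  bad_allele <- !bad_beta & !bad_se &
    (!out$effect_allele %in% bases | !out$other_allele %in% bases |
       out$effect_allele == out$other_allele)
  report <- c(invalid_beta = sum(bad_beta), invalid_se = sum(bad_se),
              invalid_alleles = sum(bad_allele), duplicate_id = 0L)
  out <- out[!(bad_beta | bad_se | bad_allele), , drop = FALSE]

  dup <- duplicated(out$snp_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate snp_id(s); keeping first occurrence",
            call. = FALSE)
    report["duplicate_id"] <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no valid summary-statistic rows survive validation", call. = FALSE)
  }
  if (!"pvalue" %in% names(out) || all(is.na(out$pvalue))) {
    out$pvalue <- wald_pvalue(out$beta, out$se)
  }
  attr(out, "report") <- report
  out
}

#' Harmonise two summary-statistic tables into aligned per-SNP pairs
#'
#' Intersects the SNPs of an X-trait (conditioning covariate) table and a
#' Y-trait (conditional outcome) table and reconciles effect alleles so
#' that both effects in a pair refer to the same allele. When the Y record
#' lists the alleles in swapped order relative to X, its effect is negated.
#' Pairs whose allele sets cannot be reconciled are dropped and counted in
#' the `"report"` attribute.
#'
#' @param x_stats,y_stats Tibbles as returned by [read_sumstats()]. `x_stats`
#'   is the GWAS of the covariate/incidence trait; `y_stats` the conditional
#'   (or, for the total-effect path, marginal) outcome GWAS.
#' @param policy `"strict"` (default) drops pairs with irreconcilable
#'   alleles; `"flip_only"` behaves identically but skips the
#'   strand-ambiguity filter implied by `drop_ambiguous`.
#' @param drop_ambiguous Drop strand-ambiguous (A/T and C/G) SNPs. Off by
#'   default: simulated and pre-harmonised consortium data carry no strand
#'   issues. Turn on for raw cross-platform meta-analysis files.
#'
#' @return A tibble with one row per reconciled SNP: `snp_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `p_x`, plus `eaf_x`/`n_x` when available.
#' @export
harmonise <- function(x_stats, y_stats, policy = c("strict", "flip_only"),
                      drop_ambiguous = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(x_stats), is.data.frame(y_stats))

  xx <- tibble::as_tibble(x_stats)
  yy <- tibble::as_tibble(y_stats)
  merged <- dplyr::inner_join(
    xx, yy, by = "snp_id", suffix = c("_x", "_y"), relationship = "one-to-one"
  )
  if (nrow(merged) == 0L) {
    stop("no SNPs shared between the two summary-statistic tables",
         call. = FALSE)
  }

  same <- merged$effect_allele_x == merged$effect_allele_y &
    merged$other_allele_x == merged$other_allele_y
  swapped <- merged$effect_allele_x == merged$other_allele_y &
    merged$other_allele_x == merged$effect_allele_y
  ambiguous <- paste0(merged$effect_allele_x, merged$other_allele_x) %in%
    c("AT", "TA", "CG", "GC")

  keep <- same | swapped
  n_irreconcilable <- sum(!keep)
  if (drop_ambiguous && policy == "strict") keep <- keep & !ambiguous
  n_ambiguous <- if (drop_ambiguous && policy == "strict") sum((same | swapped) & ambiguous) else 0L

  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) {
    stop("all shared SNPs dropped during allele reconciliation", call. = FALSE)
  }
  sign_flip <- ifelse(swapped[keep], -1, 1)

  out <- tibble::tibble(
    snp_id = merged$snp_id,
    beta_x = merged$beta_x,
    se_x   = merged$se_x,
    beta_y = sign_flip * merged$beta_y,
    se_y   = merged$se_y,
    p_x    = if ("pvalue_x" %in% names(merged)) merged$pvalue_x
             else wald_pvalue(merged$beta_x, merged$se_x)
  )
  if ("eaf_x" %in% names(merged)) out$eaf_x <- merged$eaf_x
  if ("n_x" %in% names(merged))   out$n_x  <- merged$n_x
  attr(out, "report") <- c(irreconcilable = n_irreconcilable,
                           strand_ambiguous = n_ambiguous)
  out
}

#' Recode pairs so every effect allele increases the covariate
#'
#' Re-expresses each pair on the allele with a positive (estimated) effect
#' on X: rows with `beta_x < 0` have both `beta_x` and `beta_y` negated.
#' This is the conventional coding for free-intercept instrument-effect
#' regression, but because the coding is chosen from *estimated* effects it
#' biases sampling errors positive and spoils the weak-instrument
#' correction when weak instruments dominate — which is why the
#' zero-intercept estimators, invariant to coding, are preferred.
#' Idempotent.
#'
#' @param pairs A harmonised pair tibble from [harmonise()].
#' @return The tibble with `beta_x >= 0` in every row.
#' @export
recode_positive_on_x <- function(pairs) {
  flip <- pairs$beta_x < 0
  pairs$beta_x[flip] <- -pairs$beta_x[flip]
  pairs$beta_y[flip] <- -pairs$beta_y[flip]
  pairs
}

#' Filter pairs by the p-value of the association with X
#'
#' Retains pairs whose X-association p-value is at most `p_max`, preserving
#' order. A missing `p_x` is recomputed from the Wald z statistic.
#'
#' @param pairs A harmonised pair tibble.
#' @param p_max Threshold in (0, 1]; `1` keeps every row.
#' @return The filtered tibble.
#' @export
threshold_by_x_pvalue <- function(pairs, p_max) {
  if (!is.numeric(p_max) || length(p_max) != 1L || is.na(p_max) ||
      p_max <= 0 || p_max > 1) {
    stop("p_max must be a single number in (0, 1]", call. = FALSE)
  }
  p_x <- if ("p_x" %in% names(pairs)) pairs$p_x else rep(NA_real_, nrow(pairs))
  miss <- is.na(p_x)
  if (any(miss)) p_x[miss] <- wald_pvalue(pairs$beta_x[miss], pairs$se_x[miss])
  pairs[p_x <= p_max, , drop = FALSE]
}

#' Write a harmonised pair table to TSV
#'
#' @param pairs A harmonised pair tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

# Two-sided p from the Wald z under normality; the GWAS convention.
wald_pvalue <- function(beta, se) {
  2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
}
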