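#' Pipeline configuration
#'
#' Collects every tunable of the signature-discovery pipeline in one validated
#' list. Defaults are the study settings: genes with fewer than `min_count`
#' reads in more than `max_frac_below` of samples are dropped; genes whose raw
#' counts correlate with library size above `control_r` become negative
#' control genes; differential expression is called at BH-adjusted p <
#' `de_p_adj` and |log2 fold change| > `de_min_log2fc` (i.e. |FC| > 2); the
#' mRMR candidate pool holds the `mrmr_pool` most significant DEGs; the SVM
#' grid spans gamma in 10^(-10..1) and cost in 2^(1..10).
#'
#' @param min_count Minimum read count defining "expressed" in the low-count
#'   filter (reads).
#' @param max_frac_below Maximum tolerated fraction of samples below
#'   `min_count`; genes exceeding it (strictly) are removed.
#' @param control_r Pearson correlation (raw counts vs library size) above
#'   which a gene is declared a negative control (strict inequality).
#' @param ruv_k Number of unwanted-variation factors to estimate and remove.
#' @param pseudocount Added before the log2 transform.
#' @param de_p_adj,de_min_log2fc DEG thresholds (strict) on the BH-adjusted
#'   p-value and absolute log2 fold change.
#' @param de_raw_p Optional raw p-value threshold; when non-NULL, DEG selection
#'   uses `p < de_raw_p` instead of the adjusted threshold (the study's
#'   secondary p < 0.001 mode).
#' @param mrmr_pool Maximum mRMR candidate pool size; the pool is the DEG list
#'   truncated by ascending p-value.
#' @param mrmr_scheme `"MID"` (relevance minus mean redundancy) or `"MIQ"`
#'   (quotient).
#' @param gamma_grid,cost_grid SVM hyperparameter search grids.
#' @param signature_size Number of top-ranked genes in the signature, or
#'   `"auto"` to pick the smallest size whose LOOCV accuracy is within
#'   `signature_delta` of the best over `1:signature_max`.
#' @param signature_max,signature_delta Controls for the `"auto"` rule.
#' @param n_boot Bootstrap replicates for the AUC confidence interval.
#' @param ci_level Confidence level for the AUC interval.
#' @param case_label Class label in design files mapped to "case".
#' @param seed Integer seed driving every stochastic step (fold assignment,
#'   bootstrap).
#' @return A validated list of class `"tep_config"`.
#' @examples
#' cfg <- tep_config()
#' cfg$control_r
#' @export
tep_config <- function(min_count = 5,
                       max_frac_below = 0.95,
                       control_r = 0.7,
                       ruv_k = 1,
                       pseudocount = 1,
                       de_p_adj = 0.05,
                       de_min_log2fc = 1,
                       de_raw_p = NULL,
                       mrmr_pool = 200,
                       mrmr_scheme = c("MID", "MIQ"),
                       gamma_grid = 10^(-10:1),
                       cost_grid = 2^(1:10),
                       signature_size = 3,
                       signature_max = 10,
                       signature_delta = 0.02,
                       n_boot = 2000,
                       ci_level = 0.95,
                       case_label = "ESCC",
                       seed = 1L) {
  mrmr_scheme <- match.arg(mrmr_scheme)
  cfg <- list(
    min_count = min_count, max_frac_below = max_frac_below,
    control_r = control_r, ruv_k = ruv_k, pseudocount = pseudocount,
    de_p_adj = de_p_adj, de_min_log2fc = de_min_log2fc, de_raw_p = de_raw_p,
    mrmr_pool = mrmr_pool, mrmr_scheme = mrmr_scheme,
    gamma_grid = gamma_grid, cost_grid = cost_grid,
    signature_size = signature_size, signature_max = signature_max,
    signature_delta = signature_delta,
    n_boot = n_boot, ci_level = ci_level,
    case_label = case_label, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "tep_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop_tep(sprintf("invalid configuration: `%s` %s", field, what),
                      "tepsig_error_config")
  }
  chk(is_count(cfg$min_count), "min_count", "must be a non-negative integer")
  chk(is_scalar_num(cfg$max_frac_below) &&
        cfg$max_frac_below >= 0 && cfg$max_frac_below <= 1,
      "max_frac_below", "must lie in [0, 1]")
  chk(is_scalar_num(cfg$control_r) && abs(cfg$control_r) <= 1,
      "control_r", "must lie in [-1, 1]")
  chk(is_count(cfg$ruv_k), "ruv_k", "must be a non-negative integer")
  chk(is_scalar_num(cfg$pseudocount) && cfg$pseudocount >= 0,
      "pseudocount", "must be non-negative")
  chk(is_scalar_num(cfg$de_p_adj) && cfg$de_p_adj > 0 && cfg$de_p_adj <= 1,
      "de_p_adj", "must lie in (0, 1]")
  chk(is_scalar_num(cfg$de_min_log2fc) && cfg$de_min_log2fc >= 0,
      "de_min_log2fc", "must be non-negative")
  if (!is.null(cfg$de_raw_p))
    chk(is_scalar_num(cfg$de_raw_p) && cfg$de_raw_p > 0 && cfg$de_raw_p <= 1,
        "de_raw_p", "must lie in (0, 1]")
  chk(is_count(cfg$mrmr_pool) && cfg$mrmr_pool >= 1,
      "mrmr_pool", "must be a positive integer")
  chk(length(cfg$gamma_grid) >= 1 && all(cfg$gamma_grid > 0),
      "gamma_grid", "must be non-empty and strictly positive")
  chk(length(cfg$cost_grid) >= 1 && all(cfg$cost_grid > 0),
      "cost_grid", "must be non-empty and strictly positive")
  chk(identical(cfg$signature_size, "auto") || is_count(cfg$signature_size),
      "signature_size", "must be a positive integer or \"auto\"")
  chk(is_count(cfg$signature_max) && cfg$signature_max >= 1,
      "signature_max", "must be a positive integer")
  chk(is_scalar_num(cfg$signature_delta) && cfg$signature_delta >= 0,
      "signature_delta", "must be non-negative")
  chk(is_count(cfg$n_boot) && cfg$n_boot >= 1, "n_boot",
      "must be a positive integer")
  chk(is_scalar_num(cfg$ci_level) && cfg$ci_level > 0 && cfg$ci_level < 1,
      "ci_level", "must lie in (0, 1)")
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a validated `tep_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_tep(sprintf("configuration file not found: %s", path),
             "tepsig_error_missing_file")
  raw <- yaml::read_yaml(path)
  known <- names(formals(tep_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_tep(sprintf("unknown configuration fields: %s",
                     paste(unknown, collapse = ", ")),
             "tepsig_error_config")
  do.call(tep_config, raw)
}

#' @rdname read_config
#' @param config A `tep_config` object.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
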