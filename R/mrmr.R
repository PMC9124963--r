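# Minimum-redundancy-maximum-relevance feature ranking with a Gaussian
# mutual-information estimator: MI(rho) = -1/2 log(1 - rho^2), relevance from
# the point-biserial correlation with the class, redundancy from pairwise
# Pearson correlation among candidate genes.

#' Gaussian mutual information from a correlation coefficient
#'
#' `MI = -1/2 ln(1 - rho^2)`, the mutual information of a bivariate normal
#' with correlation `rho`. Perfect correlation gives infinite MI and is capped
#' at `cap`.
#'
#' @param rho Correlation(s) in `[-1, 1]`.
#' @param cap Ceiling applied where `|rho| = 1` (default `-1/2 ln(1e-12)`).
#' @return Non-negative mutual information value(s), in nats.
#' @export
mi_from_correlation <- function(rho, cap = -0.5 * log(1e-12)) {
  if (anyNA(rho) || any(abs(rho) > 1))
    stop_tep("correlation must lie in [-1, 1]", "tepsig_error_correlation")
  pmin(-0.5 * log(pmax(1 - rho^2, 0)), cap)
}

#' Greedy mRMR gene ranking
#'
#' Ranks candidate genes by maximum relevance to the class label and minimum
#' redundancy with already-selected genes. The first gene maximizes the
#' relevance `I(g; y)`; at each later step the gene maximizing
#' `I(g; y) - mean_{s in S} I(g; s)` (scheme `"MID"`) or the corresponding
#' quotient (`"MIQ"`) is appended. All MI terms use [mi_from_correlation()]
#' on Pearson (point-biserial for the class) correlations, so the ranking is
#' invariant to affine rescaling of any gene. Ties are broken by ascending
#' `tie_p` (typically the DE p-value) and then lexicographic gene id, making
#' the ranking fully deterministic.
#'
#' @param X Samples x genes matrix of normalized expression for the candidate
#'   pool (column names = gene ids).
#' @param y Class labels (two-level factor or 0/1).
#' @param n_select Number of genes to rank (defaults to the full pool).
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param tie_p Optional per-gene p-values used for tie-breaking.
#' @return A data.frame of class `"mrmr_ranking"` with columns rank, gene,
#'   relevance, redundancy, score.
#' @export
rank_mrmr <- function(X, y, n_select = ncol(X), scheme = c("MID", "MIQ"),
                      tie_p = NULL) {
  scheme <- match.arg(scheme)
  yb <- as_binary_class(y)
  if (is.null(colnames(X)))
    stop_tep("candidate matrix must carry gene column names",
             "tepsig_error_missing_ids")
  keep <- apply(X, 2L, stats::sd) > 0
  if (!all(keep)) {
    warn_tep(sprintf("%d constant gene(s) dropped from mRMR pool",
                     sum(!keep)))
    X <- X[, keep, drop = FALSE]
    if (!is.null(tie_p)) tie_p <- tie_p[keep]
  }
  genes <- colnames(X)
  m <- length(genes)
  if (m == 0)
    stop_tep("empty mRMR candidate pool", "tepsig_error_empty_result")
  n_select <- min(n_select, m)
  if (is.null(tie_p)) tie_p <- rep(1, m)

  relevance <- mi_from_correlation(as.vector(stats::cor(X, yb)))
  red_mi <- mi_from_correlation(stats::cor(X))  # m x m, symmetric
  # deterministic preference order for exact ties: smaller p, then gene id
  pref <- order(tie_p, genes)
  pick_best <- function(score, candidates) {
    best <- max(score[candidates])
    tied <- candidates[score[candidates] >= best - 1e-12]
    tied[order(match(tied, pref))][1]
  }

  selected <- integer(0)
  red_sum <- numeric(m)
  rows <- vector("list", n_select)
  for (t in seq_len(n_select)) {
    candidates <- setdiff(seq_len(m), selected)
    if (t == 1) {
      score <- relevance
      red <- rep(0, m)
    } else {
      red <- red_sum / length(selected)
      score <- if (scheme == "MID") relevance - red
               else relevance / pmax(red, 1e-12)
    }
    g <- pick_best(score, candidates)
    rows[[t]] <- data.frame(rank = t, gene = genes[g],
                            relevance = relevance[g], redundancy = red[g],
                            score = score[g], stringsAsFactors = FALSE)
    selected <- c(selected, g)
    red_sum <- red_sum + red_mi[, g]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}
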