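# Descriptive statistics for a fitted gene panel: cluster-separation test,
# PCA embedding, and gene-by-clinical-feature correlations.

#' Test class separation of unsupervised sample clusters
#'
#' Hierarchically clusters samples with complete linkage on the
#' `1 - Pearson correlation` distance, cuts the tree into two clusters, and
#' tests the 2x2 cluster-by-class table with a two-sided Fisher's exact test.
#' A small p-value indicates non-random clustering of cases and controls.
#'
#' @param X Samples x genes matrix restricted to the panel.
#' @param y Class labels.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with `clusters` (integer vector), `table` (2x2), and
#'   `fisher_p`.
#' @export
cluster_separation_test <- function(X, y, method = "complete") {
  y <- as_class_factor(y)
  if (min(table(y)) < 2)
    stop_tep("need at least 2 samples per class", "tepsig_error_degenerate")
  cc <- stats::cor(t(X))
  if (anyNA(cc))
    stop_tep("constant sample profile(s); correlation distance undefined",
             "tepsig_error_degenerate")
  if (any(cc[upper.tri(cc)] > 1 - 1e-12))
    warn_tep("identical sample profiles detected; distances degenerate")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = method)
  clusters <- stats::cutree(hc, k = 2)
  tab <- table(cluster = clusters, class = y)
  p <- stats::fisher.test(tab)$p.value
  list(clusters = clusters, table = tab, fisher_p = p)
}

#' PCA embedding of samples
#'
#' Centers genes, computes the SVD, and returns the leading component scores
#' with their explained-variance fractions. Sign convention: each component is
#' oriented so its largest-magnitude gene loading is positive.
#'
#' @param X Samples x genes matrix.
#' @param n_components Number of leading components.
#' @return List with `scores` (samples x components), `loadings`,
#'   `explained` (variance fractions).
#' @export
pca_embed <- function(X, n_components = 2) {
  if (nrow(X) < 2)
    stop_tep("PCA needs at least 2 samples", "tepsig_error_dimensions")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop_tep("fewer usable dimensions than requested components",
             "tepsig_error_dimensions")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, explained = explained[k])
}

#' Correlate panel genes with clinical features
#'
#' Pearson correlation for continuous features, Spearman when the feature is
#' ordered-categorical. Missing values are dropped pairwise; constant vectors
#' are skipped with a warning.
#'
#' @param expr Genes x samples expression matrix for the panel.
#' @param clinical Data.frame of per-sample clinical features (rows aligned
#'   with the columns of `expr`). Ordered factors and the features named in
#'   `ordinal` use Spearman.
#' @param ordinal Character vector of feature names to treat as ordinal.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data.frame with gene, feature, method, coefficient, p, significant.
#' @export
clinical_correlations <- function(expr, clinical, ordinal = character(),
                                  alpha = 0.05) {
  stopifnot(ncol(expr) == nrow(clinical))
  out <- list()
  for (feat in names(clinical)) {
    v <- clinical[[feat]]
    use_spearman <- feat %in% ordinal || is.ordered(v)
    if (is.ordered(v)) v <- as.integer(v)
    if (!is.numeric(v)) next  # unordered categorical: no correlation defined
    for (g in rownames(expr)) {
      x <- expr[g, ]
      ok <- stats::complete.cases(x, v)
      if (sum(ok) < 3) next
      if (stats::sd(x[ok]) == 0 || stats::sd(v[ok]) == 0) {
        warn_tep(sprintf("constant vector for %s vs %s; skipped", g, feat))
        next
      }
      ct <- suppressWarnings(stats::cor.test(
        x[ok], v[ok],
        method = if (use_spearman) "spearman" else "pearson",
        exact = FALSE
      ))
      out[[length(out) + 1L]] <- data.frame(
        gene = g, feature = feat,
        method = if (use_spearman) "spearman" else "pearson",
        coefficient = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), feature = character(),
               method = character(), coefficient = numeric(),
               p = numeric(), significant = logical())
  rownames(res) <- NULL
  res
}
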