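# Preprocessing: low-count filtering, library sizes, negative-control-gene
# discovery, location-scale batch adjustment, log transformation.

#' Remove genes with insufficient read support
#'
#' A gene is kept iff the fraction of samples in which its count is below
#' `min_count` is at most `max_frac_below`; with the defaults this drops genes
#' having fewer than five reads in strictly more than 95% of samples. Sample
#' set and gene order are preserved.
#'
#' @param counts Gene x sample integer matrix.
#' @param min_count Read-count threshold defining "detected".
#' @param max_frac_below Maximum tolerated fraction of samples below
#'   `min_count` (strictly exceeding it removes the gene).
#' @return The filtered count matrix.
#' @export
filter_low_count_genes <- function(counts, min_count = 5,
                                   max_frac_below = 0.95) {
  counts <- validate_counts(counts)
  frac_below <- rowMeans(counts < min_count)
  keep <- frac_below <= max_frac_below
  if (!any(keep))
    stop_tep(paste0("low-count filter removed every gene; relax `min_count` ",
                    "or `max_frac_below`"),
             "tepsig_error_empty_result")
  counts[keep, , drop = FALSE]
}

#' Per-sample library sizes
#'
#' Library size is the column sum of the (unfiltered) count matrix.
#' @param counts Gene x sample integer matrix.
#' @return Named numeric vector of per-sample totals.
#' @export
compute_library_sizes <- function(counts) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop_tep("cannot compute library sizes of an empty matrix",
             "tepsig_error_dimensions")
  sizes <- colSums(counts)
  zero <- names(sizes)[sizes == 0]
  if (length(zero))
    stop_tep(sprintf("sample(s) with zero total counts: %s",
                     paste(zero, collapse = ", ")),
             "tepsig_error_zero_library")
  sizes
}

#' Discover library-size-tracking negative control genes
#'
#' Computes, per gene, the Pearson correlation between its raw counts and the
#' library sizes, and returns the genes whose correlation strictly exceeds
#' `r_threshold`. These library-size-tracking genes serve as negative controls
#' for unwanted-variation estimation: they are assumed untouched by the biology
#' of interest but fully exposed to technical variation. The threshold is
#' signed (strongly anti-correlated genes are not selected).
#'
#' @param counts Filtered gene x sample count matrix.
#' @param sizes Per-sample library sizes (from the unfiltered matrix).
#' @param r_threshold Signed Pearson correlation cutoff (strict).
#' @return A data.frame (class `"control_genes"`) with columns `gene` and `r`,
#'   ordered by decreasing correlation.
#' @export
select_control_genes <- function(counts, sizes, r_threshold = 0.7) {
  counts <- validate_counts(counts)
  if (ncol(counts) < 3)
    stop_tep("control-gene discovery needs at least 3 samples",
             "tepsig_error_dimensions")
  if (!identical(colnames(counts), names(sizes)))
    sizes <- sizes[colnames(counts)]
  if (anyNA(sizes))
    stop_tep("library sizes missing for some samples",
             "tepsig_error_dimensions")
  sds <- apply(counts, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warn_tep(sprintf(
      "%d constant gene(s) excluded from control-gene discovery", sum(constant)))
  x <- counts[!constant, , drop = FALSE]
  r <- as.vector(stats::cor(t(x), sizes))
  sel <- r > r_threshold
  out <- data.frame(gene = rownames(x)[sel], r = r[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("control_genes", "data.frame")
  out
}

#' Location-scale batch adjustment
#'
#' Per gene, fits a linear model with the class label as a protected
#' covariate and batch as a nuisance term, removes the batch-specific mean
#' shift, rescales within-batch residuals to the pooled residual scale, and
#' re-adds the protected class effect. This is a fully specified
#' location-scale adjuster in the ComBat family, deliberately without
#' empirical-Bayes shrinkage across genes.
#'
#' @param log_expr Gene x sample matrix on the log scale.
#' @param design Study design providing `class` and `batch` per sample
#'   (column order of `log_expr`).
#' @return Adjusted matrix with identical dimnames. With a single batch the
#'   input is returned unchanged.
#' @export
batch_adjust <- function(log_expr, design) {
  batch <- droplevels(factor(design$batch))
  if (nlevels(batch) < 2) return(log_expr)
  tab <- table(batch)
  if (any(tab < 2))
    stop_tep(sprintf("batch(es) with fewer than 2 samples: %s",
                     paste(names(tab)[tab < 2], collapse = ", ")),
             "tepsig_error_batch")
  y <- factor(design$class)
  has_class <- nlevels(droplevels(y)) == 2
  # one shared design matrix for all genes
  mm_full <- if (has_class) stats::model.matrix(~ y + batch)
             else stats::model.matrix(~ batch)
  mm_prot <- if (has_class) stats::model.matrix(~ y)
             else stats::model.matrix(~ 1, data = data.frame(x = seq_along(batch)))
  qr_full <- qr(mm_full)
  n_prot <- ncol(mm_prot)
  adj <- t(apply(log_expr, 1L, function(yy) {
    beta <- qr.coef(qr_full, yy)
    beta[is.na(beta)] <- 0
    fitted <- as.vector(mm_full %*% beta)
    resid <- yy - fitted
    protected <- as.vector(mm_prot %*% beta[seq_len(n_prot)])
    # batch effects are removed up to their sample-weighted mean, so the
    # grand mean of the gene is preserved
    batch_eff <- fitted - protected
    scl <- tapply(resid, batch, stats::sd)
    scl[is.na(scl) | scl == 0] <- 1
    pooled <- sqrt(sum((tab - 1) * scl^2) / sum(tab - 1))
    protected + mean(batch_eff) + resid * (pooled / scl[batch])
  }))
  dimnames(adj) <- dimnames(log_expr)
  adj
}

#' Log2 transform with pseudocount
#'
#' @param counts Non-negative matrix.
#' @param pseudocount Non-negative offset added before taking log2.
#' @return `log2(counts + pseudocount)` with dimnames preserved.
#' @export
log_transform <- function(counts, pseudocount = 1) {
  if (!is_scalar_num(pseudocount) || pseudocount < 0)
    stop_tep("pseudocount must be a non-negative number",
             "tepsig_error_config")
  if (any(counts < 0))
    stop_tep("counts contain negative values", "tepsig_error_negative")
  log2(counts + pseudocount)
}
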