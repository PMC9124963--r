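# Removal of unwanted variation using negative control genes (RUVg-style).
# Model: Y = X beta + W alpha + eps on the log scale; W is estimated from the
# control-gene submatrix, which by assumption carries no biology of interest.

#' Estimate factors of unwanted variation from control genes
#'
#' Centers each control gene, takes the rank-`k` truncated SVD of the
#' control-gene submatrix, and sets the sample-level factors `W` to the first
#' `k` right-singular vectors scaled by their singular values. Gene loadings
#' `alpha` for *all* genes are then obtained by least-squares regression of the
#' per-gene-centered expression on `W`. Class labels are never consulted.
#'
#' @param log_expr Gene x sample log-expression matrix.
#' @param controls A `control_genes` data.frame (or character vector of gene
#'   ids) naming the negative controls.
#' @param k Number of factors (0 allowed; removal is then the identity).
#' @return An object of class `"ruv_factors"`: list with `W` (samples x k),
#'   `alpha` (k x genes), `k`, and `d` (singular values of the centered
#'   control matrix, for scree inspection).
#' @export
estimate_unwanted_factors <- function(log_expr, controls, k = 1) {
  genes <- if (is.data.frame(controls)) controls$gene else as.character(controls)
  if (length(genes) == 0)
    stop_tep("empty control-gene set", "tepsig_error_controls")
  missing_genes <- setdiff(genes, rownames(log_expr))
  if (length(missing_genes))
    stop_tep(sprintf("control gene(s) absent from expression matrix: %s",
                     paste(utils::head(missing_genes, 5), collapse = ", ")),
             "tepsig_error_controls")
  n <- ncol(log_expr)
  if (!is_count(k) || k > min(n, length(genes)))
    stop_tep(sprintf("k must be an integer in [0, min(%d samples, %d controls)]",
                     n, length(genes)),
             "tepsig_error_ruv_k")
  ctl <- log_expr[genes, , drop = FALSE]
  ctl_c <- ctl - rowMeans(ctl)
  sv <- svd(ctl_c)
  if (k == 0) {
    W <- matrix(numeric(0), nrow = n, ncol = 0)
    alpha <- matrix(numeric(0), nrow = 0, ncol = nrow(log_expr),
                    dimnames = list(NULL, rownames(log_expr)))
  } else {
    W <- sv$v[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], nrow = k)
    expr_c <- log_expr - rowMeans(log_expr)
    # alpha = (W'W)^-1 W' Y' for every gene at once
    alpha <- solve(crossprod(W), crossprod(W, t(expr_c)))
    dimnames(alpha) <- list(NULL, rownames(log_expr))
  }
  rownames(W) <- colnames(log_expr)
  structure(list(W = W, alpha = alpha, k = k, d = sv$d),
            class = "ruv_factors")
}

#' Subtract estimated unwanted variation
#'
#' Returns `log_expr - (W alpha)'`. Because `W`'s columns are orthogonal to
#' the constant vector (the control matrix is row-centered), per-gene means
#' are preserved exactly.
#'
#' @param log_expr Gene x sample log-expression matrix.
#' @param uv A `ruv_factors` object estimated on the same samples.
#' @return Normalized matrix, same shape and dimnames as the input.
#' @export
remove_unwanted_variation <- function(log_expr, uv) {
  stopifnot(inherits(uv, "ruv_factors"))
  if (uv$k == 0) return(log_expr)
  if (nrow(uv$W) != ncol(log_expr) || ncol(uv$alpha) != nrow(log_expr))
    stop_tep("dimension mismatch between expression matrix and RUV factors",
             "tepsig_error_dimensions")
  out <- log_expr - t(uv$W %*% uv$alpha)
  dimnames(out) <- dimnames(log_expr)
  out
}
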