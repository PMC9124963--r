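# Per-gene logistic-regression differential expression.
# The class label is regressed on one gene's (normalized, log2) expression at
# a time: logit P(case) = b0 + b1 * x. Wald p-values; BH adjustment; fold
# change as the difference of class means on the log2 scale.

#' Logistic-regression association of one gene with the class label
#'
#' Maximum-likelihood fit of `logit P(case) = b0 + b1 x` by iteratively
#' reweighted least squares, with a Wald p-value for `b1`. Perfect (or
#' quasi-perfect) separation is detected and handled by a Firth-type
#' Jeffreys-penalized refit; the fallback is recorded in the `separated` flag.
#'
#' @param x Per-sample expression values (finite reals).
#' @param y Class labels: factor with levels control/case, or a 0/1 vector.
#' @return List with `beta` (slope per log2 unit), `p` (Wald), `se`, and
#'   `separated` (logical).
#' @export
fit_gene_logistic <- function(x, y) {
  yb <- as_binary_class(y)
  if (length(unique(yb)) < 2)
    stop_tep("both classes must be present", "tepsig_error_single_class")
  if (anyNA(x) || any(!is.finite(x)))
    stop_tep("expression values must be finite", "tepsig_error_non_numeric")
  if (stats::sd(x) == 0)
    return(list(beta = 0, p = 1, se = Inf, separated = FALSE))
  X <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(X, yb, family = stats::binomial())
  )
  eps <- 1e-8
  # quasi-separation also manifests as an absurd slope per SD of x, where
  # the Wald statistic has already collapsed (Hauck-Donner)
  separated <- !fit$converged ||
    any(fit$fitted.values > 1 - eps) || any(fit$fitted.values < eps) ||
    abs(fit$coefficients[2]) * stats::sd(x) > 10
  if (!separated) {
    beta <- fit$coefficients[2]
    pr <- fit$fitted.values
    info <- crossprod(X, X * (pr * (1 - pr)))
    se <- sqrt(diag(solve(info)))[2]
  } else {
    ff <- firth_logistic(X, yb)
    beta <- ff$beta[2]
    se <- ff$se[2]
  }
  z <- beta / se
  list(beta = unname(beta),
       p = unname(2 * stats::pnorm(-abs(z))),
       se = unname(se),
       separated = separated)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used only as the separation fallback. Newton iteration on the modified
# score U*(b) = X'(y - p + h (1/2 - p)), h = leverages of the weighted fit.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X, X * w)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * w
    score <- crossprod(X, y - pr + h * (0.5 - pr))
    delta <- as.vector(inv %*% score)
    # dampen huge steps for stability under separation
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-12)
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  list(beta = beta, se = se)
}

as_binary_class <- function(y) {
  if (is.factor(y)) {
    lev <- levels(droplevels(y))
    if (length(lev) > 2)
      stop_tep("class label has more than two levels",
               "tepsig_error_schema")
    as.integer(droplevels(y)) - 1L
  } else if (is.numeric(y) && all(y %in% c(0, 1))) {
    as.integer(y)
  } else if (is.character(y)) {
    as_binary_class(factor(y, levels = c("control", "case")))
  } else {
    stop_tep("class labels must be a two-level factor or 0/1 vector",
             "tepsig_error_schema")
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (step-up, capped at 1, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_tep("p-values must lie in [0, 1]", "tepsig_error_pvalues")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change between classes
#'
#' Defined as the difference of class means on the log2 expression scale, so
#' `|FC| > 2` is equivalent to `|log2fc| > 1`.
#' @inheritParams fit_gene_logistic
#' @return Scalar log2 fold change (case minus control).
#' @export
compute_fold_change <- function(x, y) {
  yb <- as_binary_class(y)
  if (length(unique(yb)) < 2)
    stop_tep("both classes must be present", "tepsig_error_single_class")
  mean(x[yb == 1]) - mean(x[yb == 0])
}

#' Gene-wise differential expression over a matrix
#'
#' Applies [fit_gene_logistic()] and [compute_fold_change()] to every gene and
#' adds BH-adjusted p-values and a direction call at the supplied thresholds.
#'
#' @param log_expr Normalized gene x sample log2-expression matrix.
#' @param y Class labels (see [fit_gene_logistic()]).
#' @param p_adj_max,min_abs_log2fc Strict thresholds used for the `direction`
#'   column.
#' @return A data.frame of class `"de_result"` with columns gene, beta, se, p,
#'   p_adj, log2fc, direction (`up`/`down`/`ns`), separated.
#' @export
run_diffexp <- function(log_expr, y, p_adj_max = 0.05, min_abs_log2fc = 1) {
  yb <- as_binary_class(y)
  fits <- apply(log_expr, 1L, function(x) {
    f <- fit_gene_logistic(x, yb)
    c(f$beta, f$se, f$p, as.numeric(f$separated))
  })
  log2fc <- apply(log_expr, 1L, compute_fold_change, y = yb)
  de <- data.frame(
    gene = rownames(log_expr),
    beta = fits[1, ], se = fits[2, ], p = fits[3, ],
    p_adj = bh_adjust(fits[3, ]),
    log2fc = log2fc,
    separated = fits[4, ] == 1,
    stringsAsFactors = FALSE
  )
  de$direction <- ifelse(
    de$p_adj < p_adj_max & de$log2fc > min_abs_log2fc, "up",
    ifelse(de$p_adj < p_adj_max & de$log2fc < -min_abs_log2fc, "down", "ns")
  )
  rownames(de) <- NULL
  class(de) <- c("de_result", "data.frame")
  de
}

#' Select differentially expressed genes
#'
#' Strict thresholds: `up` requires `p_adj < p_adj_max` and
#' `log2fc > min_abs_log2fc`; `down` analogously with the negated bound. When
#' `raw_p` is supplied, the significance filter is `p < raw_p` on the raw
#' p-value instead (the secondary selection mode).
#'
#' @param de A `de_result` data.frame.
#' @param p_adj_max,min_abs_log2fc Strict selection thresholds.
#' @param raw_p Optional raw p-value threshold replacing the adjusted one.
#' @return List with character vectors `up` and `down`.
#' @export
select_degs <- function(de, p_adj_max = 0.05, min_abs_log2fc = 1,
                        raw_p = NULL) {
  sig <- if (is.null(raw_p)) de$p_adj < p_adj_max else de$p < raw_p
  list(up = de$gene[sig & de$log2fc > min_abs_log2fc],
       down = de$gene[sig & de$log2fc < -min_abs_log2fc])
}
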