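# Gaussian-kernel SVM training with leave-one-out cross-validation.
# Discipline: for every left-out sample, feature standardization and
# hyperparameter selection use only the n-1 training fold; the held-out
# sample is scored blind with the signed decision value.

#' SVM hyperparameter grid
#'
#' Default search ranges: gamma in 10^(-10..1) (12 values) and cost in
#' 2^(1..10) (10 values).
#' @param gamma,cost Strictly positive candidate values.
#' @return List with sorted `gamma` and `cost` vectors.
#' @export
svm_grid <- function(gamma = 10^(-10:1), cost = 2^(1:10)) {
  if (!length(gamma) || !length(cost) || any(gamma <= 0) || any(cost <= 0))
    stop_tep("grids must be non-empty and strictly positive",
             "tepsig_error_config")
  list(gamma = sort(gamma), cost = sort(cost))
}

# --- internals -------------------------------------------------------------

std_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  if (any(scale == 0)) {
    warn_tep("constant feature(s) in training fold; scale set to 1")
    scale[scale == 0] <- 1
  }
  list(center = center, scale = scale)
}

std_apply <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

svm_train_raw <- function(X, y, gamma, cost) {
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = cost, scale = FALSE)
}

# signed decision value oriented so that larger = more case-like
svm_score <- function(model, X) {
  pred <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lab <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]]
  score <- if (lab[1] == "case") dv[, 1] else -dv[, 1]
  list(score = unname(score), class = unname(pred))
}

as_class_factor <- function(y) {
  yb <- as_binary_class(y)
  factor(ifelse(yb == 1, "case", "control"), levels = c("control", "case"))
}

# stratified fold assignment, deterministic given seed
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

# cross-validated accuracy over the grid; ties go to smaller cost, then
# smaller gamma (the simplest model)
grid_search <- function(X, y, grid, seed) {
  combos <- expand.grid(gamma = grid$gamma, cost = grid$cost,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$cost, combos$gamma), , drop = FALSE]
  k <- min(5L, min(table(y)))
  if (k < 2) {  # too few for inner CV: fall back to resubstitution
    acc <- vapply(seq_len(nrow(combos)), function(i) {
      m <- svm_train_raw(X, y, combos$gamma[i], combos$cost[i])
      mean(stats::predict(m, X) == y)
    }, numeric(1))
  } else {
    folds <- make_folds(y, k, seed)
    acc <- vapply(seq_len(nrow(combos)), function(i) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        m <- svm_train_raw(X[tr, , drop = FALSE], y[tr],
                           combos$gamma[i], combos$cost[i])
        correct <- correct +
          sum(stats::predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
  }
  best <- which(acc >= max(acc) - 1e-12)[1]
  list(gamma = combos$gamma[best], cost = combos$cost[best],
       accuracy = acc[best])
}

# --- public surface --------------------------------------------------------

#' Leave-one-out cross-validation of a Gaussian-kernel SVM
#'
#' For each sample: standardize the signature features on the remaining n-1
#' samples, select `(gamma, cost)` on that fold by stratified inner
#' cross-validated accuracy over the grid (ties toward smaller cost, then
#' smaller gamma), train, and score the held-out sample with the signed
#' decision value (positive = case-like). The modal `(gamma, cost)` across
#' folds is reported as the chosen parameter pair. Fully deterministic given
#' `seed`.
#'
#' @param X Samples x features numeric matrix (signature genes as columns).
#' @param y Class labels (two-level factor or 0/1; 1 = case).
#' @param grid An [svm_grid()]. Ignored when `gamma` and `cost` are supplied.
#' @param seed Integer seed for inner fold assignment.
#' @param gamma,cost Optional fixed hyperparameters; when both are given the
#'   inner grid search is skipped (used for leakage audits).
#' @return Object of class `"loocv_result"`: data.frame `samples` (sample,
#'   actual, score, predicted, gamma, cost), chosen `gamma`/`cost`,
#'   `accuracy`, `mcc`.
#' @export
loocv_evaluate <- function(X, y, grid = svm_grid(), seed = 1L,
                           gamma = NULL, cost = NULL) {
  y <- as_class_factor(y)
  if (min(table(y)) < 2)
    stop_tep("need at least 2 samples per class for LOOCV",
             "tepsig_error_degenerate")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  fixed <- !is.null(gamma) && !is.null(cost)
  fold_seeds <- derive_seeds(seed, n)
  score <- numeric(n)
  predicted <- character(n)
  g_used <- numeric(n)
  c_used <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    std <- std_fit(Xtr)
    Xtr_s <- std_apply(Xtr, std)
    if (fixed) {
      gi <- gamma; ci <- cost
    } else {
      sel <- grid_search(Xtr_s, ytr, grid, fold_seeds[i])
      gi <- sel$gamma; ci <- sel$cost
    }
    m <- svm_train_raw(Xtr_s, ytr, gi, ci)
    sc <- svm_score(m, std_apply(X[i, , drop = FALSE], std))
    score[i] <- sc$score
    predicted[i] <- as.character(sc$class)
    g_used[i] <- gi
    c_used[i] <- ci
  }
  combo <- paste(g_used, c_used, sep = "|")
  tab <- table(combo)
  modal <- names(tab)[tab == max(tab)]
  parts <- do.call(rbind, strsplit(modal, "|", fixed = TRUE))
  ordc <- order(as.numeric(parts[, 2]), as.numeric(parts[, 1]))
  chosen_gamma <- as.numeric(parts[ordc[1], 1])
  chosen_cost <- as.numeric(parts[ordc[1], 2])
  predicted <- factor(predicted, levels = c("control", "case"))
  cm <- confusion_matrix(predicted == "case", y == "case")
  stats <- confusion_stats(cm)
  structure(list(
    samples = data.frame(
      sample = rownames(X) %||% as.character(seq_len(n)),
      actual = y, score = score, predicted = predicted,
      gamma = g_used, cost = c_used, stringsAsFactors = FALSE),
    gamma = chosen_gamma, cost = chosen_cost,
    confusion = cm, accuracy = stats$accuracy, mcc = stats$mcc
  ), class = "loocv_result")
}

#' Diagnostic performance as a function of signature size
#'
#' Runs [loocv_evaluate()] on the top-`m` ranked genes for each candidate
#' size and reports accuracy and MCC per size, together with the recommended
#' size: the smallest `m` whose accuracy is within `delta` of the best.
#'
#' @param ranking An [rank_mrmr()] result.
#' @param X Samples x genes matrix covering at least the ranked genes.
#' @param y Class labels.
#' @param grid An [svm_grid()].
#' @param sizes Signature sizes to evaluate (default `1:nrow(ranking)`).
#' @param seed Integer seed.
#' @param delta Accuracy tolerance for the recommended size.
#' @return Data.frame of class `"signature_curve"` (size, accuracy, mcc) with
#'   attribute `recommended`.
#' @export
signature_size_curve <- function(ranking, X, y, grid = svm_grid(),
                                 sizes = seq_len(nrow(ranking)), seed = 1L,
                                 delta = 0.02) {
  if (max(sizes) > nrow(ranking))
    stop_tep("requested size exceeds ranking length",
             "tepsig_error_dimensions")
  res <- lapply(sizes, function(m) {
    genes <- ranking$gene[seq_len(m)]
    cv <- loocv_evaluate(X[, genes, drop = FALSE], y, grid, seed = seed)
    data.frame(size = m, accuracy = cv$accuracy, mcc = cv$mcc)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  recommended <- out$size[out$accuracy >= max(out$accuracy) - delta][1]
  structure(out, recommended = recommended,
            class = c("signature_curve", "data.frame"))
}

#' Fit the final frozen SVM on the full training cohort
#'
#' Standardizes features on the training cohort, trains at the fixed
#' `(gamma, cost)`, and freezes the centers/scales and signature gene list so
#' later scoring can never be influenced by new samples.
#'
#' @param X Samples x signature-genes training matrix.
#' @param y Training class labels.
#' @param gamma,cost Fixed hyperparameters (typically the LOOCV modal pair).
#' @return Object of class `"tep_svm"`.
#' @export
fit_final <- function(X, y, gamma, cost) {
  y <- as_class_factor(y)
  if (is.null(colnames(X)))
    stop_tep("training matrix must carry gene column names",
             "tepsig_error_missing_ids")
  std <- std_fit(X)
  model <- svm_train_raw(std_apply(X, std), y, gamma, cost)
  structure(list(model = model, std = std, genes = colnames(X),
                 gamma = gamma, cost = cost),
            class = "tep_svm")
}

#' Score new samples with a frozen SVM
#'
#' @param model A `"tep_svm"` from [fit_final()].
#' @param X_new Samples x genes matrix; must contain every signature gene.
#'   Extra columns are ignored.
#' @return Numeric vector of signed decision scores (positive = case-like),
#'   named by sample.
#' @export
predict_scores <- function(model, X_new) {
  stopifnot(inherits(model, "tep_svm"))
  miss <- setdiff(model$genes, colnames(X_new))
  if (length(miss))
    stop_tep(sprintf("signature gene(s) missing from new data: %s",
                     paste(miss, collapse = ", ")),
             "tepsig_error_missing_genes")
  X <- X_new[, model$genes, drop = FALSE]
  sc <- svm_score(model$model, std_apply(X, model$std))
  stats::setNames(sc$score, rownames(X_new))
}

#' Youden-optimal score cutoff
#'
#' Sweeps the midpoints between adjacent sorted unique scores and returns the
#' cutoff maximizing the Youden index `J = sensitivity + specificity - 1`
#' (samples scoring above the cutoff are called cases). Ties are resolved
#' toward the lower cutoff, i.e. higher sensitivity.
#'
#' @param scores Signed prediction scores.
#' @param y Class labels (1/"case" = positive).
#' @return List with `cutoff` and `youden`.
#' @export
choose_cutoff <- function(scores, y) {
  yb <- as_binary_class(y)
  if (length(unique(yb)) < 2)
    stop_tep("both classes must be present", "tepsig_error_single_class")
  u <- sort(unique(scores))
  if (length(u) < 2)
    stop_tep("all prediction scores identical; no cutoff exists",
             "tepsig_error_degenerate")
  mids <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(mids, function(ct) {
    pred <- scores > ct
    sens <- sum(pred & yb == 1) / sum(yb == 1)
    spec <- sum(!pred & yb == 0) / sum(yb == 0)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]
  list(cutoff = mids[best], youden = j[best])
}
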