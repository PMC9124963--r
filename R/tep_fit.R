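#' Fit a tumor-educated-platelet diagnostic signature
#'
#' Runs the full signature-discovery pipeline on a raw gene-by-sample count
#' matrix: low-count gene filtering, library-size computation, log2
#' transformation, location-scale batch adjustment, negative-control-gene
#' discovery, removal of unwanted variation from control-gene factors,
#' logistic-regression differential expression on the training cohort,
#' mRMR ranking of the top DEGs, leave-one-out cross-validated SVM training
#' with grid search, Youden cutoff selection, and -- when the design contains
#' a validation cohort -- frozen-model scoring and evaluation of the
#' validation samples.
#'
#' Preprocessing stages (filtering, batch adjustment, control-gene discovery,
#' unwanted-variation removal) never consult the class label and are applied
#' to all samples jointly; every label-aware stage (DE, mRMR, SVM, cutoff) is
#' fit on the training cohort only, and validation samples are scored with
#' training-frozen standardization and model.
#'
#' @param counts Integer gene x sample count matrix (see [read_counts()]).
#' @param design Study design data.frame (see [read_design()]).
#' @param config A [tep_config()].
#' @return An object of class `"tep_fit"` with components `signature`,
#'   `ranking`, `de`, `controls`, `ruv`, `loocv`, `model` (the frozen
#'   `tep_svm`), `cutoff`, `reports` (per-cohort `classifier_report`s),
#'   `normalized` (the normalized log2 matrix), `design`, and `config`.
#' @seealso [predict.tep_fit()], [summary.tep_fit()], [plot.tep_fit()]
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(n_genes = 400, n_housekeeping = 40,
#'                                  n_de = 10, seed = 7))
#' fit <- tep_fit(sim$counts, sim$design,
#'                tep_config(mrmr_pool = 50, gamma_grid = 10^(-3:0),
#'                           cost_grid = 2^(1:4)))
#' print(fit)
#' }
#' @export
tep_fit <- function(counts, design, config = tep_config()) {
  validate_config(config)
  counts <- validate_counts(counts)
  design <- validate_design(design, counts, case_label = config$case_label)

  # label-free preprocessing on all samples
  sizes <- compute_library_sizes(counts)
  filtered <- filter_low_count_genes(counts, config$min_count,
                                     config$max_frac_below)
  log_expr <- log_transform(filtered, config$pseudocount)
  log_expr <- batch_adjust(log_expr, design)
  controls <- select_control_genes(filtered, sizes, config$control_r)
  if (nrow(controls) == 0)
    stop_tep("no negative control genes found; lower `control_r`",
             "tepsig_error_controls")
  k <- min(config$ruv_k, ncol(log_expr), nrow(controls))
  ruv <- estimate_unwanted_factors(log_expr, controls, k)
  normalized <- remove_unwanted_variation(log_expr, ruv)

  train <- design$cohort == "training"
  y_train <- design$class[train]
  if (length(unique(y_train)) < 2)
    stop_tep("training cohort must contain both classes",
             "tepsig_error_degenerate")

  # label-aware stages: training cohort only
  de <- run_diffexp(normalized[, train, drop = FALSE], y_train,
                    config$de_p_adj, config$de_min_log2fc)
  degs <- select_degs(de, config$de_p_adj, config$de_min_log2fc,
                      raw_p = config$de_raw_p)
  deg_genes <- c(degs$up, degs$down)
  if (length(deg_genes) == 0)
    stop_tep("no differentially expressed genes at the configured thresholds",
             "tepsig_error_empty_result")
  de_pool <- de[de$gene %in% deg_genes, ]
  de_pool <- de_pool[order(de_pool$p, de_pool$gene), ]
  pool <- utils::head(de_pool$gene, config$mrmr_pool)

  X_train <- t(normalized[pool, train, drop = FALSE])
  ranking <- rank_mrmr(X_train, y_train,
                       n_select = min(length(pool),
                                      max(config$signature_max,
                                          if (is_count(config$signature_size))
                                            config$signature_size else 0)),
                       scheme = config$mrmr_scheme,
                       tie_p = de_pool$p[match(colnames(X_train),
                                               de_pool$gene)])
  grid <- svm_grid(config$gamma_grid, config$cost_grid)
  seeds <- derive_seeds(config$seed, 4)

  curve <- NULL
  if (identical(config$signature_size, "auto")) {
    curve <- signature_size_curve(
      ranking, X_train, y_train, grid,
      sizes = seq_len(min(config$signature_max, nrow(ranking))),
      seed = seeds[1], delta = config$signature_delta)
    sig_size <- attr(curve, "recommended")
  } else {
    sig_size <- min(config$signature_size, nrow(ranking))
  }
  signature <- ranking$gene[seq_len(sig_size)]

  loocv <- loocv_evaluate(X_train[, signature, drop = FALSE], y_train,
                          grid, seed = seeds[2])
  model <- fit_final(X_train[, signature, drop = FALSE], y_train,
                     loocv$gamma, loocv$cost)
  cutoff <- choose_cutoff(loocv$samples$score, y_train)

  reports <- list(
    training = classifier_report(loocv$samples$score, y_train,
                                 cutoff = cutoff$cutoff, cohort = "training",
                                 n_boot = config$n_boot,
                                 level = config$ci_level, seed = seeds[3])
  )
  val <- design$cohort == "validation"
  val_scores <- NULL
  if (any(val) && length(unique(design$class[val])) == 2) {
    X_val <- t(normalized[signature, val, drop = FALSE])
    val_scores <- predict_scores(model, X_val)
    y_val <- design$class[val]
    # the training-derived cutoff applied blind, plus a cutoff re-optimized
    # on the validation scores, both labelled
    reports$validation <- classifier_report(
      val_scores, y_val, cutoff = cutoff$cutoff, cohort = "validation",
      n_boot = config$n_boot, level = config$ci_level, seed = seeds[4])
    reports$validation$cutoff_source <- "training-derived"
    val_opt <- choose_cutoff(val_scores, y_val)
    reports$validation_reoptimized <- classifier_report(
      val_scores, y_val, cutoff = val_opt$cutoff,
      cohort = "validation", n_boot = config$n_boot,
      level = config$ci_level, seed = seeds[4])
    reports$validation_reoptimized$cutoff_source <- "validation-optimized"
  }

  structure(list(
    signature = signature, ranking = ranking, curve = curve, de = de,
    degs = degs, controls = controls, ruv = ruv, loocv = loocv,
    model = model, cutoff = cutoff$cutoff, reports = reports,
    normalized = normalized, val_scores = val_scores,
    design = design, config = config,
    n_genes_raw = nrow(counts), n_genes_filtered = nrow(filtered),
    n_pool = length(pool)
  ), class = "tep_fit")
}

#' @export
print.tep_fit <- function(x, ...) {
  tr <- x$reports$training
  cat("Tumor-educated platelet diagnostic signature fit\n")
  cat(sprintf("  genes: %d raw, %d after filtering, %d negative controls\n",
              x$n_genes_raw, x$n_genes_filtered, nrow(x$controls)))
  cat(sprintf("  DEGs: %d up, %d down; mRMR pool of %d, %d ranked\n",
              length(x$degs$up), length(x$degs$down), x$n_pool,
              nrow(x$ranking)))
  cat(sprintf("  signature (%d genes): %s\n", length(x$signature),
              paste(x$signature, collapse = ", ")))
  cat(sprintf("  SVM: gamma = %g, cost = %g; score cutoff = %.4f\n",
              x$model$gamma, x$model$cost, x$cutoff))
  cat(sprintf("  training LOOCV: sens %.3f, spec %.3f, ACC %.3f, MCC %.3f, AUC %.3f\n",
              tr$sensitivity, tr$specificity, tr$accuracy, tr$mcc, tr$auc))
  if (!is.null(x$reports$validation)) {
    va <- x$reports$validation
    cat(sprintf("  validation:     sens %.3f, spec %.3f, ACC %.3f, MCC %.3f, AUC %.3f\n",
                va$sensitivity, va$specificity, va$accuracy, va$mcc, va$auc))
  }
  invisible(x)
}

#' @export
summary.tep_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.tep_fit")
}

#' @export
print.summary.tep_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-cohort reports:\n")
  for (rep in f$reports) {
    cat(sprintf(
      "  %s (cutoff %s %.4f): TP %d FP %d TN %d FN %d | AUC %.3f (%d%% CI %.3f-%.3f)\n",
      rep$cohort, rep$cutoff_source, rep$cutoff,
      rep$confusion$tp, rep$confusion$fp, rep$confusion$tn, rep$confusion$fn,
      rep$auc, round(100 * rep$ci_level), rep$auc_ci_low, rep$auc_ci_high))
  }
  cat("\nSignature genes:\n")
  print(coef(f), row.names = FALSE)
  invisible(x)
}

#' Signature-gene table of a fitted model
#'
#' @param object A `tep_fit`.
#' @param ... Unused.
#' @return Data.frame of the signature genes with mRMR rank/relevance and
#'   their differential-expression statistics.
#' @export
coef.tep_fit <- function(object, ...) {
  r <- object$ranking[object$ranking$gene %in% object$signature,
                      c("rank", "gene", "relevance", "score")]
  de <- object$de[match(r$gene, object$de$gene),
                  c("beta", "p", "p_adj", "log2fc")]
  cbind(r, de)
}

#' Score new samples with a fitted signature model
#'
#' @param object A `tep_fit`.
#' @param newdata Gene x sample log2-normalized expression matrix containing
#'   the signature genes (e.g. the `normalized` component for in-study
#'   samples), or NULL to return the training LOOCV scores.
#' @param type `"score"` for signed decision values, `"class"` for the
#'   cutoff-thresholded class call.
#' @param ... Unused.
#' @return Named numeric vector of scores, or factor of class calls.
#' @export
predict.tep_fit <- function(object, newdata = NULL,
                            type = c("score", "class"), ...) {
  type <- match.arg(type)
  scores <- if (is.null(newdata)) {
    stats::setNames(object$loocv$samples$score, object$loocv$samples$sample)
  } else {
    predict_scores(object$model, t(newdata[object$signature, , drop = FALSE]))
  }
  if (type == "score") return(scores)
  factor(ifelse(scores > object$cutoff, "case", "control"),
         levels = c("control", "case"))
}

#' Plot ROC curves of a fitted signature model
#'
#' Draws the training-cohort ROC curve (and the validation curve when
#' present) with AUCs in the legend.
#' @param x A `tep_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tep_fit <- function(x, ...) {
  tr <- x$reports$training
  graphics::plot(tr$roc$fpr, tr$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "SVM/LOOCV diagnostic model", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  leg <- sprintf("training AUC = %.3f", tr$auc)
  col <- "black"
  if (!is.null(x$reports$validation)) {
    va <- x$reports$validation
    graphics::lines(va$roc$fpr, va$roc$tpr, lwd = 2, col = "firebrick")
    leg <- c(leg, sprintf("validation AUC = %.3f", va$auc))
    col <- c(col, "firebrick")
  }
  graphics::legend("bottomright", legend = leg, col = col, lwd = 2, bty = "n")
  invisible(x)
}
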