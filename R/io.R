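# On-disk formats: TSV (genes x samples, header row, first column = gene id),
# MatrixMarket MTX with companion gene/sample index files, JSON reports.
# Readers validate and reject; they never coerce malformed input.

#' Read a gene-by-sample count matrix
#'
#' @param path Path to a TSV (gene rows, sample columns, header, first column
#'   gene ids) or a MatrixMarket `.mtx` file.
#' @param format `"tsv"` or `"mtx"`. For MTX, gene and sample identifiers are
#'   read from `<path>.genes` and `<path>.samples` (one id per line).
#' @return An integer matrix (genes x samples) with unique dimnames.
#' @details Duplicate gene or sample identifiers, negative, missing or
#'   non-integer entries are rejected with distinct error classes.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_tep(sprintf("count file not found: %s", path),
             "tepsig_error_missing_file")
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2)
      stop_tep("count TSV needs a gene-id column plus >=1 sample column",
               "tepsig_error_dimensions")
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    samples <- colnames(vals)
    if (!is.numeric(vals))
      stop_tep("count TSV contains non-numeric cells",
               "tepsig_error_non_numeric")
    counts <- matrix(vals, nrow = nrow(df),
                     dimnames = list(genes, samples))
  } else {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes"))
    samples <- readLines(paste0(path, ".samples"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop_tep("MTX dimensions do not match gene/sample index files",
               "tepsig_error_dimensions")
    counts <- as.matrix(m)
    dimnames(counts) <- list(genes, samples)
  }
  validate_counts(counts)
}

#' @rdname read_counts
#' @param counts Validated integer count matrix.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks dimnames presence/uniqueness and that all entries are non-negative
#' integers; returns the matrix in integer storage.
#' @param counts Numeric matrix, genes x samples.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_tep("counts must be a numeric matrix", "tepsig_error_non_numeric")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_tep("counts must carry gene row names and sample column names",
             "tepsig_error_missing_ids")
  if (anyDuplicated(rownames(counts)))
    stop_tep("duplicate gene identifiers in count matrix",
             "tepsig_error_duplicate_ids")
  if (anyDuplicated(colnames(counts)))
    stop_tep("duplicate sample identifiers in count matrix",
             "tepsig_error_duplicate_ids")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop_tep("counts contain missing or non-finite values",
             "tepsig_error_non_numeric")
  if (any(counts < 0))
    stop_tep("counts contain negative values", "tepsig_error_negative")
  if (any(counts != floor(counts)))
    stop_tep("counts contain non-integer values", "tepsig_error_non_integer")
  storage.mode(counts) <- "integer"
  counts
}

#' Read a study-design table
#'
#' Expects a TSV with columns `sample`, `class`, `cohort` and optionally
#' `batch` plus any clinical covariate columns. Class labels equal to
#' `case_label` map to `"case"`, `"control"` stays `"control"`; anything else
#' is rejected. Cohort must be `"training"` or `"validation"`.
#'
#' @param path TSV file path.
#' @param case_label Class label to map to "case" (default `"ESCC"`).
#' @return A data.frame with at least columns sample/class/cohort/batch, class
#'   and cohort as factors with fixed level sets, extra columns preserved as
#'   clinical covariates.
#' @export
read_design <- function(path, case_label = "ESCC") {
  if (!file.exists(path))
    stop_tep(sprintf("design file not found: %s", path),
             "tepsig_error_missing_file")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_design(df, case_label = case_label)
}

#' @rdname read_design
#' @param design Study-design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a study-design table
#'
#' @inheritParams read_design
#' @param design Data.frame with sample/class/cohort (+ optional batch and
#'   clinical columns).
#' @param counts Optional count matrix to cross-check sample coverage against.
#' @export
validate_design <- function(design, counts = NULL, case_label = "ESCC") {
  need <- c("sample", "class", "cohort")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols))
    stop_tep(sprintf("design is missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "tepsig_error_schema")
  design$sample <- as.character(design$sample)
  if (anyDuplicated(design$sample))
    stop_tep("duplicate sample identifiers in design",
             "tepsig_error_duplicate_ids")
  cls <- as.character(design$class)
  cls[cls == case_label] <- "case"
  bad <- setdiff(unique(cls), c("case", "control"))
  if (length(bad))
    stop_tep(sprintf("unknown class label(s) in design: %s",
                     paste(bad, collapse = ", ")), "tepsig_error_schema")
  design$class <- factor(cls, levels = c("control", "case"))
  coh <- as.character(design$cohort)
  bad <- setdiff(unique(coh), c("training", "validation"))
  if (length(bad))
    stop_tep(sprintf("unknown cohort label(s) in design: %s",
                     paste(bad, collapse = ", ")), "tepsig_error_schema")
  design$cohort <- factor(coh, levels = c("training", "validation"))
  if (is.null(design$batch)) design$batch <- "b1"
  design$batch <- factor(design$batch)
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), design$sample)
    if (length(miss))
      stop_tep(sprintf("samples present in counts but absent from design: %s",
                       paste(miss, collapse = ", ")),
               "tepsig_error_schema")
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
    rownames(design) <- NULL
    for (co in levels(design$cohort)) {
      sub <- design$class[design$cohort == co]
      if (length(sub) && length(unique(sub)) < 2)
        warn_tep(sprintf("cohort '%s' does not contain both classes", co))
    }
  }
  design
}

#' Write or read a classifier report as JSON
#'
#' Numeric fields survive a round trip to at least 12 significant digits.
#' @param report A list (typically a `classifier_report`).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_tep(sprintf("report file not found: %s", path),
             "tepsig_error_missing_file")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
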