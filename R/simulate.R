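# Synthetic platelet RNA-seq studies with known ground truth.
#
# Counts are negative-binomial around mu_ij = L_j * b_i * 2^(s_i fc_i c_j) *
# exp(batch_{b(j),i} + lambda_i w_j): log-normal library-size factors L_j,
# heavy-tailed (log-normal) baselines b_i, a planted class effect on the DE
# genes, per-batch per-gene log-scale offsets, and a latent technical factor
# w_j with gene-specific loadings lambda_i. Housekeeping genes have large
# baselines, no class effect and no loading, so their counts track library
# size and are discoverable as negative controls.

#' Simulation configuration
#'
#' @param n_case,n_control Samples per class.
#' @param n_genes Total genes.
#' @param n_housekeeping Library-size-tracking control genes (no class
#'   effect, no latent-factor loading, high baseline).
#' @param n_de Planted class-associated genes.
#' @param log2_fc Planted effect size in log2 units.
#' @param frac_up Fraction of planted genes that are upregulated in cases.
#' @param nb_dispersion Negative-binomial size parameter for housekeeping
#'   genes (larger = less overdispersed). Housekeeping transcripts are
#'   modelled as technically noisy only, which is what makes them
#'   library-size-tracking and discoverable as negative controls.
#' @param bio_dispersion Negative-binomial size parameter for background
#'   (null) genes, whose counts carry biological variation on top of
#'   technical noise; the default (1) corresponds to a squared biological
#'   coefficient of variation of 1, typical of bulk RNA-seq.
#' @param de_dispersion Negative-binomial size parameter for the planted
#'   class-associated genes. The default (2) models reliable biomarkers:
#'   less volatile than the background transcriptome, noisier than
#'   housekeeping.
#' @param libsize_log_mean,libsize_log_sd Natural-log mean/sd of the
#'   log-normal library-size factors.
#' @param n_batches Number of batches (assigned stratified by class).
#' @param batch_shift_sd SD of per-batch per-gene log-scale offsets.
#' @param uv_strength SD of the latent-factor loadings `lambda_i` on affected
#'   genes.
#' @param frac_uv_genes Fraction of non-housekeeping genes carrying a
#'   latent-factor loading.
#' @param uv_mode `"depth-linked"` (default): the latent technical factor is
#'   the standardized log library-size factor, modelling a common cause (RNA
#'   yield/quality) behind sequencing depth and gene-specific responses -- the
#'   situation RUVg control genes are designed for. `"independent"`: the
#'   factor is standard normal, independent of depth and class.
#' @param uv_confound Shift of the log library-size factor in cases (0 =
#'   unconfounded). Positive values make cases sequenced deeper, confounding
#'   the technical factor with the class -- the RUV stress-test mode.
#' @param seed Integer seed; the study is a deterministic function of the
#'   configuration.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_case = 40, n_control = 40, n_genes = 2000,
                       n_housekeeping = 100, n_de = 30, log2_fc = 1.5,
                       frac_up = 0.7, nb_dispersion = 20, bio_dispersion = 1,
                       de_dispersion = 2,
                       libsize_log_mean = 0, libsize_log_sd = 0.5,
                       n_batches = 2, batch_shift_sd = 0.2,
                       uv_strength = 0.5, frac_uv_genes = 0.3,
                       uv_mode = c("depth-linked", "independent"),
                       uv_confound = 0, seed = 1L) {
  uv_mode <- match.arg(uv_mode)
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_housekeeping = n_housekeeping, n_de = n_de,
              log2_fc = log2_fc, frac_up = frac_up,
              nb_dispersion = nb_dispersion, bio_dispersion = bio_dispersion,
              de_dispersion = de_dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              uv_strength = uv_strength, frac_uv_genes = frac_uv_genes,
              uv_mode = uv_mode, uv_confound = uv_confound,
              seed = as.integer(seed))
  bad <- function(field, what)
    stop_tep(sprintf("invalid simulation configuration: `%s` %s", field, what),
             "tepsig_error_config")
  for (f in c("n_case", "n_control", "n_genes", "n_housekeeping", "n_de",
              "n_batches"))
    if (!is_count(cfg[[f]])) bad(f, "must be a non-negative integer")
  if (cfg$n_batches < 1) bad("n_batches", "must be at least 1")
  if (cfg$n_housekeeping + cfg$n_de > cfg$n_genes)
    bad("n_housekeeping", "+ n_de must not exceed n_genes")
  for (f in c("nb_dispersion", "bio_dispersion", "de_dispersion"))
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0)
      bad(f, "must be strictly positive")
  if (!is_scalar_num(cfg$libsize_log_sd) || cfg$libsize_log_sd <= 0)
    bad("libsize_log_sd", "must be strictly positive")
  if (!is_scalar_num(cfg$frac_uv_genes) ||
      cfg$frac_uv_genes < 0 || cfg$frac_uv_genes > 1)
    bad("frac_uv_genes", "must lie in [0, 1]")
  if (!is_scalar_num(cfg$frac_up) || cfg$frac_up < 0 || cfg$frac_up > 1)
    bad("frac_up", "must lie in [0, 1]")
  for (f in c("log2_fc", "libsize_log_mean", "batch_shift_sd",
              "uv_strength", "uv_confound"))
    if (!is_scalar_num(cfg[[f]])) bad(f, "must be a finite number")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic platelet RNA-seq study
#'
#' @param config A [sim_config()].
#' @return Object of class `"tep_sim"`: `counts` (genes x samples integer
#'   matrix), `design` (sample/class/cohort/batch plus clinical covariates
#'   age, sex, platelet_count), `truth` (per-gene role:
#'   housekeeping/de_up/de_down/null, baseline, lambda), `latent_factor`,
#'   `lib_factor` (the per-sample library-size factors L_j), `batch_offsets`,
#'   and the `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_case + config$n_control
    g <- config$n_genes
    samples <- sprintf("S%03d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(g))
    cls <- c(rep(1L, config$n_case), rep(0L, config$n_control))

    # gene roles at randomized positions
    role <- rep("null", g)
    hk <- sample.int(g, config$n_housekeeping)
    role[hk] <- "housekeeping"
    de <- if (config$n_de > 0) sample(setdiff(seq_len(g), hk), config$n_de)
          else integer(0)
    n_up <- round(config$frac_up * config$n_de)
    de_up <- de[seq_len(n_up)]
    de_down <- setdiff(de, de_up)
    role[de_up] <- "de_up"
    role[de_down] <- "de_down"

    # baselines: heavy-tailed for bulk genes, high for housekeeping,
    # moderately expressed for planted signature genes
    b <- stats::rlnorm(g, meanlog = log(20), sdlog = 1.5)
    b[hk] <- stats::rlnorm(length(hk), meanlog = log(500), sdlog = 0.5)
    b[de] <- stats::rlnorm(length(de), meanlog = log(50), sdlog = 0.8)

    s_dir <- numeric(g)
    s_dir[de_up] <- 1
    s_dir[de_down] <- -1
    fc <- ifelse(s_dir != 0, config$log2_fc, 0)

    # library-size factors; optional class confounding of depth
    logL <- config$libsize_log_mean +
      config$libsize_log_sd * stats::rnorm(n) +
      config$uv_confound * cls
    L <- exp(logL)

    # latent technical factor
    w <- if (config$uv_mode == "depth-linked")
      as.vector(scale(logL)) else stats::rnorm(n)

    lambda <- numeric(g)
    non_hk <- setdiff(seq_len(g), hk)
    n_uv <- round(config$frac_uv_genes * length(non_hk))
    uv_genes <- if (n_uv > 0) sample(non_hk, n_uv) else integer(0)
    lambda[uv_genes] <- stats::rnorm(n_uv, sd = config$uv_strength)

    # batches, stratified by class; per-batch per-gene offsets
    batch <- integer(n)
    for (cl in c(0L, 1L)) {
      idx <- which(cls == cl)
      batch[idx] <- rep_len(seq_len(config$n_batches),
                            length(idx))[sample.int(length(idx))]
    }
    batch_offsets <- matrix(
      stats::rnorm(g * config$n_batches, sd = config$batch_shift_sd),
      nrow = g, dimnames = list(genes, paste0("batch", seq_len(config$n_batches))))
    if (config$n_batches == 1) batch_offsets[] <- 0

    log_mu <- outer(log(b), log(L), "+") +
      log(2) * outer(fc * s_dir, cls) +
      batch_offsets[, batch, drop = FALSE] +
      outer(lambda, w)
    mu <- exp(log_mu)
    size_i <- rep(config$bio_dispersion, g)
    size_i[hk] <- config$nb_dispersion
    size_i[de] <- config$de_dispersion
    counts <- matrix(
      pmin(stats::rnbinom(length(mu), mu = mu, size = size_i),
           .Machine$integer.max),
      nrow = g, dimnames = list(genes, samples))
    storage.mode(counts) <- "integer"

    # cohort split, stratified by class; simple clinical covariates
    cohort <- character(n)
    for (cl in c(0L, 1L)) {
      idx <- which(cls == cl)
      half <- rep_len(c("training", "validation"),
                      length(idx))[sample.int(length(idx))]
      cohort[idx] <- half
    }
    design <- data.frame(
      sample = samples,
      class = factor(ifelse(cls == 1, "case", "control"),
                     levels = c("control", "case")),
      cohort = factor(cohort, levels = c("training", "validation")),
      batch = factor(paste0("batch", batch)),
      age = round(stats::rnorm(n, mean = 60 + 2 * cls, sd = 8)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.85, 0.15)),
      platelet_count = round(stats::rnorm(n, mean = 160 + 55 * cls, sd = 40)),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(gene = genes, role = role, baseline = b,
                        lambda = lambda, stringsAsFactors = FALSE)
    structure(list(counts = counts, design = design, truth = truth,
                   latent_factor = stats::setNames(w, samples),
                   lib_factor = stats::setNames(L, samples),
                   batch_offsets = batch_offsets, config = config),
              class = "tep_sim")
  })
}

#' Generate a null study (no class-associated genes)
#'
#' Identical to [simulate_study()] with `n_de` forced to 0; used for
#' type-I-error and null-AUC calibration.
#' @inheritParams simulate_study
#' @export
simulate_null_study <- function(config) {
  config$n_de <- 0L
  simulate_study(config)
}

#' Write a simulated study to disk
#'
#' Emits `counts.tsv`, `design.tsv` and `truth.tsv` (gene, role) in the same
#' formats the pipeline readers accept.
#' @param study A `"tep_sim"` object.
#' @param dir Output directory (created if absent).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "tep_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  write_design(study$design, file.path(dir, "design.tsv"))
  utils::write.table(study$truth[, c("gene", "role")],
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
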