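# Shared fixtures, all generated in code.

# a small, fast study for unit tests
quick_config <- function(seed = 1, ...) {
  args <- list(n_case = 30, n_control = 30, n_genes = 400,
               n_housekeeping = 40, n_de = 10, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# compact hyperparameter grid to keep SVM tests fast
small_grid <- function() svm_grid(gamma = 10^(-3:0), cost = 2^(1:4))

# run the label-free preprocessing front end of the pipeline
preprocess_study <- function(sim, k = 1) {
  sizes <- compute_library_sizes(sim$counts)
  filt <- filter_low_count_genes(sim$counts)
  le <- batch_adjust(log_transform(filt), sim$design)
  ctl <- suppressWarnings(select_control_genes(filt, sizes))
  ruv <- estimate_unwanted_factors(le, ctl, k)
  list(normalized = remove_unwanted_variation(le, ruv),
       controls = ctl, ruv = ruv, sizes = sizes, filtered = filt)
}

# a toy count matrix with dimnames
toy_counts <- function(values, n_genes, n_samples) {
  matrix(as.integer(values), nrow = n_genes, ncol = n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

genes_with_role <- function(sim, pattern) {
  sim$truth$gene[grepl(pattern, sim$truth$role)]
}
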