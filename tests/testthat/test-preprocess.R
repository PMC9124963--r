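test_that("low-count filter drops silent genes and honors the strict boundary", {
  # 20 samples: detected in exactly 1 sample -> frac below = 0.95, retained;
  # detected in 0 samples -> frac below = 1 > 0.95, removed
  m <- toy_counts(0, 3, 20)
  m[1, ] <- 10L            # detected everywhere
  m[2, 1] <- 5L            # detected in exactly one sample
  filt <- filter_low_count_genes(m)
  expect_setequal(rownames(filt), c("g1", "g2"))
  expect_identical(colnames(filt), colnames(m))

  m[2, 1] <- 4L            # now below threshold everywhere
  expect_setequal(rownames(filter_low_count_genes(m)), "g1")
  expect_error(filter_low_count_genes(toy_counts(0, 2, 20)),
               class = "tepsig_error_empty_result")
})

test_that("the filter is idempotent", {
  sim <- simulate_study(quick_config(seed = 4))
  once <- filter_low_count_genes(sim$counts)
  expect_identical(filter_low_count_genes(once), once)
})

test_that("library sizes are column sums with named failure modes", {
  m <- toy_counts(c(1, 3, 2, 4), 2, 2)  # rows (1,2), (3,4)
  expect_equal(unname(compute_library_sizes(m)), c(4, 6))
  expect_equal(compute_library_sizes(m),
               compute_library_sizes(m[c(2, 1), ]))
  expect_equal(unname(compute_library_sizes(m * 10L)), c(40, 60))
  m[, 2] <- 0L
  expect_error(compute_library_sizes(m), "s2",
               class = "tepsig_error_zero_library")
})

test_that("control-gene discovery uses a signed, strict correlation threshold", {
  sizes <- c(s1 = 100, s2 = 200, s3 = 300, s4 = 400)
  m <- toy_counts(0, 3, 4)
  m[1, ] <- as.integer(sizes / 10)       # exactly proportional, r = 1
  m[2, ] <- as.integer(rev(sizes / 10))  # anti-proportional, r = -1
  m[3, ] <- c(5L, 5L, 5L, 5L)            # constant: r undefined
  expect_warning(ctl <- select_control_genes(m, sizes), "constant")
  expect_identical(ctl$gene, "g1")
  expect_equal(ctl$r, 1, tolerance = 1e-12)
})

test_that("control-gene correlation is invariant to per-gene affine rescaling", {
  sim <- simulate_study(quick_config(seed = 5))
  sizes <- compute_library_sizes(sim$counts)
  filt <- filter_low_count_genes(sim$counts)
  ctl1 <- suppressWarnings(select_control_genes(filt, sizes))
  scaled <- filt
  scaled[1:50, ] <- scaled[1:50, ] * 3L + 7L
  ctl2 <- suppressWarnings(select_control_genes(scaled, sizes))
  expect_identical(ctl1$gene, ctl2$gene)
  expect_equal(ctl1$r, ctl2$r, tolerance = 1e-12)
})

test_that("batch adjustment is the identity for a single batch", {
  sim <- simulate_study(quick_config(seed = 6, n_batches = 1))
  le <- log_transform(filter_low_count_genes(sim$counts))
  expect_identical(batch_adjust(le, sim$design), le)
})

test_that("a pure constant batch shift is removed exactly", {
  set.seed(11)
  n <- 20
  design <- data.frame(sample = paste0("s", 1:n),
                       class = factor(rep(c("control", "case"), n / 2)),
                       batch = rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(50 * n), nrow = 50,
              dimnames = list(paste0("g", 1:50), design$sample))
  shifted <- X
  shifted[, design$batch == "B"] <- shifted[, design$batch == "B"] + 2.5
  adj <- batch_adjust(shifted, design)
  delta <- rowMeans(adj[, design$batch == "A"]) -
    rowMeans(adj[, design$batch == "B"])
  expect_lt(max(abs(delta)), 1e-8)
})

test_that("a planted class effect survives batch adjustment", {
  set.seed(12)
  n <- 40
  design <- data.frame(sample = paste0("s", 1:n),
                       class = factor(rep(c("control", "case"), n / 2),
                                      levels = c("control", "case")),
                       batch = rep(c("A", "A", "B", "B"), n / 4))  # balanced
  X <- matrix(rnorm(30 * n, sd = 0.3), nrow = 30,
              dimnames = list(paste0("g", 1:30), design$sample))
  X[1:10, design$class == "case"] <- X[1:10, design$class == "case"] + 2
  fc_clean <- vapply(1:10, function(i)
    compute_fold_change(X[i, ], design$class), numeric(1))
  X[, design$batch == "B"] <- X[, design$batch == "B"] - 1.5
  adj <- batch_adjust(X, design)
  fc <- vapply(1:10, function(i) compute_fold_change(adj[i, ], design$class),
               numeric(1))
  expect_true(all(abs(fc - fc_clean) / abs(fc_clean) < 0.05))
  expect_error(batch_adjust(X, transform(design, batch = c("C", design$batch[-1]))),
               class = "tepsig_error_batch")
})

test_that("permuted batch labels leave gene means essentially unchanged", {
  set.seed(13)
  sim <- simulate_study(quick_config(seed = 13, n_genes = 100,
                                     n_housekeeping = 10, n_de = 5))
  le <- log_transform(filter_low_count_genes(sim$counts))
  drift <- replicate(10, {
    d <- sim$design
    d$batch <- sample(d$batch)
    max(abs(rowMeans(batch_adjust(le, d)) - rowMeans(le)))
  })
  expect_lt(mean(drift), 0.05)
})

test_that("log transform matches its defining examples", {
  m <- toy_counts(c(0, 3, 1, 7), 2, 2)
  lt <- log_transform(m)
  expect_equal(lt["g1", "s1"], 0)
  expect_equal(lt["g2", "s1"], 2)
  expect_true(all(diff(log_transform(matrix(0:10, ncol = 1))) > 0))
  expect_error(log_transform(m, pseudocount = -1),
               class = "tepsig_error_config")
})
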