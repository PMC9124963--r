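test_that("Fisher's exact p equals full hypergeometric enumeration", {
  enum_fisher <- function(a, b, c, d) {
    # two-sided exact test on table (a b / c d): sum of probabilities of all
    # tables with the same margins that are no more probable
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
    p_obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(stats::fisher.test(matrix(c(8, 1, 2, 9), 2))$p.value,
               enum_fisher(8, 2, 1, 9), tolerance = 1e-9)
  expect_equal(round(enum_fisher(8, 2, 1, 9), 4), 0.0055)
  set.seed(71)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) > 50 || sum(tab) == 0) next
    expect_equal(stats::fisher.test(tab)$p.value,
                 enum_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("well-separated class blobs cluster along the class boundary", {
  set.seed(72)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  # all samples share a base expression profile; cases add an orthogonal
  # up/down pattern (a uniform shift would be invisible to the correlation
  # distance)
  base <- c(rep(2, 10), rep(-2, 10))
  patt <- c(rep(3, 5), rep(-3, 5), rep(0, 10))
  X <- matrix(rnorm(n * 20, sd = 0.3), n) +
    outer(rep(1, n), base) + outer(y, patt)
  res <- cluster_separation_test(X, y)
  expect_lt(res$fisher_p, 1e-6)
  expect_equal(length(unique(res$clusters)), 2)
  # invariance to gene order and per-gene affine rescaling
  X2 <- X[, sample(20)]
  X2[, 1] <- X2[, 1] * 50 + 3
  res2 <- cluster_separation_test(X2, y)
  expect_equal(res2$fisher_p, res$fisher_p, tolerance = 1e-9)
})

test_that("label permutation keeps cluster separation near the null", {
  set.seed(73)
  n <- 24
  X <- matrix(rnorm(n * 15), n)
  y <- rep(c(0, 1), each = n / 2)
  base <- cluster_separation_test(X, y)
  rej <- mean(replicate(60, {
    cluster_separation_test(X, sample(y))$fisher_p < 0.05
  }))
  expect_lte(rej, 0.2)
})

test_that("PCA matches covariance eigendecomposition and conventions", {
  set.seed(74)
  X <- matrix(rnorm(20 * 8), 20)
  emb <- pca_embed(X, n_components = 3)
  ev <- eigen(stats::cov(X))
  expect_equal(emb$explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  Xc <- scale(X, scale = FALSE)
  for (j in 1:3) {
    expect_equal(abs(emb$scores[, j]), abs(as.vector(Xc %*% ev$vectors[, j])),
                 tolerance = 1e-9)
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  }
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_lte(sum(emb$explained), 1 + 1e-12)
  # rank-1 data: first component explains everything
  r1 <- outer(rnorm(10), rnorm(5))
  expect_equal(pca_embed(r1, 1)$explained[1], 1, tolerance = 1e-9)
  expect_error(pca_embed(X[1, , drop = FALSE]),
               class = "tepsig_error_dimensions")
})

test_that("clinical correlations follow the textbook t-based formula", {
  set.seed(75)
  n <- 25
  expr <- matrix(rnorm(2 * n), 2, dimnames = list(c("gA", "gB"), NULL))
  clin <- data.frame(size = expr["gA", ] * 0.8 + rnorm(n, sd = 0.5),
                     stage = factor(sample(1:3, n, TRUE), ordered = TRUE))
  res <- clinical_correlations(expr, clin, ordinal = "stage")
  pa <- res[res$gene == "gA" & res$feature == "size", ]
  r <- cor(expr["gA", ], clin$size)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(pa$coefficient, r, tolerance = 1e-12)
  expect_equal(pa$p, 2 * stats::pt(-abs(tstat), n - 2), tolerance = 1e-9)
  expect_identical(res$method[res$feature == "stage"],
                   rep("spearman", 2))
  # self-correlation is perfect
  self <- clinical_correlations(expr["gA", , drop = FALSE],
                                data.frame(x = expr["gA", ]))
  expect_equal(self$coefficient, 1, tolerance = 1e-12)
  expect_true(self$significant)
})

test_that("Spearman correlations are invariant to monotone transforms", {
  set.seed(76)
  n <- 30
  expr <- matrix(rnorm(n), 1, dimnames = list("g", NULL))
  v <- rnorm(n) + expr[1, ]
  a <- clinical_correlations(expr, data.frame(f = v), ordinal = "f")
  b <- clinical_correlations(expr, data.frame(f = exp(v)), ordinal = "f")
  expect_equal(a$coefficient, b$coefficient, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})
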