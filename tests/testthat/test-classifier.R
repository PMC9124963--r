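test_that("the declared default grid matches the search ranges", {
  g <- svm_grid()
  expect_length(g$gamma, 12)
  expect_length(g$cost, 10)
  expect_equal(range(g$gamma), c(1e-10, 10))
  expect_equal(range(g$cost), c(2, 1024))
  expect_error(svm_grid(gamma = numeric(0)), class = "tepsig_error_config")
})

test_that("a widely separated class pair is classified perfectly", {
  set.seed(51)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sig = y * 10 + rnorm(n, sd = 0.1), noise = rnorm(n))
  cv <- loocv_evaluate(X, y, small_grid(), seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$samples$score[y == 1] > cv$samples$score[y == 0]))
  expect_true(cv$gamma %in% small_grid()$gamma)
  expect_true(cv$cost %in% small_grid()$cost)
  expect_true(all(cv$samples$gamma %in% small_grid()$gamma))
})

test_that("out-of-fold scores depend only on the training fold", {
  set.seed(52)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(a = y + rnorm(n, sd = 0.8), b = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  cv <- loocv_evaluate(X, y, gamma = 0.1, cost = 4)
  # each score is reproduced exactly by an independent refit on its fold
  for (i in c(1, 7, 20)) {
    std <- tepsig:::std_fit(X[-i, , drop = FALSE])
    m <- tepsig:::svm_train_raw(tepsig:::std_apply(X[-i, , drop = FALSE], std),
                                tepsig:::as_class_factor(y[-i]), 0.1, 4)
    sc <- tepsig:::svm_score(m, tepsig:::std_apply(X[i, , drop = FALSE], std))
    expect_equal(cv$samples$score[i], sc$score, tolerance = 1e-10)
  }
})

test_that("duplicating every sample does not hurt LOOCV accuracy", {
  set.seed(53)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(a = y * 2 + rnorm(n, sd = 0.7), b = rnorm(n))
  base <- loocv_evaluate(X, y, gamma = 0.1, cost = 4)
  dup <- loocv_evaluate(rbind(X, X), c(y, y), gamma = 0.1, cost = 4)
  expect_gte(dup$accuracy, base$accuracy)
})

test_that("the signature-size curve starts from the top-ranked gene", {
  set.seed(54)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(best = y * 5 + rnorm(n, sd = 0.3),
             weak = y + rnorm(n),
             noise = rnorm(n))
  ranking <- rank_mrmr(X, y)
  expect_identical(ranking$gene[1], "best")
  curve <- signature_size_curve(ranking, X, y, small_grid(), sizes = 1:3,
                                seed = 1)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  expect_true(all(curve$mcc >= -1 & curve$mcc <= 1))
  # size 1 uses exactly the top gene, which separates almost perfectly
  expect_gte(curve$accuracy[1], 0.9)
  expect_true(attr(curve, "recommended") %in% 1:3)
  expect_error(signature_size_curve(ranking, X, y, sizes = 1:9),
               class = "tepsig_error_dimensions")
})

test_that("frozen models ignore non-signature genes and name missing ones", {
  set.seed(55)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(g1 = y * 4 + rnorm(n, sd = 0.4), g2 = rnorm(n))
  model <- fit_final(X, y, gamma = 0.1, cost = 4)
  Xnew <- cbind(g1 = c(0, 4), g2 = c(1, -1), extra = c(9, 9))
  s1 <- predict_scores(model, Xnew)
  Xnew2 <- Xnew
  Xnew2[, "extra"] <- -99
  expect_equal(s1, predict_scores(model, Xnew2))
  expect_lt(s1[1], s1[2])
  # training margins have the correct sign on separable data
  tr_scores <- predict_scores(model, X)
  expect_true(all(sign(tr_scores) == ifelse(y == 1, 1, -1)))
  expect_error(predict_scores(model, Xnew[, "g2", drop = FALSE]),
               "g1", class = "tepsig_error_missing_genes")
})

test_that("scoring a validation sample is blind to its cohort companions", {
  set.seed(56)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(g1 = y * 3 + rnorm(n, sd = 0.5), g2 = rnorm(n))
  model <- fit_final(X, y, gamma = 0.1, cost = 4)
  V <- cbind(g1 = rnorm(6), g2 = rnorm(6))
  rownames(V) <- paste0("v", 1:6)
  full <- predict_scores(model, V)
  for (j in 1:6) {
    alone <- predict_scores(model, V[j, , drop = FALSE])
    expect_equal(unname(full[j]), unname(alone), tolerance = 1e-12)
  }
})

test_that("the Youden cutoff maximizes J with ties toward sensitivity", {
  res <- choose_cutoff(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 0.5)
  expect_equal(res$youden, 1)
  # equal-J plateau: the lower midpoint is preferred
  res2 <- choose_cutoff(c(1, 2, 3, 4), c(0, 1, 1, 1))
  grid_j <- sapply(c(1.5, 2.5, 3.5), function(ct) {
    pred <- c(1, 2, 3, 4) > ct
    sum(pred & c(0, 1, 1, 1) == 1) / 3 + sum(!pred & c(0, 1, 1, 1) == 0) - 1
  })
  expect_equal(res2$youden, max(grid_j))
  expect_equal(res2$cutoff, c(1.5, 2.5, 3.5)[which(grid_j == max(grid_j))[1]])
  expect_error(choose_cutoff(rep(1, 6), rep(c(0, 1), 3)),
               class = "tepsig_error_degenerate")
})
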