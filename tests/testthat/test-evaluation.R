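test_that("precision-recall reproduces the hand-enumerated example", {
  pred <- data.frame(regulator = c("a", "b", "c", "d"),
                     target = rep("t", 4),
                     score = c(0.9, 0.8, 0.7, 0.6))
  gold <- data.frame(regulator = c("a", "c"), target = c("t", "t"))
  pr <- precision_recall(pred, gold)
  expect_equal(pr$curve$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_equal(pr$curve$recall, c(1 / 2, 1 / 2, 1, 1))
  expect_equal(pr$aupr, 0.5 * 1 + 0.5 * 2 / 3, tolerance = 1e-12)
})

test_that("a perfect predictor attains AUPR 1", {
  gold <- data.frame(regulator = c("a", "b"), target = c("x", "y"))
  pred <- cbind(gold, score = c(2, 1))
  expect_equal(precision_recall(pred, gold)$aupr, 1)
})

test_that("random scores give AUPR near the gold prevalence", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:15)
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  auprs <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    gold <- pairs[sample(nrow(pairs), 30), ]
    pred <- pairs
    pred$score <- runif(nrow(pred))
    precision_recall(pred, gold)$aupr
  }, numeric(1))
  prev <- 30 / (15 * 14)
  expect_lt(abs(mean(auprs) - prev), 4 * sd(auprs) / sqrt(50))
})

test_that("binary-network PR equals the endpoint of the untied sweep", {
  set.seed(72)
  genes <- sprintf("g%02d", 1:10)
  gold <- data.frame(regulator = genes[1:5], target = genes[6:10])
  pred <- data.frame(regulator = rep(genes[1:6], 2),
                     target = rep(genes[c(6:10, 1)], 2)[c(1:6, 8:13)])
  pred <- unique(pred[pred$regulator != pred$target, ])
  pred$score <- 1                               # binary network
  pr_bin <- precision_recall(pred, gold)
  pred2 <- pred
  pred2$score <- seq(1, 0.5, length.out = nrow(pred2))  # arbitrary untied
  pr_cont <- precision_recall(pred2, gold)
  expect_equal(nrow(pr_bin$curve), 1L)
  last <- nrow(pr_cont$curve)
  expect_equal(pr_bin$curve$precision, pr_cont$curve$precision[last])
  expect_equal(pr_bin$curve$recall, pr_cont$curve$recall[last])
})

test_that("both-present restriction and empty gold are handled", {
  gold <- data.frame(regulator = c("a", "zz"), target = c("x", "yy"))
  pred <- data.frame(regulator = c("a", "b"), target = c("x", "x"),
                     score = c(1, 0.5))
  pr <- precision_recall(pred, gold, genes = c("a", "b", "x"))
  expect_equal(pr$n_gold, 1L)
  expect_error(precision_recall(pred, gold, genes = "b"), "empty gold")
})

test_that("FDC saturation and degenerate cases give slope 1 and 0", {
  ord <- sprintf("g%02d", 1:20)
  idx <- which(upper.tri(diag(20)), arr.ind = TRUE)
  edges <- data.frame(regulator = ord[idx[, 1]], target = ord[idx[, 2]],
                      p = 1e-6)
  # every prediction significant, no discard: slope 1, R^2 1
  rep1 <- fdc_linearity(edges, ord, alpha = 0.05, discard_top = 0)
  expect_equal(rep1$slope, 1, tolerance = 1e-12)
  expect_equal(rep1$r_squared, 1, tolerance = 1e-12)
  # nothing significant: slope 0
  edges$p <- 0.9
  rep0 <- fdc_linearity(edges, ord, alpha = 0.05, discard_top = 0)
  expect_equal(rep0$slope, 0)
})

test_that("null p-values give an FDC slope near alpha after discard", {
  slopes <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    ord <- sprintf("g%03d", 1:60)
    idx <- which(upper.tri(diag(60)), arr.ind = TRUE)
    edges <- data.frame(regulator = ord[idx[, 1]], target = ord[idx[, 2]],
                        p = runif(nrow(idx)))
    fdc_linearity(edges, ord, alpha = 0.1)$slope
  }, numeric(1))
  # discarding the smallest 5% of uniform p-values leaves alpha - 0.05
  expect_lt(abs(mean(slopes) - 0.05), 3 * sd(slopes) / sqrt(20))
})

test_that("cross-validation: baseline, oracle gain, and determinism", {
  sim <- simulate_instance(sim_config(n_genes = 40, n_samples = 150,
                                      mean_parents = 2, seed = 81))
  empty <- data.frame(regulator = character(0), target = character(0))
  cv0 <- cross_validate(sim$expr, sim$geno, sim$candidates, k = 5,
                        seed = 4, structure_override = empty)
  # empty-network predictor scores at the marginal variance of
  # rank-normalized data (the no-skill reference near 1)
  expect_lt(abs(cv0$summary$rmse_test - 1), 0.05)
  oracle <- sim$truth$edges[, c("regulator", "target")]
  cv1 <- cross_validate(sim$expr, sim$geno, sim$candidates, k = 5,
                        seed = 4, structure_override = oracle)
  expect_lt(cv1$summary$rmse_test, cv0$summary$rmse_test)
  # bit-for-bit reproducibility given (data, seed, threshold)
  cv2 <- cross_validate(sim$expr, sim$geno, sim$candidates, k = 5,
                        seed = 4, structure_override = oracle)
  expect_identical(cv1$summary, cv2$summary)
})

test_that("permuting parent values in the test fold destroys the gain", {
  sim <- simulate_instance(sim_config(n_genes = 30, n_samples = 150,
                                      mean_parents = 2, seed = 82))
  oracle <- sim$truth$edges[, c("regulator", "target")]
  expr <- rank_normal_transform(sim$expr)
  m <- ncol(expr)
  set.seed(5)
  test_idx <- sample(m, 30)
  train_idx <- setdiff(seq_len(m), test_idx)
  bn <- fit_linear_gaussian(expr[, train_idx], oracle)
  te <- expr[, test_idx]
  bn2 <- structure(bn, class = c("genord_bn", "bn_fit"))
  rmse <- function(d) sqrt(mean((te - predict(bn2, d))^2))
  gain <- rmse(te)
  te_perm <- te[, sample(ncol(te))]
  colnames(te_perm) <- colnames(te)
  expect_lt(gain, 0.95)
  expect_gt(rmse(te_perm), 0.95)
})
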