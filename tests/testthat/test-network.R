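test_that("truncation thresholds behave at the extremes and nest", {
  d <- greedy_max_weight_dag(full_random_scores(10, seed = 5))
  expect_equal(nrow(truncate_network(d, threshold = 0)), nrow(d$edges))
  expect_equal(nrow(truncate_network(d, threshold = 1 + 1e-9)), 0L)
  expect_error(truncate_network(d), "exactly one")
  expect_error(truncate_network(d, threshold = 0.5, top_k = 3),
               "exactly one")
  # nested sparsification
  e1 <- truncate_network(d, threshold = 0.3)
  e2 <- truncate_network(d, threshold = 0.7)
  k1 <- paste(e1$regulator, e1$target)
  k2 <- paste(e2$regulator, e2$target)
  expect_true(all(k2 %in% k1))
})

test_that("top-k on the worked DAG keeps all three edges", {
  d <- greedy_max_weight_dag(worked_scores())
  st <- truncate_network(d, top_k = 3)
  expect_equal(nrow(st), 3L)
  expect_setequal(paste(st$regulator, st$target),
                  c("1 2", "2 3", "1 3"))
})

std1 <- function(v) { v <- v - mean(v); v / sqrt(mean(v^2)) }

test_that("single-predictor entry lambda matches |x'y|/m exactly", {
  set.seed(21)
  for (i in 1:20) {
    m <- 30 + i
    x <- std1(rnorm(m)); y <- std1(rnorm(m))
    ent <- lasso_entry_lambdas(y, matrix(x, m, 1))
    expect_equal(unname(ent), abs(sum(x * y)) / m, tolerance = 1e-10)
  }
})

test_that("orthogonal predictors never enter; duplicates enter together", {
  m <- 40
  x <- std1(rep(c(1, -1), m / 2))
  z <- std1(rep(c(1, 1, -1, -1), m / 4))
  y <- std1(rep(c(1, -1, -1, 1), m / 4))   # orthogonal to x and z
  ent <- lasso_entry_lambdas(y, cbind(a = x, b = z))
  expect_equal(unname(ent), c(0, 0))
  # duplicated columns share the entry lambda
  set.seed(3)
  x1 <- std1(rnorm(m)); y2 <- std1(x1 + rnorm(m))
  ent2 <- lasso_entry_lambdas(y2, cbind(a = x1, b = x1))
  expect_equal(ent2[["a"]], ent2[["b"]])
  expect_equal(ent2[["a"]], abs(sum(x1 * y2)) / m, tolerance = 1e-10)
})

test_that("entry lambdas agree with glmnet on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  m <- 60; p <- 8
  X <- apply(matrix(rnorm(m * p), m, p), 2, std1)
  y <- std1(drop(X %*% c(1, -0.8, rep(0, p - 2))) + rnorm(m))
  ent <- lasso_entry_lambdas(y, X)
  lmax <- max(abs(crossprod(X, y))) / m
  fit <- glmnet::glmnet(X, y, standardize = FALSE,
                        lambda = exp(seq(log(lmax), log(1e-4 * lmax),
                                         length.out = 400)),
                        thresh = 1e-12)
  gent <- apply(as.matrix(fit$beta), 1, function(b) {
    i <- which(b != 0)[1]
    if (is.na(i)) 0 else fit$lambda[i]
  })
  expect_equal(unname(ent), unname(gent), tolerance = 0.02)
})

test_that("lasso p-values detect a planted parent among null predecessors", {
  hits <- logical(40)
  for (s in seq_along(hits)) {
    set.seed(700 + s)
    m <- 200
    X <- apply(matrix(rnorm(m * 20), m, 20), 2, std1)
    colnames(X) <- sprintf("P%02d", 1:20)
    y <- std1(X[, 1] + rnorm(m))            # parent explains half the variance
    pv <- lasso_pvalues(y, X, B = 1000, seed = s)$p
    hits[s] <- pv[["P01"]] < 0.01
  }
  expect_gte(mean(hits), 0.95)
})

test_that("lasso p-values are uniform for a fully null target", {
  pooled <- c()
  for (s in 1:30) {
    set.seed(800 + s)
    m <- 100
    X <- apply(matrix(rnorm(m * 10), m, 10), 2, std1)
    colnames(X) <- sprintf("P%02d", 1:10)
    y <- std1(rnorm(m))
    pooled <- c(pooled, lasso_pvalues(y, X, B = 200, seed = s)$p_randomized)
  }
  expect_gt(ks.test(pooled, "punif")$p.value, 0.01)
})

test_that("never-active predictors get p = 1 and p is monotone in lambda", {
  set.seed(91)
  m <- 50
  X <- apply(matrix(rnorm(m * 60), m, 60), 2, std1)  # p > m: saturation
  colnames(X) <- sprintf("P%02d", 1:60)
  y <- std1(rnorm(m))
  lp <- lasso_pvalues(y, X, B = 200, seed = 1)
  expect_true(all(lp$p[lp$entry == 0] == 1))
  o <- order(lp$entry, decreasing = TRUE)
  expect_true(all(diff(lp$p[o]) >= -1e-12))
  expect_error(lasso_pvalues(y, X, B = 50), "100 permutations")
})

test_that("maximum-likelihood regression uses ML conventions and sign labels", {
  m <- 20
  x <- rnorm(m)
  expr <- rbind(X = x, Y = 2 * x, Z = -x + rnorm(m, sd = 0.3))
  colnames(expr) <- paste0("S", 1:m)
  st <- data.frame(regulator = c("X", "X"), target = c("Y", "Z"))
  bn <- fit_linear_gaussian(expr, st)
  expect_equal(bn$edges$coefficient[bn$edges$target == "Y"], 2,
               tolerance = 1e-10)
  expect_true(bn$deterministic[["Y"]])
  expect_equal(bn$edges$sign[bn$edges$target == "Y"], "activating")
  expect_equal(bn$edges$sign[bn$edges$target == "Z"], "repressing")
  # zero-parent gene gets marginal moments with the ML divisor
  expect_equal(bn$sigma2[["X"]], mean((x - mean(x))^2))
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(41)
  for (i in 1:100) {
    m <- 25; k <- sample(1:3, 1)
    expr <- matrix(rnorm((k + 1) * m), k + 1, m,
                   dimnames = list(c("T", paste0("R", 1:k)), paste0("S", 1:m)))
    st <- data.frame(regulator = paste0("R", 1:k), target = "T")
    bn <- fit_linear_gaussian(expr, st)
    Xd <- cbind(1, t(expr[paste0("R", 1:k), , drop = FALSE]))
    beta <- solve(crossprod(Xd), crossprod(Xd, expr["T", ]))
    expect_equal(bn$edges$coefficient, unname(beta[-1]), tolerance = 1e-8)
    expect_equal(bn$intercept[["T"]], beta[1], tolerance = 1e-8)
  }
})

test_that("too many regulators raise the divergence error", {
  expr <- rand_expr(6, 4, 1)
  st <- data.frame(regulator = rep(rownames(expr)[2:6], 1),
                   target = rownames(expr)[1])
  expect_error(fit_linear_gaussian(expr, st), "diverges")
})

test_that("adding a parent never increases the residual variance", {
  set.seed(55)
  for (i in 1:20) {
    expr <- rand_expr(4, 30, seed = 900 + i)
    st1 <- data.frame(regulator = "G02", target = "G01")
    st2 <- data.frame(regulator = c("G02", "G03"), target = "G01")
    s1 <- fit_linear_gaussian(expr, st1)$sigma2[["G01"]]
    s2 <- fit_linear_gaussian(expr, st2)$sigma2[["G01"]]
    expect_lte(s2, s1 + 1e-12)
  }
})

test_that("lasso selection over two orderings shares true positives", {
  # overlap among top true positives across orderings exceeds the overlap
  # expected for independent random selection of admissible pairs
  sim <- simulate_instance(sim_config(n_genes = 40, n_samples = 200,
                                      mean_parents = 1.5, seed = 50))
  E <- rank_normal_transform(sim$expr)
  eq <- map_best_cis_eqtl(E, sim$geno, sim$candidates)
  sc <- causal_anchor_scores(E, sim$geno, eq, seed = 50)
  dag_f <- greedy_max_weight_dag(sc)
  dag_r <- greedy_max_weight_dag(random_score_matrix(rownames(E), eq, 51))
  net_f <- lasso_select_network(E, dag_f$node_order, alpha = NULL, B = 200,
                                seed = 52)
  net_r <- lasso_select_network(E, dag_r$node_order, alpha = NULL, B = 200,
                                seed = 53)
  truth <- paste(sim$truth$edges$regulator, sim$truth$edges$target)
  top <- function(net, k = 60) {
    net <- net[order(net$p), ]
    head(paste(net$regulator, net$target), k)
  }
  tp_f <- intersect(top(net_f), truth)
  tp_r <- intersect(top(net_r), truth)
  obs_overlap <- length(intersect(tp_f, tp_r))
  # expected overlap if the two selections were independent draws of the
  # same sizes from the admissible pair universe
  n_pairs <- 40 * 39
  exp_overlap <- length(tp_f) * length(tp_r) / n_pairs
  expect_gt(obs_overlap, exp_overlap)
})
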