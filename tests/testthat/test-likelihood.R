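test_that("empty-graph likelihood matches the Gaussian MLE closed form", {
  expr <- rand_expr(4, 30, seed = 61)
  bn <- fit_linear_gaussian(expr, data.frame(regulator = character(0),
                                             target = character(0)))
  m <- ncol(expr)
  expected <- sum(vapply(rownames(expr), function(g) {
    s2 <- mean((expr[g, ] - mean(expr[g, ]))^2)
    -(m / 2) * (log(2 * pi * s2) + 1)
  }, numeric(1)))
  expect_equal(log_likelihood(expr, bn), expected, tolerance = 1e-10)
})

test_that("likelihood matches a literal per-observation density sum", {
  set.seed(62)
  for (i in 1:20) {
    expr <- rand_expr(4, 25, seed = 1000 + i)
    st <- data.frame(regulator = c("G02", "G03", "G03"),
                     target = c("G01", "G01", "G04"))
    bn <- fit_linear_gaussian(expr, st)
    # oracle: loop over every observation
    oracle <- 0
    for (g in rownames(expr)) {
      pa <- st$regulator[st$target == g]
      for (k in seq_len(ncol(expr))) {
        mu <- bn$intercept[[g]]
        for (p in pa)
          mu <- mu + bn$edges$coefficient[bn$edges$target == g &
                                            bn$edges$regulator == p] *
            expr[p, k]
        oracle <- oracle + dnorm(expr[g, k], mu, sqrt(bn$sigma2[[g]]),
                                 log = TRUE)
      }
    }
    expect_equal(log_likelihood(expr, bn), oracle, tolerance = 1e-8)
  }
})

test_that("duplicating all samples doubles the log-likelihood", {
  expr <- rand_expr(3, 15, seed = 63)
  expr2 <- cbind(expr, expr)
  colnames(expr2) <- paste0("S", seq_len(30))
  st <- data.frame(regulator = "G02", target = "G01")
  bn <- fit_linear_gaussian(expr, st)
  bn2 <- fit_linear_gaussian(expr2, st)
  expect_equal(bn2$sigma2, bn$sigma2, tolerance = 1e-12)
  expect_equal(log_likelihood(expr2, bn2), 2 * log_likelihood(expr, bn),
               tolerance = 1e-8)
})

test_that("deterministic fits raise the divergence error unless floored", {
  m <- 10
  expr <- rbind(A = rnorm(m), B = 0)
  expr["B", ] <- 3 * expr["A", ]
  colnames(expr) <- paste0("S", 1:m)
  bn <- fit_linear_gaussian(expr, data.frame(regulator = "A", target = "B"))
  expect_error(log_likelihood(expr, bn), "diverges")
  expect_true(is.finite(log_likelihood(expr, bn, variance_floor = 1e-12)))
})

test_that("score decomposition is additive and guards excluded edges", {
  sm <- worked_scores()
  ids <- sm$gene_ids
  set.seed(64)
  expr <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(ids, paste0("S", 1:40)))
  d <- greedy_max_weight_dag(sm)
  bn <- fit_linear_gaussian(expr, data.frame(regulator = d$edges$regulator,
                                             target = d$edges$target))
  dec <- posterior_score(expr, sm, bn)
  expect_equal(dec$total, dec$data_term + dec$genetic_term, tolerance = 0)
  # genetic term equals the greedy's accumulated sum of log probabilities
  expect_equal(dec$genetic_term, sum(d$edges$weight), tolerance = 1e-12)
  # empty graph: zero genetic term
  bn0 <- fit_linear_gaussian(expr, data.frame(regulator = character(0),
                                              target = character(0)))
  expect_equal(posterior_score(expr, sm, bn0)$genetic_term, 0)
  # an excluded edge cannot be scored
  sm2 <- scores_from_edges(ids, list(list("1", "2", 0.9)))
  bad <- fit_linear_gaussian(expr, data.frame(regulator = "2", target = "1"))
  expect_error(posterior_score(expr, sm2, bad), "excluded")
})

test_that("a free certain edge with real signal increases the total", {
  set.seed(65)
  m <- 60
  a <- rnorm(m); b <- 0.8 * a + rnorm(m, sd = 0.6)
  expr <- rbind(A = a, B = b)
  colnames(expr) <- paste0("S", 1:m)
  p <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  p["A", "B"] <- 1        # certain edge: zero genetic cost (log 1 = 0)
  sm <- score_matrix(p)
  bn0 <- fit_linear_gaussian(expr, data.frame(regulator = character(0),
                                              target = character(0)))
  bn1 <- fit_linear_gaussian(expr, data.frame(regulator = "A", target = "B"))
  expect_gt(posterior_score(expr, sm, bn1)$total,
            posterior_score(expr, sm, bn0)$total)
})

test_that("likelihood is invariant under the node ordering", {
  # two full tournament DAGs from different orderings, refitted: the
  # ordering only reparametrizes the same joint Gaussian
  set.seed(66)
  sim <- simulate_instance(sim_config(n_genes = 10, n_samples = 200,
                                      seed = 66))
  E <- rank_normal_transform(sim$expr)
  lls <- vapply(1:3, function(r) {
    set.seed(66 + r)
    ord <- sample(rownames(E))
    idx <- which(upper.tri(diag(10)), arr.ind = TRUE)
    st <- data.frame(regulator = ord[idx[, 1]], target = ord[idx[, 2]])
    log_likelihood(E, fit_linear_gaussian(E, st))
  }, numeric(1))
  expect_lt(max(abs(diff(lls))) / abs(mean(lls)), 1e-6)
})
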