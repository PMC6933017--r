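#' Truncate a weighted DAG into a sparse network structure
#'
#' Applies a significance threshold on the continuous network (retain edges
#' with probability >= threshold) or keeps the top-k edges by score (ties
#' broken by regulator then target id). The result inherits acyclicity from
#' the input DAG.
#'
#' @param dag A \code{weighted_dag}.
#' @param threshold Probability threshold in [0, 1] (exclusive with
#'   \code{top_k}).
#' @param top_k Number of edges to keep (exclusive with \code{threshold}).
#' @return Data frame of class \code{bn_structure} with columns
#'   \code{regulator}, \code{target}, \code{score}.
#' @export
truncate_network <- function(dag, threshold = NULL, top_k = NULL) {
  if (is.null(threshold) == is.null(top_k))
    stop("exactly one of 'threshold' and 'top_k' must be given")
  e <- dag$edges[order(-dag$edges$prob, dag$edges$regulator,
                       dag$edges$target), , drop = FALSE]
  keep <- if (!is.null(threshold)) {
    stopifnot(threshold >= 0, threshold <= 1 + 1e-12 || threshold > 1)
    e$prob >= threshold
  } else {
    stopifnot(top_k >= 0)
    seq_len(nrow(e)) <= top_k
  }
  out <- data.frame(regulator = e$regulator[keep], target = e$target[keep],
                    score = e$prob[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bn_structure", "data.frame")
  out
}

# center and scale columns to zero mean and unit population variance
standardize_cols <- function(M) {
  M <- sweep(M, 2L, colMeans(M))
  s <- sqrt(colMeans(M^2))
  if (any(s == 0)) stop("cannot standardize a constant column")
  sweep(M, 2L, s, "/")
}

#' Lasso path with first-entry regularization strengths
#'
#' Homotopy (LARS with the lasso modification) for the objective
#' \deqn{\frac{1}{2m}\|y - X\beta\|^2 + \lambda \|\beta\|_1,}
#' run from \eqn{\lambda_{max} = \max_j |x_j^T y| / m} down to zero.
#' For every predictor the critical regularization strength at which it
#' first becomes active is recorded (0 for predictors that never enter).
#' With a single standardized predictor the entry value is exactly
#' \eqn{|x^T y| / m}. Knots of the piecewise-linear residual path are
#' returned for downstream null calibration.
#'
#' @param X Numeric matrix (samples x predictors), columns standardized.
#' @param y Numeric response (standardized).
#' @return List with \code{entry} (per-predictor entry lambda),
#'   \code{knots_lambda} (decreasing), \code{knots_resid}
#'   (samples x knots residual matrix; the residual is linear in lambda
#'   between consecutive knots and equals y above the first knot).
#' @export
lasso_path <- function(X, y) {
  m <- nrow(X); p <- ncol(X)
  if (p == 0L)
    return(list(entry = numeric(0), knots_lambda = numeric(0),
                knots_resid = matrix(numeric(0), m, 0)))
  G <- crossprod(X) / m
  c0 <- drop(crossprod(X, y)) / m
  entry <- numeric(p)
  dead <- logical(p)                    # collinear with the active set
  A <- integer(0); sA <- numeric(0); beta <- numeric(0)
  cc <- c0
  lam <- max(abs(cc))
  tol <- 1e-12 * max(lam, 1)
  kl <- lam
  kr <- list(y)
  if (lam <= tol)
    return(list(entry = entry, knots_lambda = 0,
                knots_resid = matrix(y, m, 1)))
  # bring in the first predictor(s)
  first <- which(abs(cc) >= lam - tol & !dead)
  for (j in sort(first)) {
    entry[j] <- lam
    if (add_ok(G, A, j)) { A <- c(A, j); sA <- c(sA, sign(cc[j])) }
    else dead[j] <- TRUE
  }
  beta <- numeric(length(A))
  saturated <- FALSE
  repeat {
    dA <- tryCatch(solve(G[A, A, drop = FALSE], sA), error = function(e) NULL)
    if (is.null(dA)) { saturated <- TRUE; break }
    a <- drop(G[, A, drop = FALSE] %*% dA)
    inact <- which(!dead & !(seq_len(p) %in% A))
    t_ev <- rep(Inf, p); sgn_ev <- numeric(p)
    for (j in inact) {
      tp <- (lam - cc[j]) / (1 - a[j])
      tm <- (lam + cc[j]) / (1 + a[j])
      tj <- Inf
      if (is.finite(tp) && tp > tol) { tj <- tp; sgn_ev[j] <- 1 }
      if (is.finite(tm) && tm > tol && tm < tj) { tj <- tm; sgn_ev[j] <- -1 }
      t_ev[j] <- tj
    }
    t_drop <- rep(Inf, length(A))
    hit <- -beta / dA
    t_drop[hit > tol] <- hit[hit > tol]
    t_entry <- if (length(inact)) min(t_ev[inact]) else Inf
    t_del <- if (length(A)) min(t_drop) else Inf
    t_star <- min(t_entry, t_del, lam)
    # advance to the event (or to lambda = 0)
    beta <- beta + t_star * dA
    cc <- cc - t_star * a
    lam <- lam - t_star
    r <- y - drop(X[, A, drop = FALSE] %*% beta)
    kl <- c(kl, lam); kr <- c(kr, list(r))
    if (lam <= tol) break
    if (t_del <= t_entry + tol && t_del <= t_star + tol) {
      gone <- which(t_drop <= t_star + tol)
      A <- A[-gone]; sA <- sA[-gone]; beta <- beta[-gone]
      if (length(A) == 0L) {
        # restart from the current correlations
        lam2 <- max(abs(cc[!dead]))
        if (lam2 <= tol) break
        lam <- min(lam, lam2)
        nxt <- which(abs(cc) >= lam - tol & !dead)
        for (j in nxt) {
          if (entry[j] == 0) entry[j] <- lam
          if (add_ok(G, A, j)) { A <- c(A, j); sA <- c(sA, sign(cc[j])) }
          else dead[j] <- TRUE
        }
        beta <- numeric(length(A))
      }
      next
    }
    joins <- which(!dead & !(seq_len(p) %in% A) & t_ev <= t_star + tol)
    for (j in joins[order(joins)]) {
      if (entry[j] == 0) entry[j] <- lam
      if (add_ok(G, A, j)) {
        A <- c(A, j); sA <- c(sA, sgn_ev[j]); beta <- c(beta, 0)
      } else dead[j] <- TRUE
    }
    if (length(A) >= m) { saturated <- TRUE; break }
  }
  if (kl[length(kl)] > 0) {
    # path stopped early (active set saturated or singular): continue the
    # residual linearly to its unpenalized limit on the final active set
    r0 <- if (saturated && length(A))
      stats::lm.fit(X[, A, drop = FALSE], y)$residuals
    else kr[[length(kr)]]
    kl <- c(kl, 0); kr <- c(kr, list(r0))
  }
  list(entry = entry, knots_lambda = kl,
       knots_resid = matrix(unlist(kr), m, length(kr)))
}

# can column j be added to active set A keeping G[A,A] well conditioned?
add_ok <- function(G, A, j) {
  AA <- c(A, j)
  k <- tryCatch(kappa(G[AA, AA, drop = FALSE], exact = TRUE),
                error = function(e) Inf)
  is.finite(k) && k < 1e10
}

#' Entry regularization strengths of each predecessor
#'
#' Convenience wrapper around \code{\link{lasso_path}} returning only the
#' per-predictor critical lambda at which it first becomes active.
#'
#' @param y Standardized target vector.
#' @param X Standardized predictor matrix (samples x predecessors).
#' @return Named numeric vector of entry lambdas (0 = never active).
#' @export
lasso_entry_lambdas <- function(y, X) {
  out <- lasso_path(X, y)$entry
  names(out) <- colnames(X)
  out
}

#' P-values of the critical regularization strength
#'
#' For each predecessor i of a target, tests whether its lasso-path entry
#' lambda is larger than expected for an uninformative predictor: the null
#' replaces predictor i by an independent standardized variable while the
#' other predictors are kept, and
#' \deqn{p_i = P(\lambda^{null}_{entry} \ge \lambda_i).}
#' The permutation mode estimates this from B permuted predictor columns.
#' Because the lasso path on the full predecessor set coincides with the
#' path on the set without predictor i for all lambda at or above predictor
#' i's entry, the null entry event is computed exactly from a single path
#' per target: an added variable z enters at or above a threshold t iff
#' \eqn{|z^T r(\lambda)|/m \ge \lambda} for some \eqn{\lambda \ge t}
#' along the piecewise-linear residual path r. Permutation vectors are
#' drawn once per target and shared across its predecessors. p-values are
#' monotone decreasing in the entry lambda; predictors that never enter
#' receive p = 1.
#'
#' @param y Standardized target vector.
#' @param X Standardized predictor matrix (samples x predecessors).
#' @param B Number of permutations (at least 100).
#' @param seed Integer seed.
#' @param mode \code{"permutation"} (default) or \code{"analytic"} (normal
#'   tail for the single-predictor entry statistic,
#'   \eqn{p = 2\Phi(-\lambda_i\sqrt m)}; a cross-check, exact only without
#'   competing predictors).
#' @return List with \code{p} (per-predecessor p-values, conservative),
#'   \code{entry} (entry lambdas), and \code{p_randomized} (the randomized
#'   version spreading Monte-Carlo and tie mass uniformly; exactly uniform
#'   under the null, intended for calibration diagnostics, not selection).
#' @export
lasso_pvalues <- function(y, X, B = 1000, seed = 1L,
                          mode = c("permutation", "analytic")) {
  mode <- match.arg(mode)
  m <- nrow(X); p <- ncol(X)
  path <- lasso_path(X, y)
  ent <- path$entry
  if (p == 0L) return(list(p = numeric(0), entry = ent))
  if (mode == "analytic") {
    pv <- ifelse(ent > 0, 2 * stats::pnorm(-ent * sqrt(m)), 1)
    names(pv) <- colnames(X)
    return(list(p = pv, entry = ent))
  }
  if (B < 100) stop("calibration error: need at least 100 permutations")
  kl <- path$knots_lambda
  R <- path$knots_resid
  K <- length(kl)
  pv <- rep(1, p)
  pv_rand <- rep(NA_real_, p)
  with_seed(seed, {
    Z <- vapply(seq_len(B), function(b)
      X[sample.int(m), (b - 1L) %% p + 1L], numeric(m))
    S <- crossprod(R, Z) / m                 # knots x B, signed
    CM <- apply(abs(S) - kl, 2L, cummax)     # running sup over knots
    if (is.null(dim(CM))) CM <- matrix(CM, nrow = K)
    U <- stats::runif(p)
    for (i in which(ent > 0)) {
      k <- findInterval(-ent[i], -kl)        # last knot with lambda >= ent
      ev <- CM[k, ] >= 0
      if (k < K && kl[k] > ent[i]) {
        w <- (kl[k] - ent[i]) / (kl[k] - kl[k + 1L])
        s_at <- S[k, ] * (1 - w) + S[k + 1L, ] * w
        ev <- ev | (abs(s_at) >= ent[i])
      }
      n_ge <- sum(ev)
      pv[i] <- (1 + n_ge) / (B + 1)
      pv_rand[i] <- (n_ge + U[i]) / (B + 1)
    }
    # never-entered predictors: p = 1; the null entry distribution has an
    # atom at zero (a null predictor may also never enter a saturated
    # path), so the randomized p-value spreads the tie mass uniformly
    never <- which(ent == 0)
    if (length(never)) {
      entered_null <- CM[K - 1L, ] >= 0 |
        sqrt(colSums(R[, K, drop = FALSE]^2))[1L] > 1e-8 * sqrt(m)
      n_tie <- B - sum(entered_null)
      pv_rand[never] <- (sum(entered_null) +
                           U[never] * (n_tie + 1)) / (B + 1)
    }
  })
  names(pv) <- names(pv_rand) <- colnames(X)
  list(p = pv, entry = ent, p_randomized = pv_rand)
}

#' Lasso-path network selection over a node ordering
#'
#' For every gene, tests each of its predecessors in the node order as a
#' candidate regulator with \code{\link{lasso_pvalues}} and keeps the
#' significant ones, producing a continuous network scored by
#' \eqn{-\log_{10} p}.
#'
#' @param expr Rank-normalized expression matrix.
#' @param node_order Character vector of gene ids (a topological order).
#' @param alpha Significance level on the p-values (default 0.05); pass
#'   \code{NULL} to keep the full continuous network.
#' @param B,seed,mode Passed to \code{\link{lasso_pvalues}}; per-target
#'   seeds are derived deterministically from \code{seed} so results do not
#'   depend on target evaluation order.
#' @return \code{bn_structure} data frame with columns regulator, target,
#'   score (-log10 p) and \code{p}.
#' @export
lasso_select_network <- function(expr, node_order, alpha = 0.05, B = 1000,
                                 seed = 1L, mode = "permutation") {
  stopifnot(all(node_order %in% rownames(expr)))
  res <- list()
  for (t in seq_along(node_order)[-1L]) {
    tgt <- node_order[t]
    pred <- node_order[seq_len(t - 1L)]
    X <- standardize_cols(t(expr[pred, , drop = FALSE]))
    y <- drop(standardize_cols(cbind(expr[tgt, ])))
    sub_seed <- (seed * 131071 + t * 524287) %% .Machine$integer.max
    lp <- lasso_pvalues(y, X, B = B, seed = sub_seed, mode = mode)
    res[[t]] <- data.frame(regulator = pred, target = tgt, p = lp$p,
                           p_randomized = if (mode == "permutation")
                             lp$p_randomized else lp$p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (!is.null(alpha)) out <- out[out$p <= alpha, , drop = FALSE]
  out$score <- -log10(out$p)
  out <- out[order(-out$score, out$regulator, out$target),
             c("regulator", "target", "score", "p", "p_randomized")]
  rownames(out) <- NULL
  class(out) <- c("bn_structure", "data.frame")
  out
}

#' Maximum-likelihood linear-Gaussian parameters for a network structure
#'
#' Each gene is regressed on its parents' expression profiles by ordinary
#' least squares (with intercept). The residual variance uses the
#' maximum-likelihood divisor m (not m - p - 1), matching the network
#' likelihood used downstream. Edge signs are the signs of the fitted
#' coefficients (activating for positive, repressing for negative). Genes
#' without parents get their marginal mean and ML variance. A gene with at
#' least as many parents as samples makes the likelihood divergent and is an
#' error.
#'
#' @param expr Expression matrix (genes x samples).
#' @param structure \code{bn_structure} (or any data frame with regulator
#'   and target columns).
#' @return Object of class \code{bn_fit}: list with \code{edges}
#'   (regulator, target, coefficient, sign, score), \code{intercept},
#'   \code{sigma2}, \code{deterministic} (per-gene logical: exactly
#'   deterministic fit, variance 0), \code{parents} (named list).
#' @export
fit_linear_gaussian <- function(expr, structure) {
  genes <- rownames(expr)
  m <- ncol(expr)
  miss <- setdiff(unique(c(structure$regulator, structure$target)), genes)
  if (length(miss))
    stop("structure names genes absent from the expression matrix: ",
         paste(miss, collapse = ", "))
  parents <- split(structure$regulator, factor(structure$target,
                                               levels = genes))
  intercept <- sigma2 <- stats::setNames(numeric(length(genes)), genes)
  det_flag <- stats::setNames(logical(length(genes)), genes)
  coefs <- list()
  for (g in genes) {
    pa <- parents[[g]]
    y <- expr[g, ]
    if (length(pa) >= m)
      stop("gene '", g, "' has ", length(pa), " regulators for ", m,
           " samples: log-likelihood diverges")
    if (length(pa) == 0L) {
      intercept[g] <- mean(y)
      sigma2[g] <- mean((y - mean(y))^2)
    } else {
      Xp <- cbind(`(Intercept)` = 1, t(expr[pa, , drop = FALSE]))
      fit <- stats::lm.fit(Xp, y)
      b <- fit$coefficients
      b[is.na(b)] <- 0
      intercept[g] <- b[1L]
      sigma2[g] <- mean(fit$residuals^2)
      coefs[[g]] <- data.frame(regulator = pa, target = g,
                               coefficient = unname(b[-1L]),
                               stringsAsFactors = FALSE)
    }
    det_flag[g] <- sigma2[g] <= 1e-12
  }
  edges <- if (length(coefs)) do.call(rbind, coefs) else
    data.frame(regulator = character(0), target = character(0),
               coefficient = numeric(0))
  if (nrow(edges)) {
    edges$sign <- ifelse(edges$coefficient >= 0, "activating", "repressing")
    key <- paste(edges$regulator, edges$target)
    skey <- paste(structure$regulator, structure$target)
    edges$score <- if (!is.null(structure$score))
      structure$score[match(key, skey)] else NA_real_
  }
  rownames(edges) <- NULL
  structure(list(gene_ids = genes, edges = edges, intercept = intercept,
                 sigma2 = sigma2, deterministic = det_flag,
                 parents = parents, n_samples = m),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("Linear-Gaussian Bayesian network fit: ", length(x$gene_ids),
      " genes, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "activating"), " activating, ",
      sum(x$edges$sign == "repressing"), " repressing)\n", sep = "")
  invisible(x)
}
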