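#' Fit a Bayesian gene network by genetic node ordering
#'
#' The main entry point of the package. Runs the full pipeline on matched
#' expression and genotype data: (A) per-gene rank-normal preprocessing and
#' best cis-eQTL mapping under an expected-false-discovery budget; (B)
#' pairwise causal-anchor scores using each gene's eQTL as an instrument;
#' (C) greedy assembly of the maximum-weight DAG whose topological order is
#' the genetic node ordering; (D) variable selection of each gene's parents
#' among its predecessors, either by score truncation or by lasso-path
#' critical-regularization p-values, followed by maximum-likelihood linear
#' regression of every gene on its parents.
#'
#' @param expr Expression matrix (genes x samples), raw values; set
#'   \code{normalize = FALSE} if already rank-normalized.
#' @param geno Genotype matrix (variants x samples), sample-aligned.
#' @param candidates Named list gene -> cis-candidate variant ids. Ignored
#'   when \code{eqtl} is supplied.
#' @param eqtl Optional precomputed \code{eqtl_map}.
#' @param scores Optional precomputed \code{\link{score_matrix}} (e.g. an
#'   external causal-inference run), bypassing stages A-B.
#' @param method \code{"truncate"} (default) or \code{"lasso"}.
#' @param threshold,top_k Sparsity control for \code{method = "truncate"}
#'   (exactly one).
#' @param alpha Significance level for \code{method = "lasso"}.
#' @param expected_false_discoveries eQTL mapping budget (default 1 per
#'   dataset).
#' @param normalize Apply \code{\link{rank_normal_transform}} (default
#'   TRUE).
#' @param seed Integer seed governing all randomness (permutation nulls).
#' @param B Permutations for lasso p-values.
#' @return Object of class \code{genord_bn} extending \code{bn_fit}, with
#'   additionally \code{call}, \code{method}, \code{eqtl}, \code{scores},
#'   \code{dag}, \code{node_order}, \code{expr} (the preprocessed data the
#'   parameters were fitted on).
#' @examples
#' sim <- simulate_instance(sim_config(n_genes = 20, n_samples = 100,
#'                                     seed = 7))
#' fit <- genord_bn(sim$expr, sim$geno, sim$candidates, threshold = 0.6)
#' print(fit)
#' head(coef(fit))
#' @export
genord_bn <- function(expr, geno, candidates = NULL, eqtl = NULL,
                      scores = NULL, method = c("truncate", "lasso"),
                      threshold = NULL, top_k = NULL, alpha = 0.05,
                      expected_false_discoveries = 1, normalize = TRUE,
                      seed = 1L, B = 1000) {
  method <- match.arg(method)
  cl <- match.call()
  if (normalize) expr <- rank_normal_transform(expr)
  if (is.null(scores)) {
    check_sample_alignment(expr, geno)
    if (is.null(eqtl)) {
      if (is.null(candidates))
        stop("one of 'candidates', 'eqtl' or 'scores' is required")
      eqtl <- map_best_cis_eqtl(expr, geno, candidates,
                                expected_false_discoveries)
    }
    scores <- causal_anchor_scores(expr, geno, eqtl, seed = seed)
  }
  dag <- greedy_max_weight_dag(scores)
  structure_df <- if (method == "truncate") {
    if (is.null(threshold) && is.null(top_k)) threshold <- 0.5
    truncate_network(dag, threshold = threshold, top_k = top_k)
  } else {
    lasso_select_network(expr, dag$node_order, alpha = alpha, B = B,
                         seed = seed)
  }
  bn <- fit_linear_gaussian(expr, structure_df)
  bn$call <- cl
  bn$method <- method
  bn$eqtl <- eqtl
  bn$scores <- scores
  bn$dag <- dag
  bn$node_order <- dag$node_order
  bn$expr <- expr
  class(bn) <- c("genord_bn", "bn_fit")
  bn
}

#' @export
print.genord_bn <- function(x, ...) {
  cat("Bayesian gene network (genetic node ordering, method = '",
      x$method, "')\n", sep = "")
  cat("  genes: ", length(x$gene_ids), ", samples: ", x$n_samples,
      "\n", sep = "")
  if (!is.null(x$eqtl))
    cat("  genes with cis-eQTL anchor: ", length(anchored_genes(x$eqtl)),
        "\n", sep = "")
  cat("  ordering DAG: ", nrow(x$dag$edges), " edges (",
      nrow(x$dag$skipped), " skipped as cyclic)\n", sep = "")
  cat("  selected network: ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "activating"), " activating, ",
      sum(x$edges$sign == "repressing"), " repressing)\n", sep = "")
  invisible(x)
}

#' @export
summary.genord_bn <- function(object, ...) {
  indeg <- lengths(object$parents)
  out <- list(fit = object,
              in_degree = summary(indeg),
              n_deterministic = sum(object$deterministic),
              sigma2 = summary(object$sigma2),
              loglik = tryCatch(log_likelihood(object$expr, object),
                                error = function(e) NA_real_))
  class(out) <- "summary.genord_bn"
  out
}

#' @export
print.summary.genord_bn <- function(x, ...) {
  print(x$fit)
  cat("  in-degree: "); print(x$in_degree)
  cat("  residual variance: "); print(x$sigma2)
  cat("  log-likelihood: ", format(x$loglik, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
coef.genord_bn <- function(object, ...) {
  object$edges[, c("regulator", "target", "coefficient", "sign")]
}

#' @export
logLik.genord_bn <- function(object, ...) {
  ll <- log_likelihood(object$expr, object)
  attr(ll, "df") <- nrow(object$edges) + 2 * length(object$gene_ids)
  attr(ll, "nobs") <- object$n_samples
  class(ll) <- "logLik"
  ll
}

#' Predict expression from parents' observed values
#'
#' @param object A \code{genord_bn} fit.
#' @param newdata Expression matrix (genes x samples) supplying the
#'   parents' observed values; defaults to the training data.
#' @param ... Unused.
#' @return Matrix of fitted means, genes x samples.
#' @export
predict.genord_bn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$expr
  predict_from_fit(object, newdata)
}

#' @export
residuals.genord_bn <- function(object, ...) {
  object$expr - predict_from_fit(object, object$expr)
}

#' Simulate expression data from a fitted network
#'
#' Ancestral sampling of the fitted linear-Gaussian structural equations
#' in topological order: each gene is its fitted linear function of the
#' sampled parent values plus Gaussian noise at its residual variance.
#'
#' @param object A \code{genord_bn} fit.
#' @param nsim Number of samples to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix genes x nsim.
#' @export
simulate.genord_bn <- function(object, nsim = 1, seed = NULL, ...) {
  ord <- object$node_order
  out <- matrix(0, length(object$gene_ids), nsim,
                dimnames = list(object$gene_ids,
                                paste0("sim", seq_len(nsim))))
  with_seed(seed, {
    for (g in ord) {
      mu <- rep(object$intercept[g], nsim)
      pa <- object$parents[[g]]
      if (length(pa)) {
        b <- object$edges$coefficient[object$edges$target == g]
        names(b) <- object$edges$regulator[object$edges$target == g]
        mu <- mu + drop(b[pa] %*% out[pa, , drop = FALSE])
      }
      out[g, ] <- stats::rnorm(nsim, mu, sqrt(object$sigma2[g]))
    }
  })
  out[object$gene_ids, , drop = FALSE]
}

#' Plot the selected network
#'
#' Draws the sparse network with igraph when available (activating edges
#' as solid arrows, repressing as dashed); otherwise falls back to a
#' barplot of the in-degree distribution.
#'
#' @param x A \code{genord_bn} fit.
#' @param ... Passed to the igraph plot method.
#' @export
plot.genord_bn <- function(x, ...) {
  e <- x$edges
  if (requireNamespace("igraph", quietly = TRUE) && nrow(e)) {
    g <- igraph::graph_from_data_frame(
      e[, c("regulator", "target")], directed = TRUE,
      vertices = x$gene_ids[x$gene_ids %in% c(e$regulator, e$target)])
    igraph::E(g)$lty <- ifelse(e$sign == "activating", 1, 2)
    igraph::plot.igraph(g, edge.arrow.size = 0.3, vertex.size = 6,
                        vertex.label.cex = 0.6, ...)
  } else {
    graphics::barplot(table(lengths(x$parents)),
                      xlab = "in-degree", ylab = "genes",
                      main = "In-degree distribution")
  }
  invisible(x)
}
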