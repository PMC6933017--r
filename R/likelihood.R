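#' Data log-likelihood of a fitted linear-Gaussian network
#'
#' Computes \eqn{\sum_k \sum_j \log N(x_{jk} \mid \mu_{jk},
#' \hat\sigma_j^2)} with \eqn{\mu_{jk}} the fitted linear function of the
#' parents' values in sample k. Genes with an exactly deterministic fit
#' (residual variance 0) make the likelihood divergent; this is an error
#' unless a variance floor is supplied.
#'
#' @param expr Expression matrix with the genes of the fit.
#' @param bn A \code{bn_fit} from \code{\link{fit_linear_gaussian}}.
#' @param variance_floor Optional positive floor applied to residual
#'   variances (e.g. 1e-12) for exploratory use; default off.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(expr, bn, variance_floor = NULL) {
  if (!setequal(rownames(expr), bn$gene_ids))
    stop("gene ids of the expression matrix and the fit do not match")
  s2 <- bn$sigma2
  if (is.null(variance_floor)) {
    if (any(bn$deterministic))
      stop("deterministic fit (residual variance 0) for gene(s) ",
           paste(bn$gene_ids[bn$deterministic], collapse = ", "),
           ": log-likelihood diverges (set variance_floor to clip)")
  } else s2 <- pmax(s2, variance_floor)
  ll <- 0
  for (g in bn$gene_ids) {
    mu <- bn$intercept[g]
    pa <- bn$parents[[g]]
    if (length(pa)) {
      b <- bn$edges$coefficient[bn$edges$target == g]
      names(b) <- bn$edges$regulator[bn$edges$target == g]
      mu <- mu + drop(b[pa] %*% expr[pa, , drop = FALSE])
    }
    ll <- ll + sum(stats::dnorm(expr[g, ], mean = mu, sd = sqrt(s2[g]),
                                log = TRUE))
  }
  ll
}

#' Posterior score decomposition of a network
#'
#' Decomposes the (unnormalized) posterior log-probability of a network
#' structure into the expression data term \eqn{\log p(X \mid G)} and the
#' genetic term \eqn{\sum_j \sum_{i \in Pa_j} g_{ij}} with
#' \eqn{g_{ij} = \log P_{ij}} from the pairwise score matrix. Normalization
#' constants are dropped throughout, so only differences between structures
#' on the same data are meaningful. An edge whose pairwise probability is
#' excluded (or zero) cannot be part of the model and raises an error.
#'
#' @param expr Expression matrix.
#' @param scores A \code{\link{score_matrix}}.
#' @param bn A \code{bn_fit}.
#' @param variance_floor Passed to \code{\link{log_likelihood}}.
#' @return List of class \code{score_decomposition} with \code{data_term},
#'   \code{genetic_term}, \code{total}.
#' @export
posterior_score <- function(expr, scores, bn, variance_floor = NULL) {
  e <- bn$edges
  genetic <- 0
  if (nrow(e)) {
    pij <- scores$probs[cbind(match(e$regulator, scores$gene_ids),
                              match(e$target, scores$gene_ids))]
    bad <- is.na(pij) | pij == 0
    if (any(bad))
      stop("edge(s) with excluded pairwise probability cannot be part of ",
           "the model: ",
           paste(e$regulator[bad], "->", e$target[bad], collapse = ", "))
    genetic <- sum(log(pij))
  }
  data_term <- log_likelihood(expr, bn, variance_floor)
  structure(list(data_term = data_term, genetic_term = genetic,
                 total = data_term + genetic),
            class = "score_decomposition")
}

#' @export
print.score_decomposition <- function(x, ...) {
  cat("data_term\t", format(x$data_term, digits = 10), "\n",
      "genetic_term\t", format(x$genetic_term, digits = 10), "\n",
      "total\t", format(x$total, digits = 10), "\n", sep = "")
  invisible(x)
}
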