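#' Pairwise score matrix container
#'
#' Holds posterior probabilities \eqn{P_{ij}} for the causal relation
#' i -> j over all ordered gene pairs. Cells that are excluded from the model
#' (the diagonal, and every row of a gene without an eQTL, which has zero
#' probability of being causal for any other gene) are stored as \code{NA}.
#' Edge weights for the ordering step are \eqn{g_{ij} = \log P_{ij}};
#' excluded cells correspond to \eqn{g_{ij} = -\infty}.
#'
#' @param probs Square numeric matrix with row/column names (gene ids);
#'   values in [0, 1] or NA for excluded cells.
#' @return An object of class \code{score_matrix}.
#' @export
score_matrix <- function(probs) {
  stopifnot(is.matrix(probs), nrow(probs) == ncol(probs),
            identical(rownames(probs), colnames(probs)))
  diag(probs) <- NA_real_
  rng <- range(probs, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("probabilities must lie in [0, 1]")
  structure(list(probs = probs, gene_ids = rownames(probs)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  n <- length(x$gene_ids)
  adm <- sum(!is.na(x$probs))
  cat("Pairwise causal score matrix: ", n, " genes, ", adm,
      " admissible ordered pairs\n", sep = "")
  invisible(x)
}

# genotype-class ANOVA likelihood-ratio statistics of every row of Y against
# a single grouping; returns -m * log(1 - R^2) per row (0 for constant rows)
anova_lr_stats <- function(Y, groups) {
  g <- factor(groups)
  m <- ncol(Y)
  n_c <- tabulate(g)
  M <- stats::model.matrix(~ g - 1)          # m x k indicator
  gsum <- Y %*% M                            # row sums per class
  gmean2 <- sweep(gsum^2, 2L, n_c, "/")
  tot <- rowSums(Y)
  ssb <- rowSums(gmean2) - tot^2 / m
  sst <- rowSums(Y^2) - tot^2 / m
  # rows with (numerically) no variation carry no association signal; the
  # threshold is absolute because expression is unit-scale rank-normal
  r2 <- ifelse(sst > 1e-10 * m, pmax(0, pmin(1, ssb / sst)), 0)
  -m * log1p(-pmin(r2, 1 - 1e-12))
}

#' Convert test statistics to posterior probabilities via local FDR
#'
#' Estimates, for each statistic, the posterior probability of a true effect
#' as one minus the local false discovery rate
#' \eqn{\pi_0 f_0(s) / f(s)}, where \eqn{f_0} is a kernel density of
#' permutation-null statistics, \eqn{f} a kernel density of the observed
#' statistics, and \eqn{\pi_0} is estimated conservatively as twice the
#' fraction of observed statistics below the null median (capped at 1).
#' The result is clipped to [0, 1] and made monotone non-decreasing in the
#' statistic by isotonic regression.
#'
#' @param stats Observed statistics.
#' @param null_stats Statistics from permuted data (at least 100 draws).
#' @return Numeric vector of posterior probabilities, aligned with
#'   \code{stats}.
#' @export
estimate_posteriors <- function(stats, null_stats) {
  if (length(null_stats) < 100L)
    stop("calibration error: need at least 100 null draws, got ",
         length(null_stats))
  med0 <- stats::median(null_stats)
  # tie-robust: equals 2 * F(med0-) with continuous data, 1 when all tied
  pi0 <- min(1, mean(stats <= med0) + mean(stats < med0))
  lo <- min(stats, null_stats); hi <- max(stats, null_stats)
  span <- max(hi - lo, 1e-12)
  f0d <- stats::density(null_stats, n = 1024, from = lo - 0.05 * span,
                        to = hi + 0.05 * span)
  fd <- stats::density(stats, n = 1024, from = lo - 0.05 * span,
                       to = hi + 0.05 * span)
  f0 <- stats::approx(f0d$x, f0d$y, xout = stats, yleft = 0, yright = 0)$y
  f <- stats::approx(fd$x, fd$y, xout = stats, yleft = 0, yright = 0)$y
  # leave-one-out correction: remove each point's own kernel mass so the
  # density ratio is not biased downward at the observed statistics
  N <- length(stats)
  if (N >= 2L)
    f <- (N * f - dnorm0 / fd$bw) / (N - 1L)
  # an observed point carries at least its own kernel mass; keep a fraction
  # of it as a floor so isolated extreme statistics do not explode the ratio
  f <- pmax(f, 0.1 * dnorm0 / (N * fd$bw))
  post <- 1 - pi0 * f0 / f       # clipped only after isotonic smoothing
  o <- order(stats)
  iso <- stats::isoreg(seq_along(o), post[o])
  post[o] <- pmin(1, pmax(0, iso$yf))
  post
}

#' Causal-anchor scores for all ordered gene pairs
#'
#' For every gene i with an assigned eQTL L_i and every other gene j, two
#' genotype-class ANOVA tests are combined: (a) the secondary test of X_j
#' against the genotype classes of L_i, and (b) the conditioning test of the
#' residual of X_j on X_i against the same classes. Each statistic is
#' converted to a posterior probability by permutation-calibrated local FDR
#' (\code{\link{estimate_posteriors}}; the null permutes the genotype labels
#' of the anchor). The pair score is
#' \deqn{P_{ij} = \pi_{sec}(i,j) (1 - \pi_{cond}(i,j)),}
#' high when L_i is associated with X_j but not with X_j adjusted for X_i,
#' the signature of mediation through gene i. Rows of genes without an eQTL
#' are excluded entirely.
#'
#' @param expr Rank-normalized expression matrix (genes x samples).
#' @param geno Genotype matrix, sample-aligned.
#' @param eqtl An \code{eqtl_map} from \code{\link{map_best_cis_eqtl}}.
#' @param n_null_per_stat Permutation-null draws per observed statistic
#'   (pooled per anchor; at least 100 total, capped at \code{max_null}).
#' @param max_null Cap on pooled null draws per anchor.
#' @param seed Integer seed for the permutation null.
#' @return A \code{\link{score_matrix}}.
#' @export
causal_anchor_scores <- function(expr, geno, eqtl, n_null_per_stat = 10,
                                 max_null = 1e5, seed = 1L) {
  check_sample_alignment(expr, geno)
  genes <- rownames(expr)
  n <- length(genes); m <- ncol(expr)
  probs <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  anch <- anchored_genes(eqtl)
  with_seed(seed, {
    for (gid in anch) {
      v <- eqtl$variant[eqtl$gene == gid]
      groups <- geno[v, ]
      k <- length(unique(groups))
      if (k < 2L) stop("eQTL variant '", v, "' has a single genotype class")
      if (m < k + 2L)
        stop("insufficient data: ", m, " samples for ", k,
             " genotype classes")
      i <- match(gid, genes)
      xi <- expr[i, ] - mean(expr[i, ])
      Yj <- expr[-i, , drop = FALSE]
      Yc <- Yj - rowMeans(Yj)
      # residuals of each X_j on X_i
      bet <- (Yc %*% xi) / sum(xi^2)
      Rj <- Yc - tcrossprod(bet, xi)
      s_sec <- anova_lr_stats(Yj, groups)
      s_cond <- anova_lr_stats(Rj, groups)
      n_tests <- n - 1L
      B <- ceiling(min(max_null, max(100, n_null_per_stat * n_tests)) /
                     n_tests)
      null_sec <- null_cond <- vector("list", B)
      for (b in seq_len(B)) {
        gp <- sample(groups)
        null_sec[[b]] <- anova_lr_stats(Yj, gp)
        null_cond[[b]] <- anova_lr_stats(Rj, gp)
      }
      pi_sec <- estimate_posteriors(s_sec, unlist(null_sec))
      pi_cond <- estimate_posteriors(s_cond, unlist(null_cond))
      probs[i, -i] <- pi_sec * (1 - pi_cond)
    }
  })
  score_matrix(probs)
}

#' Random score matrix (negative control)
#'
#' Uniform(0,1) probabilities on every admissible cell, with the same
#' exclusion pattern (diagonal plus rows of eQTL-less genes) as the
#' informative matrix, reproducible per seed. Used as the random-ordering
#' control in downstream analyses.
#'
#' @param gene_ids Character vector of gene ids.
#' @param eqtl An \code{eqtl_map}.
#' @param seed Integer seed.
#' @return A \code{\link{score_matrix}}.
#' @export
random_score_matrix <- function(gene_ids, eqtl, seed) {
  n <- length(gene_ids)
  probs <- matrix(NA_real_, n, n, dimnames = list(gene_ids, gene_ids))
  anch <- intersect(gene_ids, anchored_genes(eqtl))
  with_seed(seed, {
    for (gid in anch) {
      i <- match(gid, gene_ids)
      probs[i, -i] <- stats::runif(n - 1L)
    }
  })
  score_matrix(probs)
}

#' Read / write a dense score matrix
#'
#' Dense n x n TSV (same dialect as \code{\link{read_matrix}}) with
#' \code{"."} for excluded cells. Allows substituting an externally computed
#' pairwise probability matrix bit-for-bit.
#'
#' @param path File path.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- vapply(body, function(x) {
    x <- x[-1L]
    suppressWarnings(ifelse(x == ".", NA_real_, as.numeric(x)))
  }, numeric(length(header)))
  probs <- t(vals)
  dimnames(probs) <- list(ids, header)
  score_matrix(probs)
}

#' @rdname read_score_matrix
#' @param scores A \code{score_matrix}.
#' @export
write_score_matrix <- function(scores, path) {
  p <- scores$probs
  fmt <- matrix(ifelse(is.na(p), ".",
                       format(p, digits = 17, scientific = FALSE,
                              trim = TRUE)), nrow = nrow(p))
  lines <- c(paste(c("gene", colnames(p)), collapse = "\t"),
             vapply(seq_len(nrow(p)), function(i)
               paste(c(rownames(p)[i], fmt[i, ]), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

dnorm0 <- 1 / sqrt(2 * pi)   # Gaussian kernel at 0

# evaluate expr with a temporarily fixed RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
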