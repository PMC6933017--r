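#' False-discovery-control linearity diagnostic
#'
#' Checks whether a network score supports a uniform error rate across
#' target genes: after discarding the top 5\% of predictions network-wide
#' (to remove true positives, given the in-degree sparsity of real
#' networks), the number of significant regulators per target should grow
#' linearly with its number of candidate regulators (its predecessor count
#' in the node order). The slope is fitted by least squares through the
#' origin. Note the operational reading of "false positive" here: a
#' prediction that remains significant after the top-5\% discard.
#'
#' @param edges Data frame with regulator, target and either \code{p}
#'   (p-values; significant when <= alpha) or \code{score} treated as a
#'   posterior probability (significant when >= 1 - alpha).
#' @param node_order Character vector of gene ids in topological order.
#' @param alpha Significance level.
#' @param discard_top Fraction of top predictions discarded first
#'   (default 0.05).
#' @return List of class \code{fdc_report}: \code{points} (data frame
#'   target/candidates/significant), \code{slope}, \code{r_squared},
#'   \code{discarded} (data frame of removed top predictions).
#' @export
fdc_linearity <- function(edges, node_order, alpha = 0.05,
                          discard_top = 0.05) {
  use_p <- !is.null(edges$p)
  sig_score <- if (use_p) -edges$p else edges$score
  o <- order(-sig_score, edges$regulator, edges$target)
  edges <- edges[o, , drop = FALSE]
  n_top <- floor(discard_top * nrow(edges))
  discarded <- utils::head(edges, n_top)
  rest <- utils::tail(edges, nrow(edges) - n_top)
  sig <- if (use_p) rest$p <= alpha else rest$score >= 1 - alpha
  counts <- table(factor(rest$target[sig], levels = node_order))
  pts <- data.frame(target = node_order,
                    candidates = seq_along(node_order) - 1L,
                    significant = as.integer(counts[node_order]),
                    stringsAsFactors = FALSE)
  pts$significant[is.na(pts$significant)] <- 0L
  if (sum(pts$candidates > 0) < 10L)
    warning("fewer than 10 targets with candidates: diagnostic unstable")
  x <- pts$candidates; y <- pts$significant
  slope <- if (sum(x^2) > 0) sum(x * y) / sum(x^2) else 0
  r2 <- if (sum(y^2) > 0) 1 - sum((y - slope * x)^2) / sum(y^2) else 1
  structure(list(points = pts, slope = slope, r_squared = r2,
                 discarded = discarded, alpha = alpha,
                 discard_top = discard_top),
            class = "fdc_report")
}

#' @export
print.fdc_report <- function(x, ...) {
  cat("FDC linearity diagnostic (top ", 100 * x$discard_top,
      "% discarded, alpha = ", x$alpha, "):\n  slope = ",
      format(x$slope, digits = 4), ", R^2 = ",
      format(x$r_squared, digits = 4), " over ",
      nrow(x$points), " targets\n", sep = "")
  invisible(x)
}

#' Precision-recall curve and area for a predicted network
#'
#' Sweeps the predictions in order of descending score, treating tied
#' scores as a block, and accumulates precision = TP / (TP + FP) and
#' recall = TP / |gold|. The area under the curve is the step-wise sum
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} (no trapezoids). When a restriction
#' universe is supplied, gold edges are kept only if both endpoints are in
#' it, and predictions only if their regulator occurs as a gold regulator
#' and their target as a gold target.
#'
#' @param predicted Data frame with regulator, target, score.
#' @param gold Data frame with regulator, target (gold-standard edges).
#' @param genes Optional character vector: the transcriptomic gene
#'   universe used for the both-present restriction; \code{NULL} disables
#'   restriction.
#' @return List of class \code{pr_result}: \code{curve} (data frame score,
#'   tp, fp, precision, recall), \code{aupr}, \code{n_gold}. For a binary
#'   network (all scores equal) the curve is the single PR point.
#' @export
precision_recall <- function(predicted, gold, genes = NULL) {
  if (!is.null(genes)) {
    gold <- gold[gold$regulator %in% genes & gold$target %in% genes, ,
                 drop = FALSE]
    predicted <- predicted[predicted$regulator %in% gold$regulator &
                             predicted$target %in% gold$target, ,
                           drop = FALSE]
  }
  if (nrow(gold) == 0L)
    stop("empty gold standard after restriction: evaluation impossible")
  gold_key <- paste(gold$regulator, gold$target)
  if (is.null(predicted$score)) predicted$score <- 1
  predicted <- predicted[order(-predicted$score, predicted$regulator,
                               predicted$target), , drop = FALSE]
  hit <- paste(predicted$regulator, predicted$target) %in% gold_key
  # block boundaries at the last element of each tied score group
  idx <- which(!duplicated(predicted$score, fromLast = TRUE))
  tp <- cumsum(hit)[idx]
  np <- idx
  prec <- tp / np
  rec <- tp / length(gold_key)
  aupr <- sum(diff(c(0, rec)) * prec)
  structure(list(curve = data.frame(score = predicted$score[idx], tp = tp,
                                    fp = np - tp, precision = prec,
                                    recall = rec),
                 aupr = aupr, n_gold = length(gold_key)),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat("Precision-recall: ", nrow(x$curve), " points, |gold| = ", x$n_gold,
      ", AUPR = ", format(x$aupr, digits = 4), "\n", sep = "")
  invisible(x)
}

#' k-fold cross-validated predictive error of inferred networks
#'
#' Splits samples into k folds (seeded random permutation, round-robin).
#' For every fold the full inference pipeline is re-run on the training
#' samples only (rank-normalization, eQTL mapping, causal-anchor scores,
#' greedy DAG, truncation at each requested sparsity threshold, ML
#' regression); each gene in the held-out samples is then predicted from
#' its parents' observed test values through the fitted linear model.
#' Genes without parents are predicted by their training mean. Expression
#' is rank-normalized within the training and test splits separately, so
#' structure inference never sees test samples. Reported errors: rmse,
#' the root of the mean squared residual pooled over all genes and test
#' samples; mlse, the mean over genes of the log per-gene mean squared
#' residual.
#'
#' @param expr Raw expression matrix (genes x samples).
#' @param geno Genotype matrix.
#' @param candidates Cis-candidate map (named list).
#' @param thresholds Numeric vector of truncation thresholds to sweep.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment and score permutations).
#' @param expected_false_discoveries Passed to eQTL mapping.
#' @param structure_override Optional fixed \code{bn_structure} (e.g. the
#'   true simulated DAG); skips inference and only refits parameters per
#'   fold. Thresholds are ignored in that case.
#' @return List of class \code{cv_report}: \code{per_fold} data frame
#'   (threshold, fold, n_edges, rmse_train, rmse_test), \code{summary}
#'   data frame per threshold with pooled train/test rmse and mlse.
#' @export
cross_validate <- function(expr, geno, candidates, thresholds = 0.5,
                           k = 5, seed = 1L,
                           expected_false_discoveries = 1,
                           structure_override = NULL) {
  m <- ncol(expr)
  if (m < 5 * k) stop("need at least 5 samples per fold")
  folds <- with_seed(seed, {
    perm <- sample.int(m)
    split(perm, rep_len(seq_len(k), m))
  })
  labels <- if (is.null(structure_override)) thresholds else NA_real_
  per_fold <- list()
  pooled <- lapply(seq_along(labels), function(i)
    list(train = list(), test = list(),
         per_gene_sq_test = list()))
  for (f in seq_len(k)) {
    test_idx <- sort(folds[[f]])
    train_idx <- setdiff(seq_len(m), test_idx)
    tr <- rank_normal_transform(expr[, train_idx, drop = FALSE])
    te <- rank_normal_transform(expr[, test_idx, drop = FALSE])
    structures <- if (!is.null(structure_override)) {
      list(structure_override)
    } else {
      eq <- map_best_cis_eqtl(tr, geno[, train_idx, drop = FALSE],
                              candidates, expected_false_discoveries)
      sc <- causal_anchor_scores(tr, geno[, train_idx, drop = FALSE], eq,
                                 seed = seed + f)
      dag <- greedy_max_weight_dag(sc)
      lapply(thresholds, function(th) truncate_network(dag, threshold = th))
    }
    for (i in seq_along(structures)) {
      bn <- fit_linear_gaussian(tr, structures[[i]])
      pr_tr <- predict_from_fit(bn, tr)
      pr_te <- predict_from_fit(bn, te)
      res_tr <- tr - pr_tr
      res_te <- te - pr_te
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        threshold = labels[i], fold = f, n_edges = nrow(structures[[i]]),
        rmse_train = sqrt(mean(res_tr^2)), rmse_test = sqrt(mean(res_te^2)))
      pooled[[i]]$train[[f]] <- res_tr
      pooled[[i]]$test[[f]] <- res_te
    }
  }
  summary <- do.call(rbind, lapply(seq_along(labels), function(i) {
    rtr <- do.call(cbind, pooled[[i]]$train)
    rte <- do.call(cbind, pooled[[i]]$test)
    data.frame(threshold = labels[i],
               n_edges = mean(vapply(per_fold, function(d)
                 if (identical(d$threshold, labels[i]) ||
                     (is.na(labels[i]) && is.na(d$threshold)))
                   d$n_edges else NA_real_, numeric(1L)), na.rm = TRUE),
               rmse_train = sqrt(mean(rtr^2)),
               rmse_test = sqrt(mean(rte^2)),
               mlse_test = mean(log(rowMeans(rte^2))))
  }))
  structure(list(per_fold = do.call(rbind, per_fold), summary = summary,
                 k = k, seed = seed),
            class = "cv_report")
}

# predict every gene from its parents' observed values in `data`
predict_from_fit <- function(bn, data) {
  out <- matrix(0, nrow(data), ncol(data), dimnames = dimnames(data))
  for (g in bn$gene_ids) {
    mu <- bn$intercept[g]
    pa <- bn$parents[[g]]
    if (length(pa)) {
      b <- bn$edges$coefficient[bn$edges$target == g]
      names(b) <- bn$edges$regulator[bn$edges$target == g]
      out[g, ] <- mu + drop(b[pa] %*% data[pa, , drop = FALSE])
    } else out[g, ] <- mu
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation (", nrow(x$summary),
      " sparsity level(s)):\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
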