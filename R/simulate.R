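#' Configuration for the structural-equation simulator
#'
#' Defaults emulate a systems-genetics benchmark of the DREAM5 Systems
#' Genetics A flavour: a sparse random DAG over the genes, about a quarter
#' of genes carrying a biallelic cis-eQTL that directly affects their
#' expression, and linear-Gaussian expression data. The generating process
#' is an idealization (the benchmark's own kinetic simulator is nonlinear);
#' a linear-Gaussian structural equation model is used because it matches
#' the model class being fitted, making recovery tests well-posed.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (individuals).
#' @param cis_fraction Fraction of genes with a causal cis-eQTL.
#' @param mean_parents Expected number of parents per gene.
#' @param effect_size_range Range for the magnitude of edge coefficients;
#'   signs are random.
#' @param cis_variance_fraction Fraction of a cis gene's variance explained
#'   by its eQTL genotype.
#' @param maf_range Range of minor allele frequencies.
#' @param noise_sd Standard deviation of the intrinsic noise term.
#' @param candidates_per_gene Cis-candidate variants offered per gene (the
#'   causal one, when present, plus decoys).
#' @param n_confounders Optional number of latent N(0,1) confounders, each
#'   added as an unobserved common parent of a random gene pair.
#' @param seed Integer seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 100, n_samples = 300, cis_fraction = 0.25,
                       mean_parents = 2, effect_size_range = c(0.5, 1.5),
                       cis_variance_fraction = 0.5,
                       maf_range = c(0.1, 0.5), noise_sd = 1,
                       candidates_per_gene = 3, n_confounders = 0,
                       seed = 1L) {
  stopifnot(n_genes >= 2, n_samples >= 3,
            cis_fraction >= 0, cis_fraction <= 1,
            mean_parents >= 0, mean_parents < n_genes,
            cis_variance_fraction > 0, cis_variance_fraction < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, noise_sd > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a systems-genetics instance with known ground truth
#'
#' Draws a random node order and a sparse DAG (each forward edge included
#' independently so the expected in-degree equals \code{mean_parents}),
#' biallelic Hardy-Weinberg genotypes, and expression by ancestral
#' traversal of the structural equations
#' \deqn{x_j = \sum_{i \in Pa_j} \beta_{ij} x_i + \gamma_j e_j +
#' \epsilon_j,}
#' where \eqn{e_j} is the (centered) genotype dosage of gene j's cis
#' variant (cis genes only) with \eqn{\gamma_j} scaled so the genotype
#' explains \code{cis_variance_fraction} of the gene's variance, and
#' \eqn{\epsilon_j \sim N(0, noise\_sd^2)}. Every gene is offered
#' \code{candidates_per_gene} cis-candidate variants; non-causal candidates
#' are independent decoys. Fully reproducible per seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{genord_sim} with \code{expr} (genes x
#'   samples), \code{geno} (variants x samples), \code{candidates} (named
#'   list gene -> variant ids), and \code{truth} (list: \code{edges} data
#'   frame regulator/target/beta, \code{eqtl} data frame
#'   gene/variant/gamma, \code{node_order}, \code{implied_cov},
#'   \code{config}).
#' @export
simulate_instance <- function(config = sim_config()) {
  cf <- config
  n <- cf$n_genes; m <- cf$n_samples
  genes <- sprintf("G%03d", seq_len(n))
  with_seed(cf$seed, {
    ord <- sample(genes)
    q <- if (n > 1) min(1, 2 * cf$mean_parents / (n - 1)) else 0
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < q
    edges <- data.frame(regulator = ord[pairs[keep, 1L]],
                        target = ord[pairs[keep, 2L]],
                        beta = sample(c(-1, 1), sum(keep), TRUE) *
                          stats::runif(sum(keep), cf$effect_size_range[1],
                                       cf$effect_size_range[2]),
                        stringsAsFactors = FALSE)
    cis_genes <- sort(sample(genes, round(cf$cis_fraction * n)))
    # genotypes: candidate variants per gene; the first candidate of a cis
    # gene is its causal variant, the rest are independent decoys
    n_var <- n * cf$candidates_per_gene
    variants <- sprintf("V%04d", seq_len(n_var))
    maf <- stats::runif(n_var, cf$maf_range[1], cf$maf_range[2])
    geno <- matrix(stats::rbinom(n_var * m, 2L, rep(maf, m)), n_var, m,
                   dimnames = list(variants,
                                   sprintf("S%03d", seq_len(m))))
    candidates <- lapply(seq_len(n), function(i)
      variants[((i - 1L) * cf$candidates_per_gene + 1L):
                 (i * cf$candidates_per_gene)])
    names(candidates) <- genes
    causal_variant <- stats::setNames(vapply(candidates, `[[`,
                                             character(1L), 1L), genes)
    # confounders: latent standard-normal parents of random gene pairs
    conf_targets <- if (cf$n_confounders > 0)
      replicate(cf$n_confounders, sample(genes, 2L), simplify = FALSE)
    else list()
    # ancestral traversal with exact implied-covariance bookkeeping
    S <- matrix(0, n, n, dimnames = list(genes, genes))
    X <- matrix(0, n, m, dimnames = list(genes, colnames(geno)))
    gamma <- stats::setNames(rep(NA_real_, n), genes)
    Zconf <- lapply(conf_targets, function(x) stats::rnorm(m))
    for (t in seq_len(n)) {
      g <- ord[t]
      pa <- edges$regulator[edges$target == g]
      b <- edges$beta[edges$target == g]
      base <- rep(0, m); v_par <- 0
      if (length(pa)) {
        base <- drop(b %*% X[pa, , drop = FALSE])
        v_par <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
      }
      v_conf <- 0; conf_add <- rep(0, m)
      for (ci in seq_along(conf_targets)) if (g %in% conf_targets[[ci]]) {
        conf_add <- conf_add + Zconf[[ci]]
        v_conf <- v_conf + 1
      }
      eps <- stats::rnorm(m, 0, cf$noise_sd)
      V <- v_par + v_conf + cf$noise_sd^2
      x <- base + conf_add + eps
      if (g %in% cis_genes) {
        f <- maf[match(causal_variant[g], variants)]
        ve <- 2 * f * (1 - f)
        gamma[g] <- sqrt(cf$cis_variance_fraction /
                           (1 - cf$cis_variance_fraction) * V / ve)
        e <- geno[causal_variant[g], ] - 2 * f
        x <- x + gamma[g] * e
        V <- V + gamma[g]^2 * ve
      }
      X[g, ] <- x
      # implied covariances with previously generated genes
      if (t > 1L) {
        prev <- ord[seq_len(t - 1L)]
        cv <- rep(0, t - 1L)
        if (length(pa))
          cv <- drop(t(S[prev, pa, drop = FALSE] %*% b))
        for (ci in seq_along(conf_targets)) if (g %in% conf_targets[[ci]]) {
          other <- setdiff(conf_targets[[ci]], g)
          # latent confounder contributes its loading along already
          # generated co-children (unit loadings)
          if (other %in% prev) {
            contrib <- conf_cov_path(S, prev, other)
            cv <- cv + contrib
          }
        }
        S[g, prev] <- S[prev, g] <- cv
      }
      S[g, g] <- V
    }
    truth_eqtl <- data.frame(gene = cis_genes,
                             variant = causal_variant[cis_genes],
                             gamma = gamma[cis_genes],
                             stringsAsFactors = FALSE)
    rownames(truth_eqtl) <- NULL
    # the incremental covariance bookkeeping does not propagate latent
    # confounder loadings through descendants; only report it when exact
    if (cf$n_confounders > 0) S <- NULL
    structure(list(expr = X, geno = geno, candidates = candidates,
                   truth = list(edges = edges, eqtl = truth_eqtl,
                                node_order = ord, implied_cov = S,
                                config = cf)),
              class = "genord_sim")
  })
}

# covariance contribution of a unit-loading latent confounder shared with
# `other`: one unit along the column of `other` (direct), as propagated
# covariance is already handled through S for descendants
conf_cov_path <- function(S, prev, other) {
  out <- rep(0, length(prev))
  out[match(other, prev)] <- 1
  out
}

#' @export
print.genord_sim <- function(x, ...) {
  cf <- x$truth$config
  cat("Simulated systems-genetics instance: ", cf$n_genes, " genes x ",
      cf$n_samples, " samples, ", nrow(x$truth$edges), " true edges, ",
      nrow(x$truth$eqtl), " cis genes\n", sep = "")
  invisible(x)
}

#' Write / read a simulated instance
#'
#' Serializes all components as TSV files under a common prefix:
#' \code{<prefix>_expr.tsv}, \code{<prefix>_geno.tsv},
#' \code{<prefix>_candidates.tsv} (gene<TAB>variant, one row per
#' candidate), \code{<prefix>_gold.tsv} (gold-standard edge list,
#' regulator<TAB>target), \code{<prefix>_eqtl_truth.tsv}. Round-trips
#' losslessly up to float formatting; \code{read_instance} raises an
#' integrity error when files are missing.
#'
#' @param sim A \code{genord_sim}.
#' @param prefix Path prefix.
#' @export
write_instance <- function(sim, prefix) {
  write_matrix(sim$expr, paste0(prefix, "_expr.tsv"), "gene")
  write_matrix(sim$geno, paste0(prefix, "_geno.tsv"), "variant")
  cand <- data.frame(gene = rep(names(sim$candidates),
                                lengths(sim$candidates)),
                     variant = unlist(sim$candidates))
  utils::write.table(cand, paste0(prefix, "_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edge_list(sim$truth$edges[, c("regulator", "target")],
                  paste0(prefix, "_gold.tsv"))
  utils::write.table(sim$truth$eqtl, paste0(prefix, "_eqtl_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_instance
#' @export
read_instance <- function(prefix) {
  paths <- paste0(prefix, c("_expr.tsv", "_geno.tsv", "_candidates.tsv",
                            "_gold.tsv"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("partial instance on disk; missing: ",
         paste(paths[missing], collapse = ", "))
  cand <- utils::read.delim(paths[3L], stringsAsFactors = FALSE)
  list(expr = read_matrix(paths[1L], "expression"),
       geno = read_matrix(paths[2L], "genotype"),
       candidates = split(cand$variant, factor(cand$gene,
                                               levels = unique(cand$gene))),
       gold = read_edge_list(paths[4L]))
}
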