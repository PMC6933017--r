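#' Run the pipeline from a configuration
#'
#' Executes the requested stages in dependency order
#' (simulate -> eqtl -> causal -> order -> network -> score / eval),
#' reading and writing the package's TSV artifacts so stages can be re-run
#' and mixed with externally produced files. All randomness flows from the
#' single \code{seed} key; two runs with the same configuration produce
#' identical outputs. Unknown configuration keys are rejected and every
#' stage's effective parameters are echoed to the log.
#'
#' @param config Named list, or path to a flat \code{key = value} text
#'   configuration file. Recognized keys: \code{stages} (comma-separated),
#'   \code{out_prefix}, \code{expr}, \code{geno}, \code{candidates},
#'   \code{eqtl}, \code{scores_in}, \code{gold}, \code{method},
#'   \code{threshold}, \code{top_k}, \code{alpha},
#'   \code{expected_false_discoveries}, \code{seed}, \code{n_genes},
#'   \code{n_samples}, \code{cis_fraction}, \code{mean_parents},
#'   \code{cis_variance_fraction}, \code{noise_sd}, \code{log_level}.
#' @param overrides Named list of values taking precedence over the file.
#' @return Invisibly, a list of the artifacts produced.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cf <- if (is.character(config)) read_config(config) else config
  cf[names(overrides)] <- overrides
  known <- c("stages", "out_prefix", "expr", "geno", "candidates", "eqtl",
             "scores_in", "gold", "method", "threshold", "top_k", "alpha",
             "expected_false_discoveries", "seed", "n_genes", "n_samples",
             "cis_fraction", "mean_parents", "cis_variance_fraction",
             "noise_sd", "log_level")
  bad <- setdiff(names(cf), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  num <- function(k, d = NULL) if (is.null(cf[[k]])) d else as.numeric(cf[[k]])
  chr <- function(k, d = NULL) if (is.null(cf[[k]])) d else as.character(cf[[k]])
  seed <- as.integer(num("seed", 1))
  prefix <- chr("out_prefix", "genord_run")
  stages <- strsplit(chr("stages", "eqtl,causal,order,network"), ",")[[1]]
  loglev <- chr("log_level", "info")
  logmsg <- function(...) if (loglev != "quiet")
    message(format(Sys.time(), "%H:%M:%S"), " [genord] ", ...)
  artifacts <- list()

  if ("simulate" %in% stages) {
    scf <- sim_config(n_genes = num("n_genes", 100),
                      n_samples = num("n_samples", 300),
                      cis_fraction = num("cis_fraction", 0.25),
                      mean_parents = num("mean_parents", 2),
                      cis_variance_fraction =
                        num("cis_variance_fraction", 0.5),
                      noise_sd = num("noise_sd", 1), seed = seed)
    logmsg("simulate: n_genes=", scf$n_genes, " n_samples=", scf$n_samples,
           " seed=", seed)
    sim <- simulate_instance(scf)
    write_instance(sim, prefix)
    cf$expr <- paste0(prefix, "_expr.tsv")
    cf$geno <- paste0(prefix, "_geno.tsv")
    cf$candidates <- paste0(prefix, "_candidates.tsv")
    cf$gold <- paste0(prefix, "_gold.tsv")
    artifacts$sim <- sim
  }
  need <- function(key, stage) {
    if (is.null(cf[[key]]) || !file.exists(cf[[key]]))
      stop("stage '", stage, "' requires artifact '", key,
           "' which is missing")
    cf[[key]]
  }
  expr <- geno <- eq <- sc <- dag <- NULL
  load_expr <- function() {
    if (is.null(expr))
      expr <<- rank_normal_transform(read_matrix(need("expr", "input"),
                                                 "expression"))
    expr
  }
  load_geno <- function() {
    if (is.null(geno)) geno <<- read_matrix(need("geno", "input"),
                                            "genotype")
    geno
  }
  if ("eqtl" %in% stages) {
    cand <- utils::read.delim(need("candidates", "eqtl"),
                              stringsAsFactors = FALSE)
    cand <- split(cand$variant, factor(cand$gene, levels = unique(cand$gene)))
    efd <- num("expected_false_discoveries", 1)
    logmsg("eqtl: expected_false_discoveries=", efd)
    eq <- map_best_cis_eqtl(load_expr(), load_geno(), cand, efd)
    write_eqtl_map(eq, paste0(prefix, "_eqtl.tsv"))
    artifacts$eqtl <- eq
  }
  if ("causal" %in% stages) {
    if (!is.null(cf$scores_in)) {
      logmsg("causal: loading precomputed scores from ", cf$scores_in)
      sc <- read_score_matrix(need("scores_in", "causal"))
    } else {
      if (is.null(eq)) eq <- read_eqtl_map(need("eqtl", "causal"))
      logmsg("causal: permutation-calibrated anchor scores, seed=", seed)
      sc <- causal_anchor_scores(load_expr(), load_geno(), eq, seed = seed)
    }
    write_score_matrix(sc, paste0(prefix, "_scores.tsv"))
    artifacts$scores <- sc
  }
  if ("order" %in% stages) {
    if (is.null(sc)) {
      p <- paste0(prefix, "_scores.tsv")
      if (!file.exists(p)) stop("stage 'order' requires the causal score ",
                                "matrix artifact '", p, "'")
      sc <- read_score_matrix(p)
    }
    logmsg("order: greedy maximum-weight DAG")
    dag <- greedy_max_weight_dag(sc)
    write_edge_list(data.frame(regulator = dag$edges$regulator,
                               target = dag$edges$target,
                               score = dag$edges$prob),
                    paste0(prefix, "_dag.tsv"))
    writeLines(dag$node_order, paste0(prefix, "_order.tsv"))
    artifacts$dag <- dag
  }
  if ("network" %in% stages) {
    if (is.null(dag)) stop("stage 'network' requires the 'order' stage ",
                           "artifact (run order first)")
    method <- chr("method", "truncate")
    logmsg("network: method=", method)
    st <- if (method == "truncate") {
      th <- num("threshold"); tk <- num("top_k")
      if (is.null(th) && is.null(tk)) th <- 0.5
      truncate_network(dag, threshold = th, top_k = tk)
    } else {
      lasso_select_network(load_expr(), dag$node_order,
                           alpha = num("alpha", 0.05), seed = seed)
    }
    bn <- fit_linear_gaussian(load_expr(), st)
    write_edge_list(st, paste0(prefix, "_network.tsv"))
    utils::write.table(bn$edges[, c("target", "regulator", "coefficient",
                                    "sign")],
                       paste0(prefix, "_parameters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = bn$gene_ids,
                                  intercept = bn$intercept,
                                  residual_variance = bn$sigma2),
                       paste0(prefix, "_pergene.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$network <- bn
  }
  if ("eval-pr" %in% stages) {
    netp <- paste0(prefix, "_network.tsv")
    if (!file.exists(netp)) stop("stage 'eval-pr' requires the 'network' ",
                                 "stage artifact")
    pred <- read_edge_list(netp)
    gold <- read_edge_list(need("gold", "eval-pr"))
    pr <- precision_recall(pred, gold)
    logmsg("eval-pr: AUPR=", format(pr$aupr, digits = 4))
    utils::write.table(pr$curve, paste0(prefix, "_pr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$pr <- pr
  }
  invisible(artifacts)
}

# flat key = value config reader; '#' comments and blank lines ignored
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, character(1L), 1L))
}

#' Command-line interface
#'
#' Thin argument-parsing layer used by the \code{exec/genord-bn} script:
#' \code{genord-bn <stage> --config <file> [--seed N] [--out-prefix P]
#' ...} where stage is one of simulate, eqtl, causal, order, network, run
#' (the full chain), or eval-pr. Flags override config-file values.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
genord_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: genord-bn {simulate,eqtl,causal,order,network,run,eval-pr}",
        "[--config FILE] [--seed N] [--out-prefix P] [--method M]",
        "[--threshold T] [--top-k K] [--alpha A] [--expr F] [--geno F]",
        "[--candidates F] [--gold F] [--log-level L]\n")
    return(invisible(0L))
  }
  stage <- args[1]
  stages <- switch(stage,
                   run = "simulate,eqtl,causal,order,network,eval-pr",
                   stage)
  flags <- args[-1]
  ov <- list(stages = stages)
  key_map <- c("--config" = "config", "--seed" = "seed",
               "--out-prefix" = "out_prefix", "--method" = "method",
               "--threshold" = "threshold", "--top-k" = "top_k",
               "--alpha" = "alpha", "--expr" = "expr", "--geno" = "geno",
               "--candidates" = "candidates", "--gold" = "gold",
               "--eqtl" = "eqtl", "--scores-in" = "scores_in",
               "--log-level" = "log_level")
  i <- 1L
  config <- list()
  while (i <= length(flags)) {
    k <- key_map[flags[i]]
    if (is.na(k)) stop("unknown flag: ", flags[i])
    if (k == "config") config <- read_config(flags[i + 1L])
    else ov[[k]] <- flags[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    run_pipeline(config, overrides = ov)
    0L
  }, error = function(e) {
    message("genord-bn error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
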