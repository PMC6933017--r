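# shared fixture builders and independent oracles for the test suite

rand_expr <- function(n = 5, m = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("G%02d", seq_len(n)),
                         sprintf("S%02d", seq_len(m))))
}

rand_geno <- function(v = 4, m = 8, seed = 2) {
  set.seed(seed)
  matrix(rbinom(v * m, 2L, 0.4), v, m,
         dimnames = list(sprintf("V%02d", seq_len(v)),
                         sprintf("S%02d", seq_len(m))))
}

# score matrix from a named edge weight list, all other cells excluded
scores_from_edges <- function(ids, edges) {
  p <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (e in edges) p[e[[1]], e[[2]]] <- e[[3]]
  score_matrix(p)
}

# the worked 3-gene instance: greedy and brute force agree at 1.85
worked_scores <- function() {
  scores_from_edges(c("1", "2", "3"), list(
    list("1", "2", 0.9), list("2", "3", 0.8), list("3", "1", 0.7),
    list("2", "1", 0.3), list("3", "2", 0.2), list("1", "3", 0.15)))
}

# full random score matrix with every off-diagonal cell admissible
full_random_scores <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  p <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  diag(p) <- NA
  score_matrix(p)
}

# independent DFS reachability oracle on an adjacency matrix
dfs_reaches <- function(adj, from, to) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x == to) return(TRUE)
    nb <- which(adj[x, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  FALSE
}

# eqtl_map with explicit anchors (variant per gene or NA)
make_eqtl_map <- function(genes, variants) {
  structure(data.frame(gene = genes, variant = variants,
                       H = ifelse(is.na(variants), NA_real_, 1),
                       p = ifelse(is.na(variants), NA_real_, 1e-6),
                       stringsAsFactors = FALSE),
            class = c("eqtl_map", "data.frame"))
}

# mediated pair (X_j = X_i, eQTL explaining half of X_i's variance) embedded
# in a background of independent genes
mediation_instance <- function(n_bg = 28, m = 300, seed = 1) {
  set.seed(seed)
  f <- 0.3
  e <- rbinom(m, 2L, f)
  xi <- (e - 2 * f) / sqrt(2 * f * (1 - f)) + rnorm(m)
  X <- rbind(Gi = xi, Gj = xi,
             matrix(rnorm(n_bg * m), n_bg, m,
                    dimnames = list(sprintf("N%02d", seq_len(n_bg)), NULL)))
  colnames(X) <- paste0("S", seq_len(m))
  G <- rbind(V1 = e)
  colnames(G) <- colnames(X)
  storage.mode(G) <- "integer"
  list(expr = rank_normal_transform(X), geno = G,
       eqtl = make_eqtl_map(rownames(X),
                            c("V1", rep(NA, n_bg + 1))))
}
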