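#' Incremental DAG builder with online cycle detection
#'
#' Maintains a directed acyclic graph under edge insertions together with a
#' valid topological order, using a two-way bounded search (Pearce-Kelly
#' style): an insertion u -> v with order(u) > order(v) triggers a forward
#' search from v and a backward search from u restricted to the affected
#' order window; the edge is rejected iff u is reachable from v, otherwise
#' the window is locally reordered. Total work over all insertions is far
#' below one full reachability scan per edge in practice; correctness is
#' equivalent to a from-scratch DFS reachability check.
#'
#' @param gene_ids Character vector of node ids.
#' @return An object of class \code{dag_builder} with methods
#'   \code{$try_add(u, v)} (returns TRUE if accepted, FALSE if the edge
#'   would close a cycle), \code{$edges()} (two-column matrix of ids) and
#'   \code{$topo_order()} (ids in topological order).
#' @export
dag_builder <- function(gene_ids) {
  n <- length(gene_ids)
  ord <- seq_len(n)                    # ord[v]: position of node v
  out <- vector("list", n)
  inc <- vector("list", n)
  idx <- function(x) if (is.character(x)) match(x, gene_ids) else as.integer(x)

  dfs_window <- function(start, adj, keep) {
    # iterative DFS over adj restricted to nodes satisfying keep(ord)
    seen <- logical(n)
    stack <- start
    seen[start] <- TRUE
    found <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      found <- c(found, x)
      for (y in adj[[x]]) if (!seen[y] && keep(ord[y])) {
        seen[y] <- TRUE
        stack <- c(stack, y)
      }
    }
    found
  }

  try_add <- function(u, v) {
    u <- idx(u); v <- idx(v)
    if (is.na(u) || is.na(v)) stop("unknown node id")
    if (u == v) return(FALSE)
    if (ord[u] > ord[v]) {
      lb <- ord[v]; ub <- ord[u]
      fwd <- dfs_window(v, out, function(o) o <= ub)
      if (u %in% fwd) return(FALSE)
      bwd <- dfs_window(u, inc, function(o) o >= lb)
      # reorder the affected window: the backward component (ancestors of u)
      # takes the smallest freed slots in its old relative order, then the
      # forward component (descendants of v)
      nodes <- c(bwd[order(ord[bwd])], fwd[order(ord[fwd])])
      ord[nodes] <<- sort(ord[nodes])
    }
    out[[u]] <<- c(out[[u]], v)
    inc[[v]] <<- c(inc[[v]], u)
    TRUE
  }

  obj <- list(
    try_add = try_add,
    edges = function() {
      e <- do.call(rbind, lapply(seq_len(n), function(u)
        if (length(out[[u]])) cbind(u, out[[u]])))
      if (is.null(e)) matrix(character(0), 0, 2)
      else cbind(gene_ids[e[, 1]], gene_ids[e[, 2]])
    },
    topo_order = function() gene_ids[order(ord)],
    .ord = function() ord
  )
  class(obj) <- "dag_builder"
  obj
}

#' Greedy maximum-weight DAG ("genetic node ordering")
#'
#' Candidate regulations are ranked by their posterior probability and added
#' to an empty network one at a time, starting from the most probable,
#' skipping any edge that would create a directed cycle, until all
#' candidates are processed. Excluded cells (no eQTL, diagonal, zero
#' probability) are never proposed. When every admissible cell has positive
#' weight and all genes are anchored, the result is a tournament DAG with
#' n(n-1)/2 edges; its topological order is the genetic node ordering used
#' downstream. Ties in probability are broken by regulator id, then target
#' id, for reproducibility.
#'
#' @param scores A \code{\link{score_matrix}}.
#' @return Object of class \code{weighted_dag}: list with \code{gene_ids},
#'   \code{edges} (data frame regulator/target/prob/weight = log prob),
#'   \code{node_order} (ids; genes without admissible outgoing cells are
#'   placed last, id-sorted), and \code{skipped} (rejected edges).
#' @export
greedy_max_weight_dag <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  p <- scores$probs
  ids <- scores$gene_ids
  adm <- which(!is.na(p) & p > 0, arr.ind = TRUE)
  if (nrow(adm) == 0L) {
    warning("no admissible edges; returning empty DAG with trivial order")
    return(structure(list(
      gene_ids = ids,
      edges = data.frame(regulator = character(0), target = character(0),
                         prob = numeric(0), weight = numeric(0)),
      node_order = sort(ids),
      skipped = data.frame(regulator = character(0), target = character(0),
                           prob = numeric(0), reason = character(0))),
      class = "weighted_dag"))
  }
  w <- p[adm]
  o <- order(-w, ids[adm[, 1L]], ids[adm[, 2L]])
  adm <- adm[o, , drop = FALSE]; w <- w[o]
  b <- dag_builder(ids)
  acc <- logical(nrow(adm))
  for (k in seq_len(nrow(adm)))
    acc[k] <- b$try_add(adm[k, 1L], adm[k, 2L])
  edges <- data.frame(regulator = ids[adm[acc, 1L]],
                      target = ids[adm[acc, 2L]],
                      prob = w[acc], weight = log(w[acc]),
                      stringsAsFactors = FALSE)
  skipped <- data.frame(regulator = ids[adm[!acc, 1L]],
                        target = ids[adm[!acc, 2L]],
                        prob = w[!acc], reason = rep("cycle", sum(!acc)),
                        stringsAsFactors = FALSE)
  # anchored genes (any admissible outgoing cell) keep the builder's order;
  # target-only genes are appended, id-sorted
  has_out <- rowSums(!is.na(p) & p > 0) > 0
  topo <- b$topo_order()
  node_order <- c(topo[topo %in% ids[has_out]], sort(ids[!has_out]))
  dag <- structure(list(gene_ids = ids, edges = edges,
                        node_order = node_order, skipped = skipped),
                   class = "weighted_dag")
  if (!dag_is_acyclic(dag)) stop("internal error: greedy result is cyclic")
  dag
}

# full DFS acyclicity verification on a weighted_dag (construction-end check)
dag_is_acyclic <- function(dag) {
  pos <- match(dag$gene_ids, dag$node_order)
  e <- dag$edges
  if (nrow(e) == 0L) return(TRUE)
  all(pos[match(e$regulator, dag$gene_ids)] <
        pos[match(e$target, dag$gene_ids)]) && {
    # independent check: Kahn's algorithm must consume all nodes
    n <- length(dag$gene_ids)
    ei <- cbind(match(e$regulator, dag$gene_ids),
                match(e$target, dag$gene_ids))
    indeg <- tabulate(ei[, 2L], n)
    outl <- split(ei[, 2L], factor(ei[, 1L], levels = seq_len(n)))
    q <- which(indeg == 0L); done <- 0L
    while (length(q)) {
      x <- q[1L]; q <- q[-1L]; done <- done + 1L
      for (y in outl[[x]]) {
        indeg[y] <- indeg[y] - 1L
        if (indeg[y] == 0L) q <- c(q, y)
      }
    }
    done == n
  }
}

#' @export
print.weighted_dag <- function(x, ...) {
  cat("Maximum-weight DAG (greedy): ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " edges (", nrow(x$skipped), " skipped as cyclic), ",
      "total weight ", format(sum(x$edges$prob), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Exact maximum-weight DAG by exhaustive ordering search
#'
#' Testing oracle for the greedy heuristic (the problem is NP-hard in
#' general): enumerates all n! node orderings, takes every admissible
#' forward edge under each ordering, and returns the maximum total weight
#' attained and one ordering attaining it. Only for n <= 8.
#'
#' @param scores A \code{\link{score_matrix}} with at most 8 genes.
#' @return List with \code{weight} (optimal total probability mass) and
#'   \code{order} (character vector, one optimal ordering).
#' @export
brute_force_max_weight_dag <- function(scores) {
  p <- scores$probs
  n <- nrow(p)
  if (n > 8L) stop("exhaustive search limited to n <= 8, got n = ", n)
  p0 <- ifelse(is.na(p), 0, p)
  perms <- all_permutations(n)
  best_w <- -Inf; best <- NULL
  for (k in seq_len(nrow(perms))) {
    pos <- integer(n); pos[perms[k, ]] <- seq_len(n)
    w <- sum(p0[outer(pos, pos, "<")])
    if (w > best_w) { best_w <- w; best <- perms[k, ] }
  }
  list(weight = best_w, order = scores$gene_ids[best])
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}
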