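#' Kruskal-Wallis test of expression against genotype classes
#'
#' Rank-based one-way test used for eQTL mapping: samples are grouped by
#' genotype class and the tie-corrected Kruskal-Wallis H statistic is
#' computed on the within-gene expression ranks, with a chi-square
#' approximation on (number of classes - 1) degrees of freedom.
#'
#' When the expression values are completely tied (no rank variation) the
#' tie-corrected statistic is taken as 0 with p = 1.
#'
#' @param expr_row Numeric vector of expression values (length m).
#' @param geno_row Integer vector of genotype codes (length m).
#' @return List with elements \code{H} and \code{p}.
#' @export
kruskal_wallis <- function(expr_row, geno_row) {
  stopifnot(length(expr_row) == length(geno_row))
  g <- factor(geno_row)
  k <- nlevels(g)
  if (k < 2L)
    stop("Kruskal-Wallis test undefined: single genotype class")
  m <- length(expr_row)
  r <- rank(expr_row)
  rbar <- tapply(r, g, mean)
  n_g <- tabulate(g)
  H <- 12 / (m * (m + 1)) * sum(n_g * (rbar - (m + 1) / 2)^2)
  ties <- table(expr_row)
  C <- 1 - sum(ties^3 - ties) / (m^3 - m)
  if (C <= 0) return(list(H = 0, p = 1))   # all values tied
  H <- H / C
  list(H = H, p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE))
}

#' Map each gene to its best cis-eQTL
#'
#' For every gene, each cis-candidate variant is tested with
#' \code{\link{kruskal_wallis}}; the variant with the smallest p-value is
#' retained if it passes an expected-false-discovery cutoff: the p-value
#' threshold is \code{expected_false_discoveries / (number of tests
#' performed)}, so that the expected number of null genes passing is at most
#' the budget (one false discovery per dataset by default). Ties between
#' candidates are broken by larger H, then lexicographic variant id.
#'
#' @param expr Expression matrix (genes x samples).
#' @param geno Genotype matrix (variants x samples), sample-aligned with
#'   \code{expr}.
#' @param candidates Named list: gene id -> character vector of candidate
#'   variant ids (empty vectors allowed).
#' @param expected_false_discoveries Expected number of false eQTL
#'   assignments tolerated across the dataset (default 1).
#' @return Data frame of class \code{eqtl_map} with one row per gene of
#'   \code{expr} and columns \code{gene}, \code{variant} (NA when no eQTL
#'   passes), \code{H}, \code{p}.
#' @export
map_best_cis_eqtl <- function(expr, geno, candidates,
                              expected_false_discoveries = 1) {
  check_sample_alignment(expr, geno)
  genes <- rownames(expr)
  unknown <- setdiff(unlist(candidates), rownames(geno))
  if (length(unknown))
    stop("candidate variant(s) absent from genotype matrix: ",
         paste(unknown, collapse = ", "))
  n_tests <- sum(vapply(genes, function(g)
    length(candidates[[g]]), integer(1L)))
  thr <- if (n_tests > 0L) expected_false_discoveries / n_tests else 0
  res <- lapply(genes, function(gid) {
    cand <- candidates[[gid]]
    if (is.null(cand) || length(cand) == 0L)
      return(data.frame(gene = gid, variant = NA_character_,
                        H = NA_real_, p = NA_real_))
    tests <- lapply(cand, function(v) {
      gr <- geno[v, ]
      if (length(unique(gr)) < 2L) return(NULL)
      kruskal_wallis(expr[gid, ], gr)
    })
    ok <- !vapply(tests, is.null, logical(1L))
    if (!any(ok)) {
      warning("gene '", gid, "' has candidates but no testable variant; ",
              "recorded as eQTL-less")
      return(data.frame(gene = gid, variant = NA_character_,
                        H = NA_real_, p = NA_real_))
    }
    cand <- cand[ok]; tests <- tests[ok]
    p <- vapply(tests, `[[`, numeric(1L), "p")
    H <- vapply(tests, `[[`, numeric(1L), "H")
    o <- order(p, -H, cand)[1L]
    if (p[o] <= thr)
      data.frame(gene = gid, variant = cand[o], H = H[o], p = p[o])
    else
      data.frame(gene = gid, variant = NA_character_,
                 H = NA_real_, p = NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("eqtl_map", "data.frame")
  out
}

#' Read / write an eQTL map
#'
#' TSV dialect \code{gene<TAB>variant<TAB>H<TAB>p} with \code{"."} marking
#' genes without an assigned eQTL.
#'
#' @param path File path.
#' @export
read_eqtl_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = ".")
  names(df) <- c("gene", "variant", "H", "p")
  class(df) <- c("eqtl_map", "data.frame")
  df
}

#' @rdname read_eqtl_map
#' @param eqtl An \code{eqtl_map} data frame.
#' @export
write_eqtl_map <- function(eqtl, path) {
  fmt <- function(x) ifelse(is.na(x), ".",
                            format(x, digits = 17, scientific = FALSE,
                                   trim = TRUE))
  lines <- c("gene\tvariant\tH\tp",
             sprintf("%s\t%s\t%s\t%s", eqtl$gene, fmt(eqtl$variant),
                     fmt(eqtl$H), fmt(eqtl$p)))
  writeLines(lines, path)
  invisible(path)
}

# genes with an assigned eQTL ("anchored" genes)
anchored_genes <- function(eqtl) eqtl$gene[!is.na(eqtl$variant)]
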