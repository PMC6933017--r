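#' Read an expression or genotype matrix from TSV
#'
#' Matrices are stored as tab-separated text with a header row of sample ids
#' and a first column of row ids (genes for expression, variants for
#' genotypes). The first header cell is ignored. Expression values are real;
#' genotype values must be non-negative integer codes (0, 1, 2, ... for
#' genotype classes).
#'
#' @param path Path to a TSV file.
#' @param kind Either \code{"expression"} or \code{"genotype"}.
#' @return A numeric matrix with row and column names. Genotype matrices are
#'   stored in integer mode.
#' @export
read_matrix <- function(path, kind = c("expression", "genotype")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("matrix file '", path, "' must have a header and at least one row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in '", path, "'")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header)))
    stop("row ", which(nfield != length(header))[1L], " of '", path,
         "' has ", nfield[nfield != length(header)][1L],
         " fields, expected ", length(header))
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(row_ids))
    stop("duplicate row ids in '", path, "': ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  cells <- vapply(body, function(x) x[-1L], character(length(sample_ids)))
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    # cells is samples x rows (vapply transposes)
    r <- (bad - 1L) %/% length(sample_ids) + 1L
    s <- (bad - 1L) %% length(sample_ids) + 1L
    stop("non-numeric value '", cells[bad], "' at row '", row_ids[r],
         "', column '", sample_ids[s], "' in '", path, "'")
  }
  m <- matrix(vals, nrow = length(row_ids), ncol = length(sample_ids),
              byrow = TRUE, dimnames = list(row_ids, sample_ids))
  if (kind == "genotype") {
    if (any(m != round(m)) || any(m < 0))
      stop("genotype matrix '", path,
           "' contains values that are not non-negative integers")
    storage.mode(m) <- "integer"
  }
  m
}

#' Write a matrix in the package's TSV dialect
#'
#' Values are written with 17 significant digits so that
#' \code{read_matrix(write_matrix(x))} round-trips losslessly.
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @param id_header Label for the first header cell (ignored on read).
#' @export
write_matrix <- function(x, path, id_header = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  fmt <- if (is.integer(x)) format(x) else format(x, digits = 17,
                                                  scientific = FALSE,
                                                  trim = TRUE)
  fmt <- matrix(trimws(fmt), nrow = nrow(x))
  lines <- c(paste(c(id_header, colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], fmt[i, ]), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

# sample alignment check used before any paired expression/genotype operation
check_sample_alignment <- function(expr, geno) {
  if (!identical(colnames(expr), colnames(geno)))
    stop("sample ids of expression and genotype matrices do not match ",
         "(same ids in the same order are required)")
  invisible(TRUE)
}

check_genotype_classes <- function(geno) {
  usable <- apply(geno, 1L, function(g) length(unique(g)) >= 2L)
  if (!all(usable))
    warning("variant(s) with a single observed genotype class flagged ",
            "unusable: ", paste(rownames(geno)[!usable], collapse = ", "))
  usable
}

#' Per-gene rank-based transform to a standard normal distribution
#'
#' Each row is replaced by normal scores \eqn{\Phi^{-1}((r_k - 0.5)/m)} where
#' \eqn{r_k} is the within-row rank of sample \eqn{k} (average ranks for
#' ties) and \eqn{m} the number of samples. The transform is monotone in the
#' original values, symmetric, and idempotent up to floating point error.
#'
#' @param expr Expression matrix (genes x samples).
#' @return Matrix of the same shape with rank-normalized rows.
#' @export
rank_normal_transform <- function(expr) {
  stopifnot(is.matrix(expr))
  m <- ncol(expr)
  const <- apply(expr, 1L, function(x) length(unique(x)) < 2L)
  if (any(const))
    stop("constant expression row(s), transform undefined: ",
         paste(rownames(expr)[const], collapse = ", "))
  out <- t(apply(expr, 1L, function(x) qnorm((rank(x) - 0.5) / m)))
  dimnames(out) <- dimnames(expr)
  out
}

#' Read / write an edge list
#'
#' Edge lists are TSV with header \code{regulator<TAB>target<TAB>score};
#' gold-standard lists use the same dialect without the score column.
#'
#' @param path File path.
#' @return A data.frame with columns \code{regulator}, \code{target} and,
#'   when present in the file, \code{score}, sorted by descending score with
#'   ties broken by regulator then target id.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("regulator", "target")
  if (ncol(df) >= 3L) {
    names(df)[3L] <- "score"
    df <- df[order(-df$score, df$regulator, df$target), , drop = FALSE]
  }
  if (any(df$regulator == df$target)) stop("edge list contains self-edges")
  if (anyDuplicated(df[, c("regulator", "target")]))
    stop("edge list contains duplicate (regulator, target) pairs")
  rownames(df) <- NULL
  df
}

#' @rdname read_edge_list
#' @param edges Data frame with columns regulator, target and optionally
#'   score.
#' @export
write_edge_list <- function(edges, path) {
  if (!is.null(edges$score)) {
    edges <- edges[order(-edges$score, edges$regulator, edges$target), ,
                   drop = FALSE]
    lines <- c("regulator\ttarget\tscore",
               sprintf("%s\t%s\t%s", edges$regulator, edges$target,
                       format(edges$score, digits = 17, scientific = FALSE,
                              trim = TRUE)))
  } else {
    lines <- c("regulator\ttarget",
               sprintf("%s\t%s", edges$regulator, edges$target))
  }
  writeLines(lines, path)
  invisible(path)
}
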