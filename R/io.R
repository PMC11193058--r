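#' Read a microbiome count table from TSV
#'
#' Expects a tab-separated file with a header row and identifiers in the first
#' column. Counts must be non-negative integers. The returned matrix is always
#' in samples-in-rows orientation.
#'
#' @param path path to the TSV file.
#' @param orientation `"samples-in-rows"` (default) or `"samples-in-columns"`;
#'   in the latter case the file is transposed on read.
#' @return integer-valued numeric matrix, samples in rows, with dimnames.
#' @export
readCountTable <- function(path,
                           orientation = c("samples-in-rows",
                                           "samples-in-columns")) {
  orientation <- match.arg(orientation)
  w <- .readTsvMatrix(path)
  if (orientation == "samples-in-columns") w <- t(w)
  bad <- which(w < 0 | w != round(w), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at row '%s', column '%s' in %s",
      rownames(w)[bad[1, 1]], colnames(w)[bad[1, 2]], path))
  }
  storage.mode(w) <- "double"
  validateCounts(w)
  w
}

#' Read a response (e.g. metabolite) or covariate table from TSV
#'
#' Samples in rows, header row, identifiers in the first column. All entries
#' must be finite numbers.
#'
#' @inheritParams readCountTable
#' @return numeric matrix with dimnames.
#' @export
readResponseTable <- function(path,
                              orientation = c("samples-in-rows",
                                              "samples-in-columns")) {
  orientation <- match.arg(orientation)
  y <- .readTsvMatrix(path)
  if (orientation == "samples-in-columns") y <- t(y)
  if (any(!is.finite(y))) {
    bad <- which(!is.finite(y), arr.ind = TRUE)
    stop(sprintf("non-finite entry at row '%s', column '%s' in %s",
                 rownames(y)[bad[1, 1]], colnames(y)[bad[1, 2]], path))
  }
  y
}

#' Write a matrix as a TSV table with an identifier column
#'
#' Inverse of [readCountTable()] / [readResponseTable()]: `writeTsvMatrix`
#' followed by a read reproduces the matrix exactly (counts) or to full
#' double-precision round-trip (continuous tables).
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the identifier column header.
#' @export
writeTsvMatrix <- function(x, path, idColumn = "id") {
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
  # %.17g preserves doubles exactly through a write/read round trip
  xc <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  df <- data.frame(rownames(x), xc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsvMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicate column identifiers in ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    # locate the first non-numeric cell for the error message
    for (j in 2:ncol(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (any(is.na(v) & !is.na(df[[j]]))) {
        i <- which(is.na(v) & !is.na(df[[j]]))[1]
        stop(sprintf("non-numeric entry '%s' at row '%s', column '%s' in %s",
                     df[[j]][i], ids[i], colnames(df)[j], path))
      }
    }
    stop("non-numeric entries in ", path)
  }
  rownames(m) <- ids
  m
}

#' Validate a count matrix
#'
#' Checks the abundance-table invariants: no duplicated sample or feature
#' identifiers, non-negative integer counts, and at least one nonzero count
#' per sample.
#'
#' @param w samples-by-features count matrix.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validateCounts <- function(w) {
  if (is.null(rownames(w)) || is.null(colnames(w))) {
    stop("count matrix must carry sample and feature identifiers as dimnames")
  }
  if (anyDuplicated(rownames(w))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(w))) stop("duplicate feature identifiers")
  if (any(w < 0) || any(w != round(w))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(w) == 0)) {
    stop("samples with all-zero counts: ",
         paste(rownames(w)[rowSums(w) == 0], collapse = ", "))
  }
  invisible(w)
}

#' Total-sum scaling and log transform of a count table
#'
#' Adds a pseudocount to every count, divides by the padded sample total
#' (total-sum scaling), and takes logs:
#' \deqn{x_{ij} = \log\frac{w_{ij} + s}{\sum_j (w_{ij} + s)}.}
#' Rows of \code{exp(x)} sum to one, so each sample is a composition on the
#' log scale; all entries are negative.
#'
#' @param w samples-by-features count matrix.
#' @param pseudocount positive value added to every count before scaling
#'   (default 1).
#' @return numeric matrix of log relative abundances with attribute
#'   \code{"pseudocount"}.
#' @export
tssLogTransform <- function(w, pseudocount = 1) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount > 0)
  # all-zero rows are tolerated here (the pseudocount maps them to the
  # uniform composition); table readers enforce the stricter invariant
  if (any(w < 0) || any(w != round(w))) {
    stop("counts must be non-negative integers")
  }
  wp <- w + pseudocount
  x <- log(wp / rowSums(wp))
  attr(x, "pseudocount") <- pseudocount
  x
}

#' Align abundance, response and covariate tables on common samples
#'
#' Restricts all tables to the samples they share and reorders them
#' identically (order of the abundance table's ids, restricted to the common
#' set). When no covariate table is supplied, an intercept-only matrix is
#' created.
#'
#' @param x log relative abundance matrix (samples in rows).
#' @param y response matrix (samples in rows).
#' @param z optional covariate matrix (samples in rows). Its first column must
#'   be the constant 1 intercept; if absent, intercept-only is used.
#' @return list with elements \code{x}, \code{y}, \code{z}, all with identical
#'   rownames, and \code{samples}.
#' @export
alignTables <- function(x, y, z = NULL) {
  common <- intersect(rownames(x), rownames(y))
  if (!is.null(z)) common <- intersect(common, rownames(z))
  if (length(common) < 2) {
    stop("fewer than 2 samples shared across tables")
  }
  common <- rownames(x)[rownames(x) %in% common]
  x <- x[common, , drop = FALSE]
  y <- y[common, , drop = FALSE]
  if (is.null(z)) {
    z <- matrix(1, length(common), 1,
                dimnames = list(common, "(Intercept)"))
  } else {
    z <- z[common, , drop = FALSE]
    if (any(z[, 1] != 1)) {
      stop("first covariate column must be the constant intercept 1")
    }
    if (qr(z)$rank < ncol(z)) stop("covariate matrix is column-rank deficient")
  }
  list(x = x, y = y, z = z, samples = common)
}
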