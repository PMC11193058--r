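#' Serialize a fitted model to a directory of plain-text tables
#'
#' Writes \code{beta.tsv}, \code{U.tsv}, \code{V.tsv}, \code{d.tsv} and (when
#' assembled) \code{C.tsv}, plus \code{manifest.json} recording dimensions,
#' penalty settings, the chosen lambda per component and the package version.
#' Numbers are written at full double precision, so a write/read round trip
#' reproduces the fit exactly.
#'
#' @param fit a \linkS4class{TreeFarFit}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTreeFarFit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- estimatedRank(fit)
  compNames <- if (r > 0) paste0("factor", seq_len(r)) else character(0)
  .named <- function(m, what, whatCol = "col") {
    if (is.null(rownames(m))) rownames(m) <- paste0(what, seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0(whatCol, seq_len(ncol(m)))
    m
  }
  U <- .named(fit@U, "node")
  V <- .named(fit@V, "resp")
  colnames(U) <- colnames(V) <- compNames
  writeTsvMatrix(.named(fit@beta, "z", "resp"), file.path(dir, "beta.tsv"),
                 "covariate")
  writeTsvMatrix(U, file.path(dir, "U.tsv"), "node")
  writeTsvMatrix(V, file.path(dir, "V.tsv"), "response")
  dmat <- matrix(fit@d, nrow = max(r, 0), ncol = 1,
                 dimnames = list(compNames, "d"))
  if (r > 0) writeTsvMatrix(dmat, file.path(dir, "d.tsv"), "component")
  else writeLines("component\td", file.path(dir, "d.tsv"))
  if (nrow(fit@Chat) > 0) {
    writeTsvMatrix(.named(fit@Chat, "leaf", "resp"), file.path(dir, "C.tsv"),
                   "leaf")
  }
  diag <- fit@diagnostics
  manifest <- list(
    package = "treefar",
    version = as.character(utils::packageVersion("treefar")),
    rank = r,
    dims = list(m = nrow(fit@beta), q = ncol(fit@beta),
                nodes = nrow(fit@U),
                leaves = if (nrow(fit@Chat) > 0) nrow(fit@Chat) else NA),
    constraint = as.numeric(fit@cvec),
    chosenLambda = if (length(diag$components)) {
      vapply(diag$components, function(d) d$lambda, 0)
    } else numeric(0),
    penalty = if (!is.null(diag$penalty)) {
      diag$penalty[c("nLambda", "lambdaMinRatio", "elasticAlpha",
                     "adaptiveGamma", "criterion")]
    } else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a serialized fit back from a directory
#'
#' @param dir directory written by [writeTreeFarFit()].
#' @return a \linkS4class{TreeFarFit} (diagnostics restored from the
#'   manifest).
#' @export
readTreeFarFit <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  beta <- .readTsvMatrix(file.path(dir, "beta.tsv"))
  U <- .readTsvMatrix(file.path(dir, "U.tsv"))
  V <- .readTsvMatrix(file.path(dir, "V.tsv"))
  d <- if (manifest$rank > 0) {
    as.numeric(.readTsvMatrix(file.path(dir, "d.tsv"))[, 1])
  } else numeric(0)
  Chat <- if (file.exists(file.path(dir, "C.tsv"))) {
    .readTsvMatrix(file.path(dir, "C.tsv"))
  } else matrix(numeric(0), 0, 0)
  new("TreeFarFit", beta = beta, d = d, U = U, V = V, Chat = Chat,
      cvec = as.numeric(manifest$constraint),
      diagnostics = list(manifest = manifest))
}
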