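#' Latent factor scores of a fitted model
#'
#' Microbiome-side scores \code{Xtilde U} and response-side scores
#' \code{Y V}: each extracted component relates the two linearly, with slope
#' given by its singular value.
#'
#' @param fit a fitted \linkS4class{TreeFarFit} with rank >= 1.
#' @param Xtilde aggregated design (same node order as the fit).
#' @param y response matrix.
#' @return list of class \code{FactorScores} with \code{scores} (n x r),
#'   \code{responseScores} (n x r) and \code{sampleIds}.
#' @export
factorScores <- function(fit, Xtilde, y) {
  if (estimatedRank(fit) < 1) {
    stop("model has rank 0: no factors to score; refit with a weaker ",
         "penalty or larger maxRank")
  }
  stopifnot(nrow(Xtilde) == nrow(y))
  scores <- Xtilde %*% leftVectors(fit)
  responseScores <- y %*% rightVectors(fit)
  colnames(scores) <- colnames(responseScores) <-
    paste0("factor", seq_len(estimatedRank(fit)))
  structure(list(scores = scores, responseScores = responseScores,
                 sampleIds = rownames(Xtilde)),
            class = "FactorScores")
}

#' Selected features and responses of each latent factor
#'
#' Lists the nodes with nonzero left-vector weight (annotated as leaf or
#' internal; internal selections carry their descendant leaf sets, which is
#' how an aggregated feature is read: a common effect of related organisms)
#' and the responses with nonzero right-vector weight.
#'
#' @param fit a fitted \linkS4class{TreeFarFit} or \linkS4class{CrrrFit}.
#' @param A the \linkS4class{AncestryMatrix} used in the fit.
#' @param tol magnitude below which a weight counts as zero.
#' @return list with data.frames \code{u} (factor, nodeId, weight, isLeaf,
#'   descendants) and \code{v} (factor, responseId, weight).
#' @export
nonzeroLoadings <- function(fit, A, tol = 0) {
  U <- leftVectors(fit)
  V <- rightVectors(fit)
  uRows <- list()
  vRows <- list()
  for (k in seq_len(ncol(U))) {
    sel <- which(abs(U[, k]) > tol)
    if (length(sel) > 0) {
      desc <- vapply(sel, function(j) {
        if (A@isLeaf[j]) "" else {
          paste(A@leafIds[A@a[, j] == 1], collapse = ",")
        }
      }, "")
      uRows[[k]] <- data.frame(factor = k, nodeId = A@nodeIds[sel],
                               weight = U[sel, k], isLeaf = A@isLeaf[sel],
                               descendants = desc, row.names = NULL)
    }
    selV <- which(abs(V[, k]) > tol)
    if (length(selV) > 0) {
      ids <- if (is.null(rownames(V))) as.character(selV) else
        rownames(V)[selV]
      vRows[[k]] <- data.frame(factor = k, responseId = ids,
                               weight = V[selV, k], row.names = NULL)
    }
  }
  list(u = if (length(uRows)) do.call(rbind, uRows) else
         data.frame(factor = integer(0), nodeId = character(0),
                    weight = numeric(0), isLeaf = logical(0),
                    descendants = character(0)),
       v = if (length(vRows)) do.call(rbind, vRows) else
         data.frame(factor = integer(0), responseId = character(0),
                    weight = numeric(0)))
}

#' Association of latent factor scores with a binary phenotype
#'
#' One joint logistic regression of the phenotype on all factor scores plus
#' optional adjusters (e.g. age, sex, BMI), with per-factor Wald tests.
#' Factors with p below \code{alpha} are flagged. Under complete or
#' quasi-complete separation the Wald test degenerates; a ridge-penalized
#' logistic fit is used as a fallback for the effect sizes (p-values are then
#' reported as NA).
#'
#' @param scores a \code{FactorScores} object (or matrix of scores).
#' @param phenotype binary 0/1 vector aligned with the score rows.
#' @param adjusters optional covariate matrix whose first column is the
#'   intercept; remaining columns enter the model.
#' @param alpha flagging threshold on the p-value (no multiplicity
#'   correction by default).
#' @param adjustMethod optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. "BH").
#' @return data.frame with one row per factor: estimate, se, statistic,
#'   p.value, flagged.
#' @export
scorePhenotypeAssociation <- function(scores, phenotype, adjusters = NULL,
                                      alpha = 0.05, adjustMethod = NULL) {
  S <- if (inherits(scores, "FactorScores")) scores$scores else scores
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != nrow(S)) stop("phenotype length mismatch")
  if (!all(phenotype %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(phenotype)) < 2) stop("phenotype is constant")
  df <- data.frame(S, check.names = TRUE)
  factorCols <- colnames(df)
  if (!is.null(adjusters)) {
    adj <- adjusters[, -1, drop = FALSE] # intercept handled by glm
    if (ncol(adj) > 0) df <- cbind(df, data.frame(adj, check.names = TRUE))
  }
  df$.pheno <- phenotype
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.pheno ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  rows <- co[factorCols, , drop = FALSE]
  out <- data.frame(factor = factorCols, estimate = rows[, 1],
                    se = rows[, 2], statistic = rows[, 3],
                    p.value = rows[, 4], row.names = NULL)
  if (separated) {
    warning("separation detected; falling back to ridge-penalized logistic ",
            "estimates (p-values reported as NA)")
    if (requireNamespace("glmnet", quietly = TRUE)) {
      xm <- as.matrix(df[, setdiff(colnames(df), ".pheno"), drop = FALSE])
      gf <- glmnet::glmnet(xm, phenotype, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      cf <- as.numeric(stats::coef(gf))[-1]
      names(cf) <- colnames(xm)
      out$estimate <- cf[factorCols]
    }
    out$se <- out$statistic <- out$p.value <- NA_real_
  }
  if (!is.null(adjustMethod)) {
    out$p.value <- stats::p.adjust(out$p.value, method = adjustMethod)
  }
  out$flagged <- !is.na(out$p.value) & out$p.value < alpha
  out
}
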