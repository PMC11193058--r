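#' @useDynLib treefar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Penalty specification for sparse unit-rank extraction
#'
#' Collects the tuning choices of the weighted adaptive elastic-net penalty:
#' the lambda grid (by default 50 points, log-spaced from the smallest lambda
#' that zeroes the component down to \code{lambdaMinRatio} times it), the
#' elastic-net mixing \code{elasticAlpha} (1 = pure lasso; the default 0.95
#' keeps a small ridge stabilizer), the adaptive-weight exponent
#' \code{adaptiveGamma} (0 = plain elastic net), and the model-selection
#' criterion used along the path.
#'
#' @param nLambda number of grid points.
#' @param lambdaMinRatio ratio of the smallest to the largest lambda.
#' @param elasticAlpha elastic-net mixing in (0, 1].
#' @param adaptiveGamma non-negative exponent of the reciprocal-magnitude
#'   adaptive weights.
#' @param criterion "BIC" or "GIC".
#' @param lambdaGrid optional explicit decreasing grid overriding the
#'   automatic one.
#' @return object of class \code{PenaltySpec}.
#' @export
penaltySpec <- function(nLambda = 50, lambdaMinRatio = 1e-3,
                        elasticAlpha = 0.95, adaptiveGamma = 1,
                        criterion = c("BIC", "GIC"), lambdaGrid = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(elasticAlpha > 0, elasticAlpha <= 1, adaptiveGamma >= 0,
            nLambda >= 1, lambdaMinRatio > 0, lambdaMinRatio < 1)
  if (!is.null(lambdaGrid)) {
    # an explicit grid may end at 0 (unpenalized limit)
    if (any(lambdaGrid < 0) ||
        (length(lambdaGrid) > 1 &&
         is.unsorted(rev(lambdaGrid), strictly = TRUE))) {
      stop("lambdaGrid must be strictly decreasing and non-negative")
    }
  }
  structure(list(nLambda = as.integer(nLambda),
                 lambdaMinRatio = lambdaMinRatio,
                 elasticAlpha = elasticAlpha,
                 adaptiveGamma = adaptiveGamma,
                 criterion = criterion,
                 lambdaGrid = lambdaGrid),
            class = "PenaltySpec")
}

#' Initial unit-rank triple from a ridge-stabilized reduced-rank estimate
#'
#' Computes the ridge estimate \code{solve(crossprod(X) + eps n I, crossprod(X, Y))} on the (deflated,
#' covariate-residualized) response, takes its leading singular triple,
#' projects the left vector onto the constraint null space
#' \code{u} with \code{sum(c * u) = 0} and renormalizes. Deterministic; the sign is fixed
#' so the largest-magnitude entry of v is positive. A zero response returns
#' \code{d = 0}, the signal to stop extraction.
#'
#' @param Ytilde deflated response (n x q), covariates already projected out.
#' @param Xtilde aggregated design (n x P).
#' @param cvec constraint vector (length P).
#' @param ridgeEps ridge stabilizer, multiplied by n on the Gram diagonal.
#' @param gram optional precomputed \code{crossprod(Xtilde)}.
#' @return list with elements \code{d}, \code{u}, \code{v}.
#' @export
initialUnitRank <- function(Ytilde, Xtilde, cvec, ridgeEps = 1e-2,
                            gram = NULL) {
  stopifnot(all(is.finite(Ytilde)), all(is.finite(Xtilde)))
  n <- nrow(Xtilde)
  P <- ncol(Xtilde)
  if (max(abs(Ytilde)) < 1e-12) {
    return(list(d = 0, u = rep(0, P), v = rep(0, ncol(Ytilde))))
  }
  if (is.null(gram)) gram <- crossprod(Xtilde)
  gammaRidge <- solve(gram + diag(ridgeEps * n, P), crossprod(Xtilde, Ytilde))
  sv <- svd(gammaRidge)
  cnorm2 <- sum(cvec^2)
  for (k in seq_along(sv$d)) {
    if (sv$d[k] <= 1e-12 * sv$d[1]) break
    u <- sv$u[, k]
    u <- u - cvec * (sum(cvec * u) / cnorm2)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) {
      u <- u / nu
      v <- sv$v[, k]
      if (v[which.max(abs(v))] < 0) {
        v <- -v
        u <- -u
      }
      return(list(d = sv$d[k] * nu, u = u, v = v))
    }
  }
  list(d = 0, u = rep(0, P), v = rep(0, ncol(Ytilde)))
}

#' Adaptive elastic-net weights from an initial unit-rank triple
#'
#' Reciprocal-magnitude weights \code{w = (|init| + tau)^(-gamma)}, floored by
#' \code{tau = 1e-8} and capped at \code{1e8}, so entries that the initial
#' estimate places near zero are penalized (effectively excluded) while strong
#' entries are penalized lightly. \code{gamma = 0} gives unit weights, i.e. a
#' plain elastic net.
#'
#' @param init initial triple from [initialUnitRank()]; must have
#'   \code{d > 0}.
#' @param gamma non-negative weight exponent.
#' @return object of class \code{AdaptiveWeights}: a list with \code{wU},
#'   \code{wV}, the initial triple, and \code{gamma}.
#' @export
adaptiveWeights <- function(init, gamma = 1) {
  if (init$d <= 0) stop("adaptive weights require a nonzero initial estimate")
  stopifnot(gamma >= 0)
  tau <- 1e-8
  cap <- 1e8
  wU <- pmin((abs(init$u) + tau)^(-gamma), cap)
  wV <- pmin((abs(init$v) + tau)^(-gamma), cap)
  structure(list(wU = wU, wV = wV, dInit = init$d,
                 uInit = init$u, vInit = init$v, gamma = gamma),
            class = "AdaptiveWeights")
}

#' Select a lambda by an information criterion along the path
#'
#' \code{BIC = n q log(SSE / (n q)) + log(n q) df} with
#' \code{df = nnz(u) + nnz(v) - 1} (0 for the null fit); GIC replaces the
#' \code{log(n q)} factor with \code{log(log(n q)) log(max(P, q))}. Ties are
#' broken toward the larger (sparser) lambda.
#'
#' @param path data.frame with columns \code{lambda} (decreasing), \code{sse},
#'   \code{df}.
#' @param n,q,P problem dimensions.
#' @param criterion "BIC" or "GIC".
#' @return index of the chosen lambda in the path.
#' @export
selectLambda <- function(path, n, q, P, criterion = c("BIC", "GIC")) {
  criterion <- match.arg(criterion)
  if (nrow(path) == 0) stop("empty tuning path")
  nq <- n * q
  factor <- if (criterion == "BIC") log(nq) else log(log(nq)) * log(max(P, q))
  crit <- nq * log(pmax(path$sse, 1e-300) / nq) + factor * path$df
  ok <- is.finite(crit)
  if (!any(ok)) stop("no finite criterion values along the path")
  crit[!ok] <- Inf
  # path is ordered from the largest lambda down, so the first index among
  # ties is the sparser solution
  which(crit <= min(crit) + 1e-10)[1]
}

# penalized objective of one unit-rank component (unit-norm u, v, scale d)
.ureObjective <- function(sse, d, u, v, lambda, alpha, wU, wV) {
  sse + lambda * (alpha * d * sum(wU * abs(u)) * sum(wV * abs(v)) +
    (1 - alpha) / 2 * d^2 * sum(wU * u^2) * sum(wV * v^2))
}

# project an unnormalized left vector onto {c'u = 0} within its support,
# preserving exact zeros; a singleton support cannot satisfy the constraint
# and collapses to zero
.projectSupport <- function(u, cvec) {
  s <- which(u != 0)
  if (length(s) == 0) return(u)
  cs <- cvec[s]
  u[s] <- u[s] - cs * (sum(cs * u[s]) / sum(cs^2))
  u
}

#' Penalized unit-rank extraction (one component, full lambda path)
#'
#' Solves the constrained sparse unit-rank problem
#' \deqn{\min_{\beta,d,u,v} \|Y_k - Z\beta - \tilde X\, d u v^T\|_F^2 +
#'   \rho_\lambda(\tilde\Gamma \circ duv^T)}
#' subject to \code{sum(c * u) = 0}, \code{||u|| = ||v|| = 1}, by block
#' relaxation: a closed-form soft-thresholded v-step, a coordinate-descent
#' u-step under the equality constraint (augmented Lagrangian in u-space,
#' followed by a support-restricted projection that zeroes the constraint to
#' machine
#' precision without disturbing the support), and an unpenalized
#' least-squares beta-step. The path is traversed from the largest lambda
#' down with warm starts; the returned solution is the one chosen by the
#' information criterion in \code{penalty}. If every lambda yields an
#' all-zero component, \code{d = 0} is returned.
#'
#' @param Yk deflated response (n x q).
#' @param Xtilde aggregated design (n x P).
#' @param Z covariate matrix (n x m) with leading intercept column.
#' @param cvec constraint vector.
#' @param weights an \code{AdaptiveWeights} object.
#' @param penalty a [penaltySpec()].
#' @param tol relative objective-change tolerance of the block iteration.
#' @param maxIter maximum block iterations per lambda.
#' @param gram optional precomputed \code{crossprod(Xtilde)}.
#' @return list with \code{beta}, \code{component} (list \code{d}, \code{u},
#'   \code{v}), and \code{diagnostics} (path table, chosen index, convergence
#'   flags, objective trace of the chosen fit).
#' @export
fitUnitRank <- function(Yk, Xtilde, Z, cvec, weights, penalty = penaltySpec(),
                    tol = 1e-4, maxIter = 200, gram = NULL) {
  stopifnot(inherits(weights, "AdaptiveWeights"))
  n <- nrow(Yk)
  q <- ncol(Yk)
  P <- ncol(Xtilde)
  if (max(abs(cvec)) == 0) stop("constraint vector must be nonzero")
  alpha <- penalty$elasticAlpha
  wU <- weights$wU
  wV <- weights$wV
  if (is.null(gram)) gram <- crossprod(Xtilde)
  qrZ <- qr(Z)
  beta0 <- qr.coef(qrZ, Yk)
  R0 <- Yk - Z %*% beta0

  u0 <- weights$uInit
  v0 <- weights$vInit
  grid <- penalty$lambdaGrid
  if (is.null(grid)) {
    aU0 <- sum(wU * abs(u0))
    aV0 <- sum(wV * abs(v0))
    # KKT bound for the smallest lambda giving a fully zero component at the
    # initialization direction
    s0 <- Xtilde %*% u0
    kktV <- max(abs(2 * crossprod(s0, R0))[1, ] / (alpha * aU0 * wV))
    kktU <- max(abs(2 * crossprod(Xtilde, R0 %*% v0)) / (alpha * aV0 * wU))
    lamMax <- max(kktV, kktU) * 1.0001
    if (!is.finite(lamMax) || lamMax <= 0) {
      return(list(beta = beta0,
                  component = list(d = 0, u = rep(0, P), v = rep(0, q)),
                  diagnostics = list(path = NULL, chosen = NA_integer_,
                                     converged = logical(0))))
    }
    grid <- exp(seq(log(lamMax), log(lamMax * penalty$lambdaMinRatio),
                    length.out = penalty$nLambda))
  }

  fits <- vector("list", length(grid))
  sse <- df <- numeric(length(grid))
  converged <- logical(length(grid))
  state <- list(u = u0, v = v0, d = 0, beta = beta0)
  ymultState <- 0

  for (li in seq_along(grid)) {
    lambda <- grid[li]
    u <- state$u
    v <- state$v
    d <- state$d
    beta <- state$beta
    if (sum(abs(u)) == 0 || sum(abs(v)) == 0) {
      u <- u0
      v <- v0
      d <- 0
    }
    objTrace <- numeric(0)
    obj <- Inf
    conv <- FALSE
    ymult <- if (li > 1) ymultState else 0
    for (it in seq_len(maxIter)) {
      Yres <- Yk - Z %*% beta
      # v-step: closed-form weighted elastic net on the single predictor Xu
      aU <- sum(wU * abs(u))
      bU <- sum(wU * u^2)
      s <- Xtilde %*% u
      ssq <- sum(s^2)
      sy <- crossprod(s, Yres)[1, ]
      vt <- .soft(2 * sy, lambda * alpha * aU * wV) /
        (2 * ssq + lambda * (1 - alpha) * bU * wV)
      if (all(vt == 0)) {
        d <- 0
        conv <- TRUE
        break
      }
      dv <- sqrt(sum(vt^2))
      v <- vt / dv
      # u-step: constrained coordinate descent on the unnormalized vector
      aV <- sum(wV * abs(v))
      bV <- sum(wV * v^2)
      g <- crossprod(Xtilde, Yres %*% v)[, 1]
      lam1 <- lambda * alpha * aV * wU
      lam2 <- lambda * (1 - alpha) * bV * wU / 2
      sol <- .cdConstrainedEnet(gram, g, cvec, lam1, lam2, u * d, ymult)
      ymult <- sol$ymult
      ut <- .projectSupport(as.numeric(sol$u), cvec)
      if (all(ut == 0)) {
        d <- 0
        conv <- TRUE
        break
      }
      d <- sqrt(sum(ut^2))
      u <- ut / d
      # beta-step: unpenalized least squares on the residual
      fitted <- (Xtilde %*% u) %*% t(v) * d
      beta <- qr.coef(qrZ, Yk - fitted)
      res <- Yk - fitted - Z %*% beta
      sseCur <- sum(res^2)
      objNew <- .ureObjective(sseCur, d, u, v, lambda, alpha, wU, wV)
      objTrace <- c(objTrace, objNew)
      if (is.finite(obj) && abs(obj - objNew) <= tol * (abs(obj) + 1e-12)) {
        obj <- objNew
        conv <- TRUE
        break
      }
      obj <- objNew
    }
    if (d == 0) {
      beta <- beta0
      u <- rep(0, P)
      v <- rep(0, q)
      sse[li] <- sum(R0^2)
      df[li] <- 0
    } else {
      if (v[which.max(abs(v))] < 0) {
        v <- -v
        u <- -u
      }
      fitted <- (Xtilde %*% u) %*% t(v) * d
      sse[li] <- sum((Yk - fitted - Z %*% beta)^2)
      df[li] <- sum(u != 0) + sum(v != 0) - 1
    }
    converged[li] <- conv
    fits[[li]] <- list(d = d, u = u, v = v, beta = beta, objTrace = objTrace)
    state <- list(u = u, v = v, d = d, beta = beta)
    ymultState <- ymult
  }

  path <- data.frame(lambda = grid, sse = sse, df = df)
  chosen <- selectLambda(path, n, q, P, penalty$criterion)
  best <- fits[[chosen]]
  list(beta = best$beta,
       component = list(d = best$d, u = best$u, v = best$v),
       diagnostics = list(path = path, chosen = chosen,
                          lambda = grid[chosen],
                          converged = converged,
                          objTrace = best$objTrace))
}

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Sequential sparse factor regression on an aggregated design
#'
#' Extracts sparse unit-rank components one at a time: initialize from a
#' ridge-stabilized reduced-rank estimate of the deflated response, form
#' adaptive weights, solve the penalized unit-rank problem along a lambda
#' path, keep the criterion-selected solution, deflate the response, and
#' repeat until a zero singular value is detected or \code{maxRank}
#' components have been extracted. The covariate coefficients are refit
#' jointly by least squares after extraction (per-step estimates are kept in
#' the diagnostics). Columns of the design and the response are mean-centered
#' internally; reported coefficients are on the original scale.
#'
#' @param Y response matrix (n x q).
#' @param Xtilde aggregated design (n x P), e.g. from [aggregateFeatures()].
#' @param Z covariate matrix with leading intercept column, or NULL for
#'   intercept only.
#' @param cvec constraint vector from [constraintVector()].
#' @param maxRank maximum number of components to extract.
#' @param penalty a [penaltySpec()].
#' @param tol,maxIter block-relaxation controls per lambda.
#' @param initRidge ridge stabilizer of the initialization.
#' @return a \linkS4class{TreeFarFit} (leaf-level \code{Chat} is filled by
#'   [assembleC()]).
#' @export
fitSequentialFactors <- function(Y, Xtilde, Z = NULL, cvec, maxRank = 3,
                                 penalty = penaltySpec(), tol = 1e-4,
                                 maxIter = 200, initRidge = 1e-2) {
  stopifnot(maxRank >= 1, nrow(Y) == nrow(Xtilde))
  n <- nrow(Y)
  q <- ncol(Y)
  if (is.null(Z)) {
    Z <- matrix(1, n, 1, dimnames = list(rownames(Y), "(Intercept)"))
  }
  if (any(Z[, 1] != 1)) stop("first column of Z must be the intercept 1")
  if (length(cvec) != ncol(Xtilde)) {
    stop("constraint vector length must match ncol(Xtilde)")
  }

  # drop constant aggregated columns (zero variance): they cannot carry
  # signal and break the penalized updates
  sds <- apply(Xtilde, 2, stats::sd)
  keep <- sds > 0
  dropped <- which(!keep)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped),
            " constant aggregated feature column(s): ",
            paste(colnames(Xtilde)[dropped], collapse = ", "))
  }
  Xk <- Xtilde[, keep, drop = FALSE]
  ck <- cvec[keep]
  Pfull <- ncol(Xtilde)

  # internal centering; intercept is restored on the original scale below
  xbar <- colMeans(Xk)
  ybar <- colMeans(Y)
  Xc <- sweep(Xk, 2, xbar)
  Yc <- sweep(Y, 2, ybar)
  Zc <- Z
  zbar <- rep(0, ncol(Z))
  if (ncol(Z) > 1) {
    zbar[-1] <- colMeans(Z[, -1, drop = FALSE])
    Zc[, -1] <- sweep(Z[, -1, drop = FALSE], 2, zbar[-1])
  }
  gram <- crossprod(Xc)
  qrZc <- qr(Zc)

  comps <- list()
  betaSteps <- list()
  compDiag <- list()
  GammaCum <- matrix(0, ncol(Xc), q)
  for (k in seq_len(maxRank)) {
    Yk <- Yc - Xc %*% GammaCum
    YkResid <- Yk - Zc %*% qr.coef(qrZc, Yk)
    init <- initialUnitRank(YkResid, Xc, ck, ridgeEps = initRidge,
                            gram = gram)
    if (init$d <= 0) break
    w <- adaptiveWeights(init, gamma = penalty$adaptiveGamma)
    ure <- tryCatch(
      fitUnitRank(Yk, Xc, Zc, ck, w, penalty, tol = tol, maxIter = maxIter,
              gram = gram),
      error = function(e) stop("component ", k, ": ", conditionMessage(e)))
    if (ure$component$d <= 0) break
    comps[[k]] <- ure$component
    betaSteps[[k]] <- ure$beta
    compDiag[[k]] <- ure$diagnostics
    GammaCum <- GammaCum + ure$component$d *
      tcrossprod(ure$component$u, ure$component$v)
  }

  r <- length(comps)
  U <- matrix(0, Pfull, r, dimnames = list(colnames(Xtilde), NULL))
  V <- matrix(0, q, r, dimnames = list(colnames(Y), NULL))
  d <- numeric(r)
  for (k in seq_len(r)) {
    U[keep, k] <- comps[[k]]$u
    V[, k] <- comps[[k]]$v
    d[k] <- comps[[k]]$d
  }

  # joint refit of the covariate effects given all extracted components
  betac <- qr.coef(qrZc, Yc - Xc %*% GammaCum)
  beta <- betac
  beta[1, ] <- betac[1, ] + ybar - drop(crossprod(GammaCum, xbar))
  if (ncol(Z) > 1) {
    beta[1, ] <- beta[1, ] - drop(crossprod(betac[-1, , drop = FALSE],
                                            zbar[-1]))
  }
  dimnames(beta) <- list(colnames(Z), colnames(Y))

  new("TreeFarFit", beta = beta, d = d, U = U, V = V,
      Chat = matrix(numeric(0), 0, 0), cvec = as.numeric(cvec),
      diagnostics = list(components = compDiag, betaSteps = betaSteps,
                         droppedColumns = dropped, n = n,
                         maxRank = maxRank, penalty = penalty))
}

#' @rdname assembleC
setMethod("assembleC", signature("TreeFarFit", "AncestryMatrix"),
  function(object, A) {
    Gamma <- coefGamma(object)
    if (nrow(Gamma) != ncol(A@a)) stop("fit and ancestry dimensions differ")
    object@Chat <- A@a %*% Gamma
    rownames(object@Chat) <- A@leafIds
    validObject(object)
    object
  })

#' @rdname assembleC
setMethod("assembleC", signature("CrrrFit", "AncestryMatrix"),
  function(object, A) {
    if (nrow(object@Gamma) != ncol(A@a)) {
      stop("fit and ancestry dimensions differ")
    }
    object@Chat <- A@a %*% object@Gamma
    rownames(object@Chat) <- A@leafIds
    validObject(object)
    object
  })

#' Tree-aggregated sparse factor regression (end-to-end)
#'
#' Full pipeline: total-sum-scaling log transform of the counts, taxonomic
#' tree construction, ancestry-matrix expansion of the design, sequential
#' sparse unit-rank extraction under the compositional zero-sum constraint,
#' and assembly of the leaf-level coefficient matrix \code{C = A Gamma}.
#'
#' @param counts samples-by-features count matrix (see [validateCounts()]).
#' @param taxonomy an \code{ape} \code{phylo} whose tips are the count
#'   features, or a named lineage list/vector accepted by
#'   [treeFromLineages()].
#' @param y response matrix (samples in rows).
#' @param z optional covariate matrix with leading intercept column.
#' @param pseudocount pseudocount of the log transform.
#' @param maxRank maximum number of latent factors.
#' @param penalty a [penaltySpec()].
#' @param ... passed to [fitSequentialFactors()].
#' @return a \linkS4class{TreeFarFit} with \code{Chat} assembled; the
#'   ancestry matrix and aggregated design are attached to the diagnostics.
#' @export
treeFar <- function(counts, taxonomy, y, z = NULL, pseudocount = 1,
                    maxRank = 3, penalty = penaltySpec(), ...) {
  tree <- if (is(taxonomy, "phylo")) .tidyTree(taxonomy)
          else treeFromLineages(taxonomy)
  if (!setequal(tree$tip.label, colnames(counts))) {
    stop("taxonomy leaves must match the count table features")
  }
  x <- tssLogTransform(counts, pseudocount)
  al <- alignTables(x, y, z)
  A <- buildAncestryMatrix(tree, leafOrder = colnames(counts))
  Xt <- aggregateFeatures(al$x, A)
  cv <- constraintVector(A)
  fit <- fitSequentialFactors(al$y, Xt, al$z, cv, maxRank = maxRank,
                              penalty = penalty, ...)
  fit <- assembleC(fit, A)
  fit@diagnostics$ancestry <- A
  fit@diagnostics$Xtilde <- Xt
  fit@diagnostics$pseudocount <- pseudocount
  fit
}

#' Predicted responses from a fitted model
#'
#' \code{Yhat = Z beta + Xtilde Gamma} on the aggregated design.
#'
#' @param object a \linkS4class{TreeFarFit} or \linkS4class{CrrrFit}.
#' @param Xtilde aggregated design to predict on.
#' @param Z covariate matrix (intercept first); intercept-only if NULL.
#' @return matrix of fitted responses.
#' @export
predictResponse <- function(object, Xtilde, Z = NULL) {
  if (is.null(Z)) Z <- matrix(1, nrow(Xtilde), 1)
  Z %*% object@beta + Xtilde %*% coefGamma(object)
}
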