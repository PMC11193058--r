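# shared fixtures and independent oracles, all built in code

# two genera over three leaves; the unary node over s3 collapses
smallTree3 <- function() {
  treeFromLineages(list(s1 = "g1", s2 = "g1", s3 = "g2"))
}

# balanced two-genus tree over four leaves
balancedTree4 <- function() {
  treeFromLineages(list(l1 = "a", l2 = "a", l3 = "b", l4 = "b"))
}

# eight leaves under three internal nodes (plus root): aggregated dimension 11
oracleTree <- function() {
  treeFromLineages(list(
    l1 = "gA", l2 = "gA", l3 = "gA",
    l4 = "gB", l5 = "gB", l6 = "gB",
    l7 = "gC", l8 = "gC"))
}

# draw a unit-norm vector on a given support satisfying sum(cvec * u) = 0;
# entries are redrawn until all support entries are bounded away from zero,
# so the support is recoverable in principle
randomConstrainedU <- function(P, support, cvec, minEntry = 0.15) {
  repeat {
    u <- rep(0, P)
    u[support] <- stats::runif(length(support), 0.5, 1) *
      sample(c(-1, 1), length(support), replace = TRUE)
    cs <- cvec[support]
    u[support] <- u[support] - cs * sum(cs * u[support]) / sum(cs^2)
    nrm <- sqrt(sum(u^2))
    if (nrm > 1e-8 && min(abs(u[support] / nrm)) >= minEntry) {
      return(u / nrm)
    }
  }
}

# small full-rank regression instance with a rank-1 constrained truth;
# Xtilde is a generic design (no aggregation structure), cvec mixes weights
makeRank1Instance <- function(seed, n = 60, P = 10, q = 4, sigma = 0,
                              dTrue = 3) {
  set.seed(seed)
  Xt <- matrix(rnorm(n * P), n, P)
  cvec <- c(rep(1, P - 2), 2, 2)
  u <- randomConstrainedU(P, sample(P, 4), cvec)
  v <- stats::runif(q, 0.5, 1) * sample(c(-1, 1), q, replace = TRUE)
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) {
    v <- -v
    u <- -u
  }
  Z <- matrix(1, n, 1)
  beta <- matrix(rnorm(q), 1, q)
  Y <- Z %*% beta + dTrue * (Xt %*% u) %*% t(v) +
    sigma * matrix(rnorm(n * q), n, q)
  list(Y = Y, Xt = Xt, Z = Z, cvec = cvec, u = u, v = v, d = dTrue,
       beta = beta)
}

# aggregated-instance generator on the 8-leaf tree (rank-deficient design,
# as aggregation always is)
makeAggregatedInstance <- function(seed, n = 60, q = 4, rank = 2,
                                   dTrue = c(3, 2), sigma = 0.2) {
  set.seed(seed)
  tree <- oracleTree()
  leafs <- tree$tip.label
  X <- matrix(rnorm(n * length(leafs)), n,
              dimnames = list(NULL, leafs))
  A <- buildAncestryMatrix(tree, leafOrder = leafs)
  Xt <- aggregateFeatures(X, A)
  cvec <- constraintVector(A)
  P <- ncol(Xt)
  U <- sapply(seq_len(rank), function(k) {
    randomConstrainedU(P, sample(P, 3), cvec)
  })
  V <- qr.Q(qr(matrix(rnorm(q * rank), q, rank)))
  Gamma <- U %*% (dTrue * t(V))
  Z <- matrix(1, n, 1)
  beta <- matrix(rnorm(q), 1, q)
  Y <- Z %*% beta + Xt %*% Gamma + sigma * matrix(rnorm(n * q), n, q)
  list(Y = Y, X = X, Xt = Xt, Z = Z, A = A, cvec = cvec, Gamma = Gamma,
       U = U, V = V, d = dTrue, beta = beta)
}

# full penalized objective of the unit-rank problem, beta profiled out by
# least squares; gamma-matrix parameterization makes it scale-invariant
ureObjectiveFull <- function(uraw, vraw, Yk, Xt, Z, lambda, alpha, wU, wV) {
  Gam <- tcrossprod(uraw, vraw)
  fitted <- Xt %*% Gam
  beta <- qr.coef(qr(Z), Yk - fitted)
  res <- Yk - fitted - Z %*% beta
  Wmat <- wU %o% wV
  sum(res^2) + lambda * (alpha * sum(Wmat * abs(Gam)) +
    (1 - alpha) / 2 * sum(Wmat * Gam^2))
}

# independent brute-force solver of the constrained penalized unit-rank
# problem: multi-start Nelder-Mead over the null-space parameterization
# u = N w (constraint exact by construction)
bruteForceUnitRank <- function(Yk, Xt, Z, cvec, lambda, alpha, wU, wV,
                               nStarts = 8, seed = 1, startAt = NULL) {
  N <- qr.Q(qr(cbind(cvec)), complete = TRUE)[, -1, drop = FALSE]
  q <- ncol(Yk)
  obj <- function(theta) {
    w <- theta[seq_len(ncol(N))]
    vraw <- theta[-seq_len(ncol(N))]
    ureObjectiveFull(N %*% w, vraw, Yk, Xt, Z, lambda, alpha, wU, wV)
  }
  set.seed(seed)
  best <- Inf
  starts <- lapply(seq_len(nStarts), function(i) {
    rnorm(ncol(N) + q) * 0.5
  })
  if (!is.null(startAt)) starts <- c(list(startAt), starts)
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-12))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# write a matrix to a temporary TSV and return the path
tmpTsv <- function(x, idColumn = "id") {
  f <- tempfile(fileext = ".tsv")
  writeTsvMatrix(x, f, idColumn = idColumn)
  f
}
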