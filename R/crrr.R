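#' Linear-constrained reduced-rank regression (dense baseline)
#'
#' Reduced-rank regression of Y on the aggregated design under the zero-sum
#' constraint but with no sparsity penalty. The covariates are projected out,
#' the coefficient matrix is reparameterized as \code{Gamma = N W} with
#' \code{N} an orthonormal basis of the null space of the constraint row (so the
#' constraint holds by construction), the ridge-stabilized full-rank solution
#' \code{W = solve(crossprod(M) + eps n I, crossprod(M, Y))} with
#' \code{M = Xtilde N} is computed,
#' and its fitted values are truncated to rank \code{rank} by SVD. The
#' estimate is dense: no entries are shrunk to exact zero, so against a
#' sparse truth this baseline has false positive rate 1 and false negative
#' rate 0 by construction.
#'
#' @param Y response matrix (n x q).
#' @param Xtilde aggregated design (n x P).
#' @param Z covariate matrix with leading intercept column, or NULL.
#' @param cvec constraint vector.
#' @param rank target rank (must not exceed \code{min(P - 1, q, n)}).
#' @param ridgeEps ridge stabilizer (default 1e-4), needed because the
#'   aggregated dimension typically exceeds n.
#' @return a \linkS4class{CrrrFit}.
#' @export
fitCrrr <- function(Y, Xtilde, Z = NULL, cvec, rank, ridgeEps = 1e-4) {
  stopifnot(nrow(Y) == nrow(Xtilde), length(cvec) == ncol(Xtilde))
  n <- nrow(Y)
  q <- ncol(Y)
  P <- ncol(Xtilde)
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(P - 1, q, n)) {
    stop("rank must be between 1 and min(P - 1, q, n)")
  }
  if (is.null(Z)) {
    Z <- matrix(1, n, 1, dimnames = list(rownames(Y), "(Intercept)"))
  }
  if (any(Z[, 1] != 1)) stop("first column of Z must be the intercept 1")

  xbar <- colMeans(Xtilde)
  ybar <- colMeans(Y)
  Xc <- sweep(Xtilde, 2, xbar)
  Yc <- sweep(Y, 2, ybar)
  Zc <- Z
  zbar <- rep(0, ncol(Z))
  if (ncol(Z) > 1) {
    zbar[-1] <- colMeans(Z[, -1, drop = FALSE])
    Zc[, -1] <- sweep(Z[, -1, drop = FALSE], 2, zbar[-1])
  }
  qrZc <- qr(Zc)
  Ystar <- Yc - Zc %*% qr.coef(qrZc, Yc)
  Xstar <- Xc - Zc %*% qr.coef(qrZc, Xc)

  # orthonormal null-space basis of the constraint row
  N <- qr.Q(qr(cbind(cvec)), complete = TRUE)[, -1, drop = FALSE]
  M <- Xstar %*% N
  Wfull <- solve(crossprod(M) + diag(ridgeEps * n, ncol(M)),
                 crossprod(M, Ystar))
  Fhat <- M %*% Wfull
  sv <- svd(Fhat, nu = 0, nv = rank)
  Vr <- sv$v[, seq_len(rank), drop = FALSE]
  Wr <- Wfull %*% Vr %*% t(Vr)
  Gamma <- N %*% Wr
  dimnames(Gamma) <- list(colnames(Xtilde), colnames(Y))

  betac <- qr.coef(qrZc, Yc - Xc %*% Gamma)
  beta <- betac
  beta[1, ] <- betac[1, ] + ybar - drop(crossprod(Gamma, xbar))
  if (ncol(Z) > 1) {
    beta[1, ] <- beta[1, ] - drop(crossprod(betac[-1, , drop = FALSE],
                                            zbar[-1]))
  }
  dimnames(beta) <- list(colnames(Z), colnames(Y))

  svG <- svd(Gamma, nu = rank, nv = rank)
  U <- svG$u
  V <- svG$v
  for (k in seq_len(rank)) {
    if (V[which.max(abs(V[, k])), k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  rownames(U) <- colnames(Xtilde)
  rownames(V) <- colnames(Y)

  new("CrrrFit", beta = beta, Gamma = Gamma, d = svG$d[seq_len(rank)],
      U = U, V = V, Chat = matrix(numeric(0), 0, 0),
      cvec = as.numeric(cvec), rank = rank)
}
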