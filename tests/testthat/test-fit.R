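test_that("ridge initialization recovers a noiseless constrained triple", {
  inst <- makeRank1Instance(seed = 1, sigma = 0)
  Yres <- inst$Y - matrix(colMeans(inst$Y), nrow(inst$Y), ncol(inst$Y),
                          byrow = TRUE)
  Xc <- scale(inst$Xt, scale = FALSE)
  init <- initialUnitRank(Yres, Xc, inst$cvec, ridgeEps = 1e-8)
  flip <- sign(sum(init$u * inst$u))
  expect_lt(max(abs(flip * init$u - inst$u)), 1e-6)
  expect_lt(max(abs(flip * init$v - inst$v)), 1e-6)
  expect_equal(init$d, inst$d, tolerance = 1e-6)
  # sign convention: the dominant entry of v is positive
  expect_gt(init$v[which.max(abs(init$v))], 0)
  # zero response signals termination
  init0 <- initialUnitRank(matrix(0, 60, 4), Xc, inst$cvec)
  expect_equal(init0$d, 0)
})

test_that("adaptive weights follow the reciprocal-magnitude construction", {
  init <- list(d = 1, u = c(0.8, 0.6, 0), v = c(1, 0))
  w0 <- adaptiveWeights(init, gamma = 0)
  expect_equal(w0$wU, rep(1, 3))
  expect_equal(w0$wV, rep(1, 2))
  w1 <- adaptiveWeights(init, gamma = 1)
  expect_equal(w1$wU[1:2], c(1.25, 5 / 3), tolerance = 1e-6)
  w2 <- adaptiveWeights(init, gamma = 2)
  expect_equal(w2$wU[3], 1e8)  # zero entry hits the cap: excluded
  expect_error(adaptiveWeights(list(d = 0, u = 0, v = 0)), "nonzero")
})

test_that("a large enough penalty shrinks the component to zero", {
  inst <- makeRank1Instance(seed = 2, sigma = 0.3)
  init <- initialUnitRank(inst$Y, inst$Xt, inst$cvec)
  w <- adaptiveWeights(init)
  fit <- fitUnitRank(inst$Y, inst$Xt, inst$Z, inst$cvec, w,
                 penaltySpec(lambdaGrid = 1e9))
  expect_equal(fit$component$d, 0)
  expect_true(all(fit$component$u == 0))
  expect_true(all(fit$component$v == 0))
  # beta falls back to plain least squares of Y on Z
  expect_equal(fit$beta, qr.coef(qr(inst$Z), inst$Y), tolerance = 1e-10)
})

test_that("noiseless rank-1 truth is recovered in the unpenalized limit", {
  inst <- makeRank1Instance(seed = 3, sigma = 0)
  init <- initialUnitRank(inst$Y - matrix(colMeans(inst$Y), 60, 4,
                                          byrow = TRUE),
                          scale(inst$Xt, scale = FALSE), inst$cvec)
  w <- adaptiveWeights(init)
  fit <- fitUnitRank(inst$Y, inst$Xt, inst$Z, inst$cvec, w,
                 penaltySpec(lambdaGrid = 1e-10),
                 tol = 1e-12, maxIter = 2000)
  cmp <- fit$component
  flip <- sign(sum(cmp$u * inst$u))
  expect_lt(max(abs(flip * cmp$u - inst$u)) / max(abs(inst$u)), 1e-4)
  expect_lt(max(abs(flip * cmp$v - inst$v)) / max(abs(inst$v)), 1e-4)
  expect_equal(cmp$d, inst$d, tolerance = 1e-4)
  expect_equal(fit$beta, inst$beta, tolerance = 1e-3)
  expect_lt(abs(sum(inst$cvec * cmp$u)), 1e-8)
  expect_equal(sum(cmp$u^2), 1, tolerance = 1e-10)
  expect_equal(sum(cmp$v^2), 1, tolerance = 1e-10)
})

test_that("block relaxation never increases the penalized objective", {
  inst <- makeRank1Instance(seed = 4, sigma = 0.5)
  init <- initialUnitRank(inst$Y, inst$Xt, inst$cvec)
  w <- adaptiveWeights(init)
  fit <- fitUnitRank(inst$Y, inst$Xt, inst$Z, inst$cvec, w,
                 penaltySpec(nLambda = 12))
  tr <- fit$diagnostics$objTrace
  if (length(tr) > 1) {
    expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
  expect_true(any(fit$diagnostics$converged))
})

test_that("solver objective matches a brute-force multi-start optimizer", {
  # small dense instance: p = 3 leaves (identity aggregation), q = 2, n = 40
  set.seed(7)
  n <- 40
  Xt <- matrix(rnorm(n * 3), n, 3)
  cvec <- rep(1, 3)
  u <- c(1, -1, 0) / sqrt(2)
  v <- c(0.8, 0.6)
  Z <- matrix(1, n, 1)
  Y <- 2 * (Xt %*% u) %*% t(v) + 0.4 * matrix(rnorm(n * 2), n, 2)
  init <- initialUnitRank(Y, Xt, cvec)
  w <- adaptiveWeights(init)
  for (lambda in c(0.5, 5)) {
    fit <- fitUnitRank(Y, Xt, Z, cvec, w,
                   penaltySpec(lambdaGrid = lambda, elasticAlpha = 0.95),
                   tol = 1e-12, maxIter = 5000)
    cmp <- fit$component
    ours <- ureObjectiveFull(cmp$d * cmp$u, cmp$v, Y, Xt, Z, lambda, 0.95,
                             w$wU, w$wV)
    oracle <- bruteForceUnitRank(Y, Xt, Z, cvec, lambda, 0.95, w$wU, w$wV,
                                 nStarts = 10, seed = 11)
    expect_lte(ours, oracle + 1e-6)
  }
})

test_that("information criterion selection breaks ties toward sparsity", {
  path <- data.frame(lambda = c(2, 1), sse = c(10, 10), df = c(2, 2))
  expect_equal(selectLambda(path, n = 20, q = 3, P = 5), 1L)
  single <- data.frame(lambda = 1, sse = 5, df = 3)
  expect_equal(selectLambda(single, n = 20, q = 3, P = 5), 1L)
  expect_error(selectLambda(single[0, ], n = 20, q = 3, P = 5), "empty")
  # a strictly better fit at equal df wins
  path2 <- data.frame(lambda = c(2, 1), sse = c(10, 8), df = c(2, 2))
  expect_equal(selectLambda(path2, n = 20, q = 3, P = 5), 2L)
})

test_that("criterion-tuned fits recover a recoverable rank-1 support", {
  hits <- 0L
  for (seed in 1:10) {
    inst <- makeRank1Instance(seed = 100 + seed, n = 80, P = 12, q = 4,
                              sigma = 0.15)
    fit <- fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec,
                                maxRank = 1)
    if (estimatedRank(fit) == 1 &&
        identical(which(leftVectors(fit)[, 1] != 0), which(inst$u != 0)) &&
        identical(which(rightVectors(fit)[, 1] != 0), which(inst$v != 0))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("sequential extraction is consistent and terminates on rank", {
  inst <- makeAggregatedInstance(seed = 5, n = 120, q = 6, rank = 2,
                                 dTrue = c(3, 2), sigma = 0.3)
  fit2 <- fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec,
                               maxRank = 4)
  expect_equal(estimatedRank(fit2), 2L)
  fit1 <- fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec,
                               maxRank = 1)
  expect_equal(leftVectors(fit1)[, 1], leftVectors(fit2)[, 1],
               tolerance = 1e-12)
  expect_equal(singularValues(fit1)[1], singularValues(fit2)[1],
               tolerance = 1e-12)

  # pure noise with nothing to find yields the null model
  set.seed(77)
  Ynoise <- matrix(rnorm(120 * 6), 120, 6)
  fit0 <- fitSequentialFactors(Ynoise, inst$Xt, inst$Z, inst$cvec,
                               maxRank = 3)
  expect_equal(estimatedRank(fit0), 0L)
  expect_equal(fit0@beta, qr.coef(qr(inst$Z), Ynoise), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("fitted components satisfy constraint, normalization and signs", {
  inst <- makeAggregatedInstance(seed = 6, rank = 2, sigma = 0.2)
  fit <- assembleC(fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec,
                                        maxRank = 3), inst$A)
  r <- estimatedRank(fit)
  expect_gte(r, 1L)
  U <- leftVectors(fit)
  V <- rightVectors(fit)
  for (k in seq_len(r)) {
    expect_lt(abs(sum(inst$cvec * U[, k])), 1e-8)
    expect_equal(sum(U[, k]^2), 1, tolerance = 1e-10)
    expect_equal(sum(V[, k]^2), 1, tolerance = 1e-10)
    expect_gt(V[which.max(abs(V[, k])), k], 0)
  }
  expect_lt(max(abs(colSums(coefC(fit)))), 1e-8)

  # component-wise reconstruction equals the assembled coefficient matrix
  GammaSum <- Reduce(`+`, lapply(seq_len(r), function(k) {
    singularValues(fit)[k] * tcrossprod(U[, k], V[, k])
  }))
  expect_equal(unname(coefGamma(fit)), unname(GammaSum), tolerance = 1e-12)
  # residual telescoping on the original scale
  res <- inst$Y - predictResponse(fit, inst$Xt, inst$Z)
  resByComp <- inst$Y - inst$Z %*% fit@beta - inst$Xt %*% GammaSum
  expect_equal(res, resByComp, tolerance = 1e-12)
})

test_that("constant aggregated columns are dropped and zero-padded back", {
  inst <- makeRank1Instance(seed = 8, sigma = 0.2)
  XtC <- cbind(inst$Xt, const = 5)
  cv <- c(inst$cvec, 1)
  expect_warning(
    fit <- fitSequentialFactors(inst$Y, XtC, inst$Z, cv, maxRank = 1),
    "constant")
  expect_equal(nrow(leftVectors(fit)), ncol(XtC))
  expect_equal(unname(leftVectors(fit)[ncol(XtC), ]), 0)
})

test_that("unpenalized sequential fit matches constrained reduced-rank
           regression", {
  for (seed in 1:3) {
    inst <- makeRank1Instance(seed = 30 + seed, n = 50, P = 8, q = 4,
                              sigma = 0.3)
    fit <- fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec,
                                maxRank = 2,
                                penalty = penaltySpec(lambdaGrid = 1e-10),
                                tol = 1e-12, maxIter = 5000)
    crrr <- fitCrrr(inst$Y, inst$Xt, inst$Z, inst$cvec, rank = 2,
                    ridgeEps = 1e-12)
    expect_lt(sqrt(sum((coefGamma(fit) - coefGamma(crrr))^2)), 1e-6)
  }
})
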