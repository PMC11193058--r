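test_that("factor scores relate microbiome and response sides linearly", {
  inst <- makeAggregatedInstance(seed = 51, rank = 1, dTrue = 4, sigma = 0.05)
  fit <- fitSequentialFactors(inst$Y, inst$Xt, inst$Z, inst$cvec, maxRank = 2)
  expect_gte(estimatedRank(fit), 1)
  fs <- factorScores(fit, inst$Xt, inst$Y)
  expect_gte(abs(stats::cor(fs$scores[, 1], fs$responseScores[, 1])), 0.99)

  # a single-nonzero left vector copies (scales) one design column
  fit1 <- fit
  fit1@U[, 1] <- 0
  fit1@U[3, 1] <- 1
  fs1 <- factorScores(fit1, inst$Xt, inst$Y)
  expect_equal(unname(fs1$scores[, 1]), unname(inst$Xt[, 3]))

  # permuting samples permutes score rows identically
  perm <- sample(nrow(inst$Xt))
  fsP <- factorScores(fit, inst$Xt[perm, ], inst$Y[perm, ])
  expect_equal(unname(fsP$scores), unname(fs$scores[perm, , drop = FALSE]))

  fit0 <- fit
  fit0@U <- fit0@U[, 0, drop = FALSE]
  fit0@V <- fit0@V[, 0, drop = FALSE]
  fit0@d <- numeric(0)
  expect_error(factorScores(fit0, inst$Xt, inst$Y), "rank 0")
})

test_that("nonzero loadings annotate internal nodes with descendants", {
  A <- buildAncestryMatrix(smallTree3(), leafOrder = c("s1", "s2", "s3"))
  cvec <- constraintVector(A)
  u <- c(0.5, 0.5, 0, -0.5)          # s1, s2 leaves and node g1
  u <- u - cvec * sum(cvec * u) / sum(cvec^2)
  u <- u / sqrt(sum(u^2))
  v <- c(1, 0, 0)
  fit <- new("TreeFarFit", beta = matrix(0, 1, 3), d = 2,
             U = cbind(u), V = cbind(v), Chat = matrix(numeric(0), 0, 0),
             cvec = as.numeric(cvec), diagnostics = list())
  ld <- nonzeroLoadings(fit, A)
  gRow <- ld$u[ld$u$nodeId == "g1", ]
  expect_equal(nrow(gRow), 1)
  expect_false(gRow$isLeaf)
  expect_equal(gRow$descendants, "s1,s2")
  expect_equal(ld$v$responseId, "1")

  # zero fit yields empty listings; dense fit returns everything
  fit0 <- fit
  fit0@U[] <- 0
  fit0@V[] <- 0
  ld0 <- nonzeroLoadings(fit0, A)
  expect_equal(nrow(ld0$u), 0)
  expect_equal(nrow(ld0$v), 0)
})

test_that("phenotype association flags truly predictive factors", {
  set.seed(52)
  n <- 300
  S <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, paste0("factor", 1:3)))
  pheno <- as.numeric(S[, 1] > stats::median(S[, 1]))
  # add noise so the classes are not perfectly separable
  flip <- sample(n, 40)
  pheno[flip] <- 1 - pheno[flip]
  res <- scorePhenotypeAssociation(S, pheno)
  expect_true(res$flagged[res$factor == "factor1"])
  expect_equal(nrow(res), 3)
  expect_error(scorePhenotypeAssociation(S, rep(1, n)), "constant")
  expect_error(scorePhenotypeAssociation(S, rep(0.5, n)), "binary")
})

test_that("association test holds its size under the null", {
  set.seed(53)
  n <- 300
  hits <- 0L
  total <- 0L
  for (rep in 1:200) {
    S <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(NULL, c("factor1", "factor2")))
    pheno <- stats::rbinom(n, 1, 0.5)
    res <- scorePhenotypeAssociation(S, pheno)
    hits <- hits + sum(res$p.value < 0.05)
    total <- total + nrow(res)
  }
  expect_lt(abs(hits / total - 0.05), 0.03)
})

test_that("adjusters enter the association model", {
  set.seed(54)
  n <- 200
  age <- rnorm(n)
  S <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "factor1"))
  lin <- 2 * age
  pheno <- stats::rbinom(n, 1, stats::plogis(lin))
  adj <- cbind("(Intercept)" = 1, age = age)
  resAdj <- scorePhenotypeAssociation(S, pheno, adjusters = adj)
  expect_false(resAdj$flagged[1])
  resBH <- scorePhenotypeAssociation(S, pheno, adjusters = adj,
                                     adjustMethod = "BH")
  expect_gte(resBH$p.value[1], resAdj$p.value[1])
})
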