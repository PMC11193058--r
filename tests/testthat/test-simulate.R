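test_that("datasets are fully deterministic under a fixed seed", {
  des <- simulationDesign(n = 40, p = 20, q = 5, seed = 3, treeDepth = 3)
  d1 <- simulateDataset(des)
  d2 <- simulateDataset(des)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$truth$U, d2$truth$U)
  d3 <- simulateDataset(simulationDesign(n = 40, p = 20, q = 5, seed = 4,
                                         treeDepth = 3))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("simulated trees have exactly p leaves and vary with the seed", {
  for (p in c(4, 17, 60)) {
    tr <- simulateTree(p, seed = 5)
    expect_equal(length(tr$tip.label), p)
    expect_s3_class(tr, "phylo")
    # valid for downstream use
    A <- buildAncestryMatrix(tr)
    expect_equal(nrow(ancestry(A)), p)
  }
  t1 <- simulateTree(40, seed = 1)
  t2 <- simulateTree(40, seed = 2)
  expect_false(identical(t1$edge, t2$edge))
  expect_identical(simulateTree(40, seed = 1)$edge, t1$edge)
})

test_that("count surrogate produces zero-inflated realistic compositions", {
  des <- simulationDesign(seed = 9)  # default n = 300, p = 200
  cw <- simulateCounts(des)
  w <- cw$counts
  expect_true(all(w >= 0), all(w == round(w)))
  expect_true(all(rowSums(w) > 0))
  expect_gt(mean(w == 0), 0.3)
  # per-feature prevalence centers near the Beta mean a0 / (a0 + b0) = 0.3
  expect_lt(abs(mean(colMeans(w > 0)) - 0.3), 0.05)

  # degenerate limit: always-present features, no per-sample dispersion
  desDeg <- simulationDesign(n = 50, p = 20, seed = 2, zeroInflA = 1e6,
                             zeroInflB = 1e-3, sigma1 = 1e-8)
  wDeg <- simulateCounts(desDeg)$counts
  expect_lt(mean(wDeg == 0), 0.01)
  # composition is essentially fixed across samples
  props <- wDeg / rowSums(wDeg)
  expect_lt(max(apply(props, 2, stats::sd)), 0.01)
})

test_that("coefficient generator honors setting, constraint and spectrum", {
  des <- simulationDesign(n = 60, p = 40, q = 10, seed = 21, treeDepth = 4)
  dat <- simulateDataset(des)
  cvec <- dat$cvec
  U <- dat$truth$U
  expect_lt(max(abs(crossprod(cvec, U))), 1e-10)
  expect_lt(max(abs(colSums(dat$truth$C))), 1e-10)
  expect_equal(sqrt(colSums(U^2)), rep(1, 3), tolerance = 1e-10)
  expect_equal(svd(dat$truth$Gamma)$d[1:3], c(4, 3, 2), tolerance = 1e-8)

  # setting (d): support confined to internal-node columns
  desD <- simulationDesign(n = 60, p = 40, q = 10, seed = 22, treeDepth = 4,
                           setting = "d")
  datD <- simulateDataset(desD)
  supp <- which(rowSums(datD$truth$U != 0) > 0)
  expect_true(all(!datD$A@isLeaf[supp]))

  # setting (a): support confined to top-variance-quartile leaves
  vars <- apply(dat$x, 2, stats::var)
  eligible <- which(dat$A@isLeaf)[vars >= stats::quantile(vars, 0.75)]
  suppA <- which(rowSums(dat$truth$U != 0) > 0)
  expect_true(all(suppA %in% eligible))

  # setting (b): support confined to bottom-prevalence-quartile leaves
  desB <- simulationDesign(n = 60, p = 40, q = 10, seed = 23, treeDepth = 4,
                           setting = "b")
  datB <- simulateDataset(desB)
  prev <- colMeans(datB$counts > 0)
  eligibleB <- which(datB$A@isLeaf)[prev <= stats::quantile(prev, 0.25)]
  suppB <- which(rowSums(datB$truth$U != 0) > 0)
  expect_true(all(suppB %in% eligibleB))
})

test_that("responses achieve the requested signal-to-noise ratio exactly", {
  des <- simulationDesign(n = 50, p = 30, q = 8, seed = 31, treeDepth = 4)
  dat <- simulateDataset(des)
  r <- des@rank
  sr <- dat$truth$d[r] * sqrt(sum((dat$xtilde %*% dat$truth$U[, r])^2))
  expect_equal(sr / sqrt(sum(dat$E^2)), des@snr, tolerance = 1e-10)
  # the model identity holds exactly
  expect_lt(max(abs(dat$y - dat$z %*% dat$truth$beta -
                      dat$xtilde %*% dat$truth$Gamma - dat$E)), 1e-12)
  # halving the SNR doubles the (same-seed) error matrix
  desHalf <- simulationDesign(n = 50, p = 30, q = 8, seed = 31,
                              treeDepth = 4, snr = 0.25)
  datHalf <- simulateDataset(desHalf)
  expect_equal(datHalf$E, 2 * dat$E, tolerance = 1e-12)
  # near-noiseless limit
  desInf <- simulationDesign(n = 50, p = 30, q = 8, seed = 31,
                             treeDepth = 4, snr = 1e8)
  expect_lt(sqrt(sum(simulateDataset(desInf)$E^2)), 1e-4)
  # total-signal convention is available
  datTot <- simulateDataset(des, snrDef = "total")
  expect_equal(sqrt(sum((datTot$xtilde %*% datTot$truth$Gamma)^2)) /
                 sqrt(sum(datTot$E^2)), des@snr, tolerance = 1e-10)
})
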