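test_that("lineage trees merge shared prefixes and key nodes by full prefix", {
  tr <- smallTree3()
  expect_setequal(tr$tip.label, c("s1", "s2", "s3"))
  # g1 keeps two leaves; the unary node over s3 is collapsed
  expect_true("g1" %in% tr$node.label)
  expect_false("g2" %in% tr$node.label)

  # identical genus names under different families remain distinct
  tr2 <- treeFromLineages(list(s1 = "f1;g1", s2 = "f1;g1",
                               s3 = "f2;g1", s4 = "f2;g1"))
  expect_true(all(c("f1;g1", "f2;g1") %in% tr2$node.label))

  # all-unique single-rank lineages collapse to a star
  tr3 <- treeFromLineages(list(a = "gA", b = "gB", c = "gC"))
  expect_equal(tr3$Nnode, 1L)

  expect_error(treeFromLineages(list(a = character(0))), "non-empty")
  expect_error(treeFromLineages(stats::setNames(list("g1", "g1"),
                                                c("a", "a"))), "uniquely")
})

test_that("newick trees load equivalently and reject duplicate leaves", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((s1,s2)g1,(s3)g2)root;", f)
  A <- buildAncestryMatrix(treeFromNewick(f), leafOrder = c("s1", "s2", "s3"))
  expect_equal(unname(ancestry(A)),
               cbind(diag(3), c(1, 1, 0)))

  writeLines("(s1,s2,s3)root;", f)
  trStar <- treeFromNewick(f)
  expect_equal(trStar$Nnode, 1L)
  expect_equal(unname(ancestry(buildAncestryMatrix(trStar))), diag(3))

  writeLines("((s1,s1));", f)
  expect_error(treeFromNewick(f), "duplicate")
})

test_that("ancestry matrix has identity leaf block and descendant columns", {
  A3 <- buildAncestryMatrix(smallTree3(), leafOrder = c("s1", "s2", "s3"))
  expect_equal(dim(ancestry(A3)), c(3L, 4L))
  expect_equal(ancestry(A3)[, "g1"], c(s1 = 1, s2 = 1, s3 = 0))
  expect_equal(constraintVector(A3),
               c(s1 = 1, s2 = 1, s3 = 1, g1 = 2))

  A4 <- buildAncestryMatrix(balancedTree4())
  expect_equal(unname(colSums(ancestry(A4))), c(1, 1, 1, 1, 2, 2))
  expect_equal(unname(constraintVector(A4)), c(1, 1, 1, 1, 2, 2))

  # permuted leaf order permutes rows and the leaf block stays an identity
  Ap <- buildAncestryMatrix(balancedTree4(),
                            leafOrder = c("l3", "l1", "l4", "l2"))
  expect_equal(unname(ancestry(Ap)[, 1:4]), diag(4))
  expect_equal(sum(ancestry(Ap)[, "a"]), 2)
  expect_error(buildAncestryMatrix(balancedTree4(),
                                   leafOrder = c("l1", "l2")),
               "permutation")
})

test_that("nested-support and column-count invariants hold on random trees", {
  for (seed in c(2, 9)) {
    tr <- simulateTree(30, treeDepth = 4, seed = seed)
    expect_equal(length(tr$tip.label), 30L)
    A <- buildAncestryMatrix(tr)
    a <- ancestry(A)
    expect_true(all(a %in% c(0, 1)))
    expect_equal(unname(a[, seq_len(30)]), diag(30))
    intern <- which(!A@isLeaf)
    for (i in intern) {
      for (j in intern) {
        if (i == j) next
        overlap <- sum(a[, i] * a[, j])
        # tree columns are laminar: nested or disjoint
        expect_true(overlap == 0 || overlap == min(sum(a[, i]), sum(a[, j])))
      }
    }
  }
})

test_that("aggregation equals the matrix product and sums descendant leaves", {
  A3 <- buildAncestryMatrix(smallTree3(), leafOrder = c("s1", "s2", "s3"))
  X <- matrix(c(1, 2, 3), 1, 3, dimnames = list("s", c("s1", "s2", "s3")))
  expect_equal(unname(aggregateFeatures(X, A3)), matrix(c(1, 2, 3, 3), 1))

  set.seed(3)
  X4 <- matrix(rnorm(20), 5, 4,
               dimnames = list(NULL, c("l1", "l2", "l3", "l4")))
  A4 <- buildAncestryMatrix(balancedTree4())
  Xt <- aggregateFeatures(X4, A4)
  expect_equal(Xt[, "a"], X4[, "l1"] + X4[, "l2"])
  expect_equal(Xt[, "b"], X4[, "l3"] + X4[, "l4"])
  expect_equal(Xt[, 1:4], X4, ignore_attr = TRUE)

  expect_error(aggregateFeatures(X4[, c(2, 1, 3, 4)], A4), "order")

  # star tree: A = I and the constraint reduces to the classic zero sum
  trStar <- treeFromLineages(list(a = "gA", b = "gB", c = "gC"))
  Astar <- buildAncestryMatrix(trStar, leafOrder = c("a", "b", "c"))
  expect_equal(unname(ancestry(Astar)), diag(3))
  expect_equal(unname(constraintVector(Astar)), rep(1, 3))
})
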