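test_that("Kruskal tree weight matches exhaustive enumeration (N <= 6)", {
  for (i in 1:60) {
    n <- 3 + (i %% 4)                          # 3..6 nodes
    w <- randomWeightMatrix(n, seed = 1000 + i)
    tr <- maxSpanningTree(w)
    expect_equal(sum(treeEdges(tr)$weight), enumerateMaxTreeWeight(w),
                 tolerance = 1e-12)
    expect_equal(nrow(treeEdges(tr)), n - 1L)
  }
})

test_that("dominant hub rows give star trees; graded paths give path trees", {
  # hub: node 1 strongly connected to everyone, weak elsewhere
  w <- randomWeightMatrix(4, seed = 1) * 0.2
  w[1, 2:4] <- w[2:4, 1] <- c(0.9, 0.8, 0.85)
  tr <- maxSpanningTree(w)
  deg <- mstMetrics(tr)$degree
  expect_equal(unname(deg[c("ch01")]), 3)

  # weights strictly increasing along a path: consecutive edges dominate
  n <- 5
  w2 <- matrix(0.01, n, n); diag(w2) <- 0
  for (i in 1:(n - 1)) w2[i, i + 1] <- w2[i + 1, i] <- 0.5 + 0.1 * i
  dimnames(w2) <- list(sprintf("ch%02d", 1:n), sprintf("ch%02d", 1:n))
  tr2 <- maxSpanningTree(w2)
  m2 <- mstMetrics(tr2)
  expect_equal(m2$n_leaves, 2L)
  expect_equal(max(m2$degree), 2)

  # N = 2: the single edge
  w3 <- matrix(c(0, .4, .4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  tr3 <- maxSpanningTree(w3)
  expect_equal(nrow(treeEdges(tr3)), 1L)
  expect_true(is.na(mstMetrics(tr3)$bc_max))
})

test_that("star and path metrics match hand-computed values", {
  w <- matrix(0.1, 5, 5); w[1, 2:5] <- w[2:5, 1] <- 0.9; diag(w) <- 0
  dimnames(w) <- list(sprintf("ch%02d", 1:5), sprintf("ch%02d", 1:5))
  star <- mstMetrics(maxSpanningTree(w))
  expect_equal(star$n_leaves, 4L)
  expect_equal(star$leaf_fraction, 1)
  expect_equal(star$kmax, 1)
  expect_equal(star$bc_max, 1)               # centre of a star has BC 1
  expect_equal(star$diameter, 2 / 4)
  expect_equal(star$tree_hierarchy, 4 / (2 * 4 * 1))   # 0.5
  expect_equal(star$eccentricity_edges, mean(c(1, 2, 2, 2, 2)))

  n <- 5
  w2 <- matrix(0.01, n, n); diag(w2) <- 0
  for (i in 1:(n - 1)) w2[i, i + 1] <- w2[i + 1, i] <- 0.8
  dimnames(w2) <- list(sprintf("ch%02d", 1:n), sprintf("ch%02d", 1:n))
  path <- mstMetrics(maxSpanningTree(w2))
  expect_equal(path$leaf_fraction, 0.5)
  expect_equal(path$diameter, 1)
  expect_equal(path$kmax, 0.5)
})

test_that("leaves always have zero betweenness and the Th identity holds", {
  for (i in 1:25) {
    n <- 4 + (i %% 3)
    met <- mstMetrics(maxSpanningTree(randomWeightMatrix(n, seed = 2000 + i)))
    leaves <- names(met$degree)[met$degree == 1]
    expect_equal(unname(met$betweenness[leaves]),
                 rep(0, length(leaves)))
    expect_equal(met$tree_hierarchy,
                 met$n_leaves / (2 * met$n_edges * met$bc_max),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under channel relabeling", {
  w <- randomWeightMatrix(6, seed = 31)
  set.seed(32)
  perm <- sample(6)
  wp <- w[perm, perm]
  a <- mstMetrics(maxSpanningTree(w))
  b <- mstMetrics(maxSpanningTree(wp))
  for (k in c("kmax", "leaf_fraction", "diameter", "bc_max", "eccentricity",
              "tree_hierarchy"))
    expect_equal(a[[k]], b[[k]], tolerance = 1e-12)
})

test_that("tree edge mean dominates the whole-brain mean", {
  for (i in 1:30) {
    w <- randomWeightMatrix(5 + (i %% 4), seed = 3000 + i)
    tr <- maxSpanningTree(w)
    expect_gte(mstEdgeMean(tr, w), wholeBrainMean(w))
  }
  wc <- matrix(0.4, 4, 4); diag(wc) <- 0
  dimnames(wc) <- list(letters[1:4], letters[1:4])
  expect_equal(mstEdgeMean(maxSpanningTree(wc), wc), 0.4)
  wOther <- randomWeightMatrix(5, seed = 4)
  expect_error(mstEdgeMean(maxSpanningTree(randomWeightMatrix(4, seed = 5)),
                           wOther), "node sets differ")
})

test_that("overlap is symmetric, bounded, and 100 iff edge sets coincide", {
  w <- randomWeightMatrix(8, seed = 41)
  t1 <- maxSpanningTree(w)
  expect_equal(mstOverlap(t1, t1), 100)

  # star vs path on the same nodes: share exactly one edge
  n <- 5
  ws <- matrix(0.1, n, n); ws[1, 2:n] <- ws[2:n, 1] <- 0.9; diag(ws) <- 0
  dimnames(ws) <- list(sprintf("ch%02d", 1:n), sprintf("ch%02d", 1:n))
  wp <- matrix(0.01, n, n); diag(wp) <- 0
  for (i in 1:(n - 1)) wp[i, i + 1] <- wp[i + 1, i] <- 0.8
  dimnames(wp) <- dimnames(ws)
  tS <- maxSpanningTree(ws); tP <- maxSpanningTree(wp)
  expect_equal(mstOverlap(tS, tP), mstOverlap(tP, tS))
  expect_equal(mstOverlap(tS, tP), 100 * 1 / 4)   # only edge ch01-ch02 shared
  expect_lt(mstOverlap(tS, tP), 100)

  w2 <- randomWeightMatrix(8, seed = 42)
  t2 <- maxSpanningTree(w2)
  ovl <- mstOverlap(t1, t2)
  expect_true(ovl >= 0 && ovl <= 100)
  expect_error(mstOverlap(t1, maxSpanningTree(randomWeightMatrix(6, 43))),
               "different node sets")
})

test_that("ties are counted and broken deterministically", {
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  dimnames(w) <- list(letters[1:4], letters[1:4])
  t1 <- maxSpanningTree(w)
  t2 <- maxSpanningTree(w)
  expect_identical(treeEdges(t1), treeEdges(t2))
  expect_gt(t1@nTies, 0L)
  # lexicographic tie-break picks (a,b), (a,c), (a,d)
  expect_equal(sort(paste(treeEdges(t1)$from, treeEdges(t1)$to)),
               c("a b", "a c", "a d"))
})

test_that("overlap percentages convert to edge counts on a 64-channel tree", {
  expect_equal(overlapEdgeCount(10.8, 64), 6.8, tolerance = 0.01)
  expect_equal(overlapEdgeCount(4.7, 64), 3.0, tolerance = 0.02)
  expect_equal(overlapEdgeCount(100, 64), 63)
})
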