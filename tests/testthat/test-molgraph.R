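test_that("buildGraph validates its input", {
  expect_error(buildGraph(matrix(character(0), ncol = 2)), "empty")
  expect_error(buildGraph(rbind(c("a", "a"))), "self-loop")
  expect_error(buildGraph(rbind(c("a", "b"), c("b", "a"))), "duplicate")
  expect_error(buildGraph(rbind(c("a", "b"), c("c", "d"))), "disconnected")
})

test_that("path graph degrees follow the definition", {
  g <- buildGraph(rbind(c("a", "b"), c("b", "c")))
  expect_identical(graphDegrees(g)[c("a", "b", "c")],
                   c(a = 1L, b = 2L, c = 1L))
  expect_identical(numEdges(g), 2L)
})

test_that("disconnected input can be reduced to its largest component", {
  e <- rbind(c("a", "b"), c("b", "c"), c("x", "y"))
  expect_warning(g <- buildGraph(e, largestComponent = TRUE), "dropped 2")
  expect_setequal(names(graphDegrees(g)), c("a", "b", "c"))
})

test_that("edge partitions of small named graphs match closed forms", {
  single <- buildGraph(rbind(c("a", "b")))
  p <- edgePartition(single)
  expect_equal(unname(partitionPairs(p)), rbind(c(1L, 1L)))
  expect_identical(partitionCounts(p), 1L)

  star <- buildGraph(rbind(c("hub", "l1"), c("hub", "l2"), c("hub", "l3")))
  p <- edgePartition(star)
  expect_equal(unname(partitionPairs(p)), rbind(c(1L, 3L)))
  expect_identical(partitionCounts(p), 3L)
})

test_that("the worked-example molecule reproduces its published partition", {
  for (g in list(epinephrineGraph(), parseSmiles("CNCC(O)c1ccc(O)c(O)c1"))) {
    p <- edgePartition(g)
    expect_equal(unname(partitionPairs(p)), EPI_PARTITION_PAIRS,
                 ignore_attr = TRUE)
    expect_identical(partitionCounts(p), EPI_PARTITION_COUNTS)
    expect_identical(numEdges(p), 13L)
  }
})

test_that("SMILES ingestion is hydrogen-suppressed with one edge per bond", {
  p <- edgePartition(parseSmiles("CC"))
  expect_equal(unname(partitionPairs(p)), rbind(c(1L, 1L)), ignore_attr = TRUE)
  # cyclohexane and benzene give the same simple 6-cycle
  for (smi in c("C1CCCCC1", "c1ccccc1")) {
    p <- edgePartition(parseSmiles(smi))
    expect_equal(unname(partitionPairs(p)), rbind(c(2L, 2L)),
                 ignore_attr = TRUE)
    expect_identical(partitionCounts(p), 6L)
  }
  expect_error(parseSmiles("not a molecule("), "parse")
})

test_that("partition totals and the first-Zagreb edge/vertex identity hold on random graphs", {
  set.seed(42)
  for (i in 1:60) {
    g <- random_tree_graph(sample(3:25, 1))
    p <- edgePartition(g)
    expect_identical(numEdges(p), numEdges(g))
    # sum over partition of count*(a+b) equals sum of squared degrees
    pr <- partitionPairs(p)
    expect_equal(sum(partitionCounts(p) * (pr[, 1] + pr[, 2])),
                 sum(graphDegrees(g)^2))
  }
})

test_that("edge partitions are invariant under vertex relabeling", {
  set.seed(7)
  g <- randomMolecularGraph(15, seed = 11)
  e <- graphEdges(g)
  perm <- setNames(sample(paste0("w", 1:15)), unique(c(e)))
  g2 <- buildGraph(cbind(perm[e[, 1]], perm[e[, 2]]))
  expect_equal(partitionPairs(edgePartition(g)),
               partitionPairs(edgePartition(g2)))
  expect_identical(partitionCounts(edgePartition(g)),
                   partitionCounts(edgePartition(g2)))
})

test_that("makePartition canonicalizes and aggregates degree pairs", {
  p <- makePartition(rbind(c(2, 1), c(1, 2), c(3, 1)), c(1, 2, 4))
  expect_equal(unname(partitionPairs(p)), rbind(c(1L, 2L), c(1L, 3L)),
               ignore_attr = TRUE)
  expect_identical(partitionCounts(p), c(3L, 4L))
  expect_error(makePartition(rbind(c(1, 2)), 0), "positive")
})

test_that("edge list files round-trip through readEdgeList", {
  g <- epinephrineGraph()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(graphEdges(g)), tmp, row.names = FALSE,
            quote = FALSE)
  g2 <- readEdgeList(tmp)
  expect_identical(partitionCounts(edgePartition(g2)),
                   partitionCounts(edgePartition(g)))
})
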