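test_that("dual-graph validity rules accept and reject the right matrices", {
  expect_true(isValidDualGraph(mat(c(0, 3), c(3, 0))))
  expect_true(isValidDualGraph(mat(c(2, 1), c(1, 2))))
  expect_true(isValidDualGraph(mat(c(2, 2), c(2, 0))))
  # degree sum too small
  expect_false(isValidDualGraph(mat(c(0, 1), c(1, 0))))
  # degree 5 on both vertices
  expect_false(isValidDualGraph(mat(c(2, 3), c(3, 2))))
  # disconnected
  expect_false(isValidDualGraph(mat(c(2, 0), c(0, 2))))
  # asymmetric, bad diagonal, out-of-range multiplicity
  expect_false(isValidDualGraph(mat(c(0, 3), c(2, 0))))
  expect_false(isValidDualGraph(mat(c(1, 2), c(2, 1))))
  expect_false(isValidDualGraph(mat(c(0, 4), c(4, 0))))
  # structural problems are errors, not FALSE
  expect_error(isValidDualGraph(matrix(1:6, 2, 3)), "square")
  expect_error(isValidDualGraph(mat(c(0.5, 3), c(3, 0))), "integer")
  expect_error(DualGraph(mat(c(0, 1), c(1, 0))), "invalid dual graph")
})

test_that("canonical form is a complete isomorphism invariant", {
  g1 <- mat(c(0, 3), c(3, 0))
  g2 <- mat(c(2, 1), c(1, 2))
  expect_false(canonicalForm(g1) == canonicalForm(g2))
  # permutation invariance, property-style over several catalogs
  set.seed(42)
  for (n in 3:5) {
    cat_n <- testCatalog(n)
    for (g in cat_n@graphs[sample.int(length(cat_n), min(15, length(cat_n)))]) {
      A <- adjacency(g)
      for (rep in 1:5) {
        p <- sample(n)
        expect_identical(canonicalForm(A[p, p]), canonicalForm(A))
      }
    }
  }
  # agreement with the all-permutation oracle at n = 4: equal keys iff
  # equal oracle keys
  c4 <- testCatalog(4)
  pkgKeys <- vapply(c4@graphs, canonicalForm, character(1))
  orcKeys <- vapply(c4@graphs, function(g) oraclePermKey(adjacency(g)),
                    character(1))
  expect_identical(anyDuplicated(pkgKeys), 0L)
  expect_identical(anyDuplicated(orcKeys), 0L)
})

test_that("enumeration reproduces the hand-checkable counts and the brute-force oracle", {
  expect_identical(length(testCatalog(2)), 3L)
  expect_identical(length(testCatalog(3)), 8L)
  # exhaustive oracle: scan every matrix, dedupe by all-permutation key
  for (n in 2:4) {
    orc <- oracleEnumerate(n)
    got <- vapply(testCatalog(n)@graphs,
                  function(g) oraclePermKey(adjacency(g)), character(1))
    expect_setequal(got, orc)
  }
  # the 2-vertex catalog is exactly the three known topologies
  keys2 <- vapply(testCatalog(2)@graphs, canonicalForm, character(1))
  expected2 <- vapply(list(mat(c(0, 3), c(3, 0)),
                           mat(c(2, 1), c(1, 2)),
                           mat(c(2, 2), c(2, 0))), canonicalForm, character(1))
  expect_setequal(keys2, expected2)
  expect_error(enumerateDualGraphs(1), ">= 2")
})

test_that("every catalog member satisfies the dual-graph invariants", {
  for (n in 2:5) {
    cc <- testCatalog(n)
    for (g in cc@graphs) {
      A <- adjacency(g)
      expect_identical(sum(A), as.integer(4 * n - 2))
      expect_lte(max(rowSums(A)), 4)
      expect_identical(oracleComponents(A), 1L)
      expect_gt(fiedlerNumber(g), 0)
    }
  }
})

test_that("Laplacian and Fiedler numbers match hand computations", {
  expect_equal(graphLaplacian(DualGraph(mat(c(2, 1), c(1, 2)))),
               mat(c(1, -1), c(-1, 1)))
  expect_equal(graphLaplacian(DualGraph(mat(c(0, 3), c(3, 0)))),
               mat(c(3, -3), c(-3, 3)))
  expect_equal(fiedlerNumber(DualGraph(mat(c(2, 1), c(1, 2)))), 2)
  expect_equal(fiedlerNumber(DualGraph(mat(c(2, 2), c(2, 0)))), 4)
  expect_equal(fiedlerNumber(DualGraph(mat(c(0, 3), c(3, 0)))), 6)
  # zero row sums for every catalog member
  for (g in testCatalog(4)@graphs)
    expect_equal(max(abs(rowSums(graphLaplacian(g)))), 0)
})

test_that("ID assignment ranks by ascending Fiedler with deterministic ties", {
  c2 <- testCatalog(2)
  expect_identical(graphIds(c2), c("2_1", "2_2", "2_3"))
  expect_identical(canonicalForm(c2[["2_1"]]),
                   canonicalForm(mat(c(2, 1), c(1, 2))))
  expect_identical(canonicalForm(c2[["2_2"]]),
                   canonicalForm(mat(c(2, 2), c(2, 0))))
  expect_identical(canonicalForm(c2[["2_3"]]),
                   canonicalForm(mat(c(0, 3), c(3, 0))))
  # determinism: permuting the input order leaves the assignment unchanged
  c3 <- testCatalog(3)
  set.seed(7)
  perm <- sample(length(c3))
  shuffled <- new("GraphCatalog",
                  graphs = lapply(c3@graphs[perm], function(g) {
                    g@id <- NA_character_; g
                  }),
                  ids = rep(NA_character_, length(c3)),
                  metadata = c3@metadata)
  re <- assignIds(shuffled)
  expect_identical(
    vapply(re@graphs, canonicalForm, character(1)),
    vapply(c3@graphs, canonicalForm, character(1)))
  # k values are exactly 1..count and descending order reverses them
  expect_identical(graphIds(c3), sprintf("3_%d", 1:8))
  desc <- assignIds(shuffled, order = "descending")
  expect_identical(
    vapply(desc@graphs, canonicalForm, character(1)),
    rev(vapply(c3@graphs, canonicalForm, character(1))))
  # mixed vertex counts refuse
  expect_error(assignIds(combineCatalogs(list(c2, c3))), "single vertex count")
})

test_that("catalog accessors and indexing behave", {
  c3 <- testCatalog(3)
  expect_identical(length(c3), 8L)
  expect_identical(vertexCounts(c3), rep(3L, 8))
  expect_identical(graphId(c3[["3_4"]]), "3_4")
  expect_identical(canonicalForm(c3[[4]]), canonicalForm(c3[["3_4"]]))
  expect_error(c3[["9_1"]], "no graph with ID")
  expect_identical(edgeCount(c3[["3_1"]]), 5L)  # 2n - 1 strand segments
})
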