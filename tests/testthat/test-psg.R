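test_that("filtration complexes follow the distance semantics and nest", {
  kiss <- DualGraph(mat(c(0, 3), c(3, 0)))
  expect_identical(nrow(buildFiltration(kiss, 1)$simplices[[2]]), 0L)
  expect_identical(nrow(buildFiltration(kiss, 2)$simplices[[2]]), 0L)
  expect_identical(nrow(buildFiltration(kiss, 3)$simplices[[2]]), 1L)
  # at d = 3 the edge set is the full skeleton, so the complex is connected
  for (g in testCatalog(4)@graphs[1:10]) {
    K3 <- buildFiltration(g, 3)
    A <- adjacency(g)
    expect_identical(nrow(K3$simplices[[2]]),
                     sum(A[upper.tri(A)] >= 1))
    # nesting: simplices at d are a subset of those at d+1
    for (d in 1:2) {
      Ka <- buildFiltration(g, d); Kb <- buildFiltration(g, d + 1)
      for (q in 2:4) {
        a <- apply(Ka$simplices[[q]], 1, paste, collapse = ",")
        b <- apply(Kb$simplices[[q]], 1, paste, collapse = ",")
        expect_true(all(a %in% b))
      }
    }
  }
})

test_that("persistent Laplacians match hand eigendecompositions", {
  # path on 3 vertices entering at d = 1: eigenvalues {0, 1, 3}
  path3 <- DualGraph(pathGraph(3))
  L0 <- persistentLaplacian(buildFiltration(path3, 1), 0)
  expect_equal(sort(eigen(L0, symmetric = TRUE)$values), c(0, 1, 3))
  # empty edge set: zero n x n matrix
  kiss <- DualGraph(mat(c(0, 3), c(3, 0)))
  expect_equal(persistentLaplacian(buildFiltration(kiss, 1), 0),
               matrix(0, 2, 2))
  # filled triangle: q = 1 Laplacian has eigenvalues {3, 3, 3}, empty kernel
  tri <- DualGraph(mat(c(2, 1, 1), c(1, 2, 1), c(1, 1, 0)))
  K <- buildFiltration(tri, 1)
  expect_identical(nrow(K$simplices[[3]]), 1L)  # the 2-simplex is present
  L1 <- persistentLaplacian(K, 1)
  expect_equal(sort(eigen(L1, symmetric = TRUE)$values), c(3, 3, 3))
  expect_identical(laplacianSpectrum(L1)$betti, 0L)
})

test_that("boundary-of-boundary vanishes on catalog graphs", {
  for (g in testCatalog(5)@graphs[seq(1, 110, by = 12)]) {
    K <- buildFiltration(g, 3)
    for (q in 1:2) {
      Bq <- boundaryMatrix(K, q)
      Bq1 <- boundaryMatrix(K, q + 1)
      if (ncol(Bq) > 0 && ncol(Bq1) > 0)
        expect_equal(max(abs(Bq %*% Bq1)), 0)
    }
  }
})

test_that("spectrum extraction counts zeros and preserves the trace", {
  s <- laplacianSpectrum(matrix(0, 2, 2))
  expect_equal(s$values, c(0, 0))
  expect_identical(s$betti, 2L)
  s2 <- laplacianSpectrum(mat(c(1, -1), c(-1, 1)))
  expect_equal(s2$values, c(0, 2))
  expect_identical(s2$betti, 1L)
  expect_error(laplacianSpectrum(mat(c(1, 2), c(0, 1))), "symmetric")
  for (g in testCatalog(4)@graphs[1:8]) {
    L <- persistentLaplacian(buildFiltration(g, 2), 0)
    expect_equal(sum(laplacianSpectrum(L)$values), sum(diag(L)))
  }
})

test_that("feature vectors match the hand-computed 2-vertex references", {
  expected <- list(
    "2_1" = c(2, 2, 1, 1,  2, 2, 2, 1, 1, 1, 1,  2, 2, 2, 1, 1, 1, 1,  1),
    "2_2" = c(0, 0, 0, 2,  2, 2, 2, 1, 1, 1, 1,  2, 2, 2, 1, 1, 1, 1,  0.5),
    "2_3" = c(0, 0, 0, 2,  0, 0, 0, 0, 0, 0, 2,  2, 2, 2, 1, 1, 1, 1,  0))
  c2 <- testCatalog(2)
  for (id in names(expected)) {
    got <- psgFeatures(c2[[id]])
    expect_equal(unname(got), expected[[id]], tolerance = 1e-12, label = id)
    expect_identical(names(got), psgFeatureNames())
  }
  # average degree arithmetic on a second example
  expect_equal(unname(psgFeatures(DualGraph(mat(c(2, 1), c(1, 2))))["avg_degree"]), 1)
})

test_that("spectral statistics satisfy their structural identities", {
  for (n in 2:5) {
    for (g in testCatalog(n)@graphs[seq(1, length(testCatalog(n)),
                                        length.out = min(12, length(testCatalog(n))))]) {
      f <- psgFeatures(g)
      A <- adjacency(g)
      # Betti-0 monotone, final connectivity
      expect_gte(f[["d1_zero_count"]], f[["d2_zero_count"]])
      expect_gte(f[["d2_zero_count"]], f[["d3_zero_count"]])
      expect_identical(f[["d3_zero_count"]], 1)
      # trace identity: eigenvalue sum = 2 x edges present at d
      for (d in 1:3) {
        nm <- paste0("d", d, "_sum")
        expect_equal(f[[nm]], 2 * sum(A[upper.tri(A)] %in% 1:d))
      }
      # variance = std^2
      expect_equal(f[["d2_variance"]], f[["d2_std"]]^2)
      expect_equal(f[["d3_variance"]], f[["d3_std"]]^2)
      # beta_0 equals a union-find component count on the same edge set
      for (d in 1:3) {
        Ad <- A * (A <= d)
        nm <- paste0("d", d, "_zero_count")
        expect_identical(as.integer(f[[nm]]), oracleComponents(Ad))
      }
      # loopless graphs have zero average degree
      if (all(diag(A) == 0)) expect_identical(f[["avg_degree"]], 0)
    }
  }
})

test_that("nonzero-minimum feature is total and zero-statistics flag works", {
  kiss <- DualGraph(mat(c(0, 3), c(3, 0)))
  f <- psgFeatures(kiss)
  expect_identical(f[["d1_nonzero_min"]], 0)  # all-zero spectrum
  fz <- psgFeatures(kiss, includeZeros = FALSE)
  # at d = 3 the nonzero spectrum is {2}: mean 2, variance 0
  expect_equal(fz[["d3_mean"]], 2)
  expect_equal(fz[["d3_variance"]], 0)
  expect_identical(fz[["d3_zero_count"]], 1)  # zero count itself unchanged
})

test_that("catalog featurization is consistent and round-trips", {
  c2 <- testCatalog(2)
  tab <- featurizeCatalog(c2)
  expect_identical(dim(tab), c(3L, 20L))
  expect_identical(names(tab), c("id", psgFeatureNames()))
  expect_equal(as.numeric(tab[tab$id == "2_3", -1]),
               unname(psgFeatures(c2[["2_3"]])))
  tmp <- tempfile(fileext = ".tsv")
  writeFeatureTable(tab, tmp)
  back <- readFeatureTable(tmp)
  expect_equal(back, tab, tolerance = 1e-12)
})
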