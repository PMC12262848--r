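# well-separated two-Gaussian data with ID rownames; first nLab rows of
# blob 1 are "known RNA"
makeBlobs <- function(n = 200, p = 5, sep = 6, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(matrix(rnorm(half * p), half, p),
             matrix(rnorm((n - half) * p, mean = sep / sqrt(p)), n - half, p))
  rownames(x) <- sprintf("9_%d", seq_len(n))
  list(x = x, truth = rep(1:2, c(half, n - half)),
       labels = rownames(x)[1:10])
}

test_that("standardization is a zero-mean unit-variance invertible map", {
  b <- makeBlobs(100)
  m <- cbind(b$x, constant = 5)
  s <- standardizeFeatures(m)
  expect_equal(max(abs(colMeans(s))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(s[, 1:5], 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(s[, "constant"]), rep(0, 100))
  expect_equal(invertStandardization(s), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardizeFeatures(cbind(b$x, NA)), "finite")
})

test_that("all six methods recover well-separated blobs and are seed-deterministic", {
  b <- makeBlobs(240, sep = 8, seed = 3)
  for (m in clusterMethods()) {
    a1 <- runClustering(b$x, m, seed = 4)
    a2 <- runClustering(b$x, m, seed = 4)
    expect_identical(a1, a2)
    agree <- max(mean((a1 == 1) == (b$truth == 1)),
                 mean((a1 == 2) == (b$truth == 1)))
    expect_equal(agree, 1, label = m)
  }
  expect_error(runClustering(b$x, "pam"), "arg")
  expect_error(runClustering(b$x, "ward", wardMaxRows = 100L), "size guard")
})

test_that("RNA-like designation follows the labeled majority with a tie path", {
  x <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10), ncol = 1)
  rownames(x) <- sprintf("4_%d", 1:8)
  a <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  # all labeled graphs in cluster 2 -> cluster 2 is RNA-like
  r <- designateRnaLike(x, a, labels = c("4_5", "4_6"))
  expect_identical(r@rnaLikeCluster, 2L)
  expect_setequal(rnaLikeIds(r), c("4_5", "4_6", "4_7", "4_8"))
  # 3 of 4 labeled in cluster 1
  r2 <- designateRnaLike(x, a, labels = c("4_1", "4_2", "4_3", "4_5"))
  expect_identical(r2@rnaLikeCluster, 1L)
  # symmetric 2-2 split exercises the tie rule (smaller cluster wins)
  a3 <- c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L)
  expect_warning(
    r3 <- designateRnaLike(x, a3, labels = c("4_1", "4_2", "4_6", "4_7")),
    "tie")
  expect_identical(r3@rnaLikeCluster, 2L)
  expect_true(r3@tie)
  # no labeled graph at all is a designation error
  expect_error(designateRnaLike(x, a, labels = "7_99"), "designation error")
  # centers are the cluster centroids, distances Euclidean
  expect_equal(unname(r@centers[, 1]), c(0, 10))
  expect_equal(unname(r@distances[1, ]), c(0, 10))
})

test_that("metrics agree with from-formula oracles on toy inputs", {
  set.seed(9)
  x <- matrix(rnorm(36), 12, 3)
  rownames(x) <- sprintf("5_%d", 1:12)
  a <- rep(c(1L, 2L), each = 6)
  labels <- c("5_1", "5_2", "5_3", "5_7")
  r <- designateRnaLike(x, a, labels)
  ev <- evaluateClustering(r)
  expect_equal(ev$sensitivity,
               oracleSensitivity(rownames(x), a, r@rnaLikeCluster, labels),
               tolerance = 1e-9)
  expect_equal(ev$silhouette, oracleSilhouette(x, a), tolerance = 1e-9)
  expect_equal(ev$homogeneity,
               oracleHomogeneity(rownames(x) %in% labels, a),
               tolerance = 1e-9)
  expect_equal(ev$rna_like_share, 50)
  # sensitivity + labeled share in the other cluster = 100
  inRna <- a == r@rnaLikeCluster
  lab <- rownames(x) %in% labels
  expect_equal(ev$sensitivity + 100 * sum(lab & !inRna) / sum(lab), 100)
  # all labeled in the RNA-like cluster gives sensitivity 100
  r100 <- designateRnaLike(x, a, labels = c("5_1", "5_4"))
  expect_equal(evaluateClustering(r100)$sensitivity, 100)
})

test_that("metrics are invariant under raw label swap", {
  b <- makeBlobs(60, seed = 12)
  a <- runClustering(b$x, "kmeans", seed = 0)
  r1 <- designateRnaLike(b$x, a, b$labels)
  r2 <- designateRnaLike(b$x, 3L - a, b$labels)
  expect_equal(evaluateClustering(r1)[, -1], evaluateClustering(r2)[, -1],
               tolerance = 1e-12)
  expect_setequal(rnaLikeIds(r1), rnaLikeIds(r2))
})

test_that("center ranking orders hypothetical graphs by distance with ID tie-breaks", {
  x <- matrix(c(0, 1, 2, 3, 4, 20, 21, 22), ncol = 1)
  rownames(x) <- c("4_9", "4_2", "4_3", "4_4", "4_5", "4_6", "4_7", "4_8")
  a <- c(rep(1L, 5), rep(2L, 3))
  r <- designateRnaLike(x, a, labels = c("4_2", "4_4"))
  rk <- rankByCenter(r, "rna_like", k = 3)
  # center of cluster 1 is 2; hypothetical members 4_9(0), 4_3(2), 4_5(4)
  expect_identical(rk$id, c("4_3", "4_5", "4_9"))
  expect_equal(rk$distance, c(0, 2, 2))
  # a hypothetical point exactly at the centroid ranks first; ties by ID
  expect_warning(rkAll <- rankByCenter(r, "non_rna_like", k = 15), "only")
  expect_identical(rkAll$id, c("4_7", "4_6", "4_8"))
  expect_lte(nrow(rkAll), 15)
})

test_that("consensus counting follows the set arithmetic", {
  top <- c("4_1", "4_2", "4_3")
  expect_identical(consensusTop(list(top, top, top), 3)$id, top)
  disjoint <- list(c("4_1"), c("4_2"), c("4_3"))
  expect_identical(nrow(consensusTop(disjoint, 3)), 0L)
  overlap <- list(c("4_1", "4_2"), c("4_1", "4_3"), c("4_1", "4_2"),
                  c("4_4"))
  co <- consensusTop(overlap, 2)
  expect_identical(co$id, c("4_1", "4_2"))
  expect_identical(co$count, c(3L, 2L))
  expect_error(consensusTop(list(top), 3), "at least")
})

test_that("PCA embedding matches covariance eigenstructure", {
  # data on a line: second component carries no variance
  t <- seq(-1, 1, length.out = 20)
  lineData <- cbind(t, 2 * t, -t)
  emb <- pcaEmbed(lineData)
  ev <- attr(emb, "explainedVariance")
  expect_equal(ev[1], 1, tolerance = 1e-12)
  expect_equal(unname(emb[, 2]), rep(0, 20), tolerance = 1e-9)
  # 3-point toy against a hand eigendecomposition of the covariance
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  e <- eigen(stats::cov(pts))
  emb3 <- pcaEmbed(pts)
  expect_equal(as.numeric(abs(stats::cor(emb3[, 1], pts %*% e$vectors[, 1]))),
               1, tolerance = 1e-9)
  # orthogonal transform leaves explained variance untouched
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  d <- makeBlobs(50, p = 3)$x
  expect_equal(attr(pcaEmbed(d), "explainedVariance"),
               attr(pcaEmbed(d %*% Q), "explainedVariance"),
               tolerance = 1e-9)
  expect_error(pcaEmbed(pts[1, , drop = FALSE], components = 2), "fewer rows")
})

test_that("later-vintage validation counts confirmed graphs by vertex count", {
  x <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  rownames(x) <- c("4_1", "4_2", "5_1", "5_2", "5_3", "5_4")
  a <- c(1L, 1L, 1L, 2L, 2L, 2L)
  r <- designateRnaLike(x, a, labels = c("4_1"))
  # later labels subset of earlier: nothing new to confirm
  v0 <- validateAgainst(r, laterLabels = c("4_1"))
  expect_identical(sum(v0$confirmed), 0L)
  # new graphs: 4_2 and 5_1 are in the RNA-like cluster, 5_2 is not
  v <- validateAgainst(r, laterLabels = c("4_1", "4_2", "5_1", "5_2"))
  expect_identical(v$confirmed[v$vertices == 4], 1L)
  expect_identical(v$confirmed[v$vertices == 5], 1L)
})

test_that("vertex-grouped dataset construction respects ranges", {
  feats <- rbind(
    data.frame(id = sprintf("4_%d", 1:3), f = 1:3),
    data.frame(id = sprintf("5_%d", 1:2), f = 4:5),
    data.frame(id = sprintf("6_%d", 1:4), f = 6:9))
  ds <- makeDatasets(feats, which = c("V4&5", "V6"))
  expect_identical(nrow(ds[["V4&5"]]), 5L)
  expect_identical(nrow(ds[["V6"]]), 4L)
  expect_error(makeDatasets(feats, which = "V7"), "needs vertex counts")
  expect_error(makeDatasets(feats), "needs vertex counts")  # All needs 4..9
  all67 <- makeDatasets(feats, which = "All", allowPartial = TRUE)
  expect_identical(nrow(all67[["All"]]), 9L)
  expect_error(makeDatasets(feats, which = "V10"), "unknown dataset")
})
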