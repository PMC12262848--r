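# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths: brute-force enumeration over raw matrices,
# all-permutation isomorphism, union-find connectivity, and from-formula
# clustering metrics.

# --- brute-force dual-graph enumeration (n <= 4) -------------------------

# all valid labeled adjacency matrices by exhaustive scan
oracleAllMatrices <- function(n) {
  npairs <- n * (n - 1) / 2
  offGrid <- expand.grid(rep(list(0:3), npairs))
  diagGrid <- expand.grid(rep(list(c(0, 2)), n))
  out <- list()
  for (i in seq_len(nrow(offGrid))) {
    off <- as.integer(offGrid[i, ])
    A0 <- matrix(0L, n, n)
    A0[upper.tri(A0)] <- off
    A0 <- A0 + t(A0)
    for (j in seq_len(nrow(diagGrid))) {
      A <- A0
      diag(A) <- as.integer(diagGrid[j, ])
      if (sum(A) != 4 * n - 2) next
      if (any(rowSums(A) > 4)) next
      if (oracleComponents(A) != 1L) next
      out[[length(out) + 1L]] <- A
    }
  }
  out
}

# number of connected components via union-find on the off-diagonal support
oracleComponents <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# minimal row-major key over all vertex permutations (independent of the
# package's canonical form)
oraclePermKey <- function(A) {
  n <- nrow(A)
  perms <- oraclePermutations(n)
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    s <- paste(A[p, p], collapse = ",")
    if (is.null(best) || s < best) best <- s
  }
  best
}

oraclePermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oraclePermutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    ins <- cbind(sub, n)
    ins[, c(k, n)] <- ins[, c(n, k)]
    out <- rbind(out, ins)
  }
  out
}

# isomorphism classes of all valid matrices, as a set of permutation keys
oracleEnumerate <- function(n) {
  unique(vapply(oracleAllMatrices(n), oraclePermKey, character(1)))
}

# --- clustering metric oracles ------------------------------------------

oracleSensitivity <- function(ids, assignment, rnaCluster, labels) {
  lab <- ids %in% labels
  100 * sum(lab & assignment == rnaCluster) / sum(lab)
}

oracleSilhouette <- function(x, assignment) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(k) mean(D[i, assignment == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracleHomogeneity <- function(classes, clusters) {
  n <- length(classes)
  ent <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hC <- ent(classes)
  if (hC == 0) return(1)
  hCK <- 0
  for (k in unique(clusters)) {
    sel <- clusters == k
    hCK <- hCK + sum(sel) / n * ent(classes[sel])
  }
  1 - hCK / hC
}

# --- small graph builders ------------------------------------------------

mat <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# a valid loop-decorated path on n vertices: loops everywhere plus single
# edges along the path (degree sum 2n + 2(n-1) = 4n - 2 exactly)
pathGraph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  diag(A) <- 2L
  A
}

# random valid dual graph via the package enumerator (fixed catalogs)
randomCatalogGraphs <- function(catalogs, k, seed) {
  pool <- unlist(lapply(catalogs, function(cc) cc@graphs))
  set.seed(seed)
  pool[sample.int(length(pool), k, replace = k > length(pool))]
}

# --- shared catalog cache (enumeration is deterministic) -----------------

.catalogCache <- new.env(parent = emptyenv())
testCatalog <- function(n) {
  key <- as.character(n)
  if (is.null(.catalogCache[[key]]))
    .catalogCache[[key]] <- enumerateDualGraphs(n)
  .catalogCache[[key]]
}

# --- subgraph gluing oracle ---------------------------------------------

# Gluing oracle: a graph is separable iff it can be assembled from two
# smaller valid dual graphs sharing one vertex.  The merge is the inverse of
# the vertex-sharing split: the shared vertex keeps a self-loop only when
# both parts carry one; a merge of two loop-free shared vertices is not a
# legal split image.  Keys are all-permutation minimal forms, independent of
# the package's canonical labelling.
oracleGlueKeys <- function(n, catalogs) {
  keys <- character(0)
  sizes <- list()
  for (n1 in 2:(n - 1)) {
    n2 <- n + 1 - n1
    if (n2 < 2 || n2 > n - 1 || n1 > n2) next
    sizes[[length(sizes) + 1L]] <- c(n1, n2)
  }
  for (sz in sizes) {
    g1s <- catalogs[[as.character(sz[1])]]@graphs
    g2s <- catalogs[[as.character(sz[2])]]@graphs
    for (g1 in g1s) for (g2 in g2s) {
      A1 <- adjacency(g1); A2 <- adjacency(g2)
      for (u in seq_len(nrow(A1))) for (w in seq_len(nrow(A2))) {
        l1 <- A1[u, u] == 2; l2 <- A2[w, w] == 2
        if (!l1 && !l2) next
        merged <- oracleMerge(A1, u, A2, w, loop = l1 && l2)
        if (is.null(merged)) next
        keys <- c(keys, oraclePermKey(merged))
      }
    }
  }
  unique(keys)
}

oracleMerge <- function(A1, u, A2, w, loop) {
  n1 <- nrow(A1); n2 <- nrow(A2)
  o1 <- setdiff(seq_len(n1), u); o2 <- setdiff(seq_len(n2), w)
  n <- n1 + n2 - 1L
  M <- matrix(0L, n, n)
  i1 <- seq_along(o1)                      # part-1 vertices
  i2 <- length(o1) + seq_along(o2)         # part-2 vertices
  im <- n                                  # merged shared vertex
  M[i1, i1] <- A1[o1, o1]
  M[i2, i2] <- A2[o2, o2]
  M[i1, im] <- A1[o1, u]; M[im, i1] <- A1[u, o1]
  M[i2, im] <- A2[o2, w]; M[im, i2] <- A2[w, o2]
  M[im, im] <- if (loop) 2L else 0L
  if (max(rowSums(M)) > 4 || sum(M) != 4 * n - 2) return(NULL)
  M
}

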