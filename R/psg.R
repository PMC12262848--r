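# Distance-filtration simplicial complexes, boundary matrices, persistent
# Laplacians and the 19-dimensional persistent-spectral feature vector.

#' Build the distance-filtration simplicial complex of a dual graph
#'
#' Adjacency entries are read as distances: an edge \{i, j\} is present in
#' the complex at filtration value \code{d} iff \eqn{1 \le A_{ij} \le d}, so
#' the complexes at d = 1, 2, 3 are nested.  Self-loops and edge
#' multiplicities do not create extra simplices.  Triangles and tetrahedra
#' are the 3- and 4-cliques of the present edge set (clique completion up to
#' dimension 3).
#'
#' @param g a \linkS4class{DualGraph}.
#' @param d filtration value, one of 0, 1, 2, 3 (0 = vertices only).
#' @return a list of class \code{"FiltrationComplex"} with components
#'   \code{n}, \code{d}, and \code{simplices} (a list of integer matrices,
#'   one row per simplex, for dimensions 0..3).
#' @examples
#' K <- buildFiltration(DualGraph(rbind(c(0, 3), c(3, 0))), d = 1)
#' nrow(K$simplices[[2]])  # 0 edges: the triple connection enters at d = 3
#' @export
buildFiltration <- function(g, d) {
  stopifnot(is(g, "DualGraph"), d %in% 0:3)
  A <- adjacency(g)
  n <- nrow(A)
  present <- A >= 1 & A <= d
  diag(present) <- FALSE
  edges <- which(upper.tri(A) & present, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  tri <- .cliques(present, n, 3L)
  tet <- .cliques(present, n, 4L)
  structure(list(n = n, d = d,
                 simplices = list(matrix(seq_len(n), ncol = 1),
                                  unname(edges), tri, tet)),
            class = "FiltrationComplex")
}

# all k-cliques of a symmetric logical adjacency, one sorted row per clique
.cliques <- function(present, n, k) {
  if (n < k) return(matrix(integer(0), 0, k))
  cmb <- t(combn(n, k))
  keep <- apply(cmb, 1, function(v) {
    all(present[t(combn(v, 2))[, c(1, 2), drop = FALSE]])
  })
  cmb[keep, , drop = FALSE]
}

#' Boundary matrix of a filtration complex
#'
#' Signed incidence matrix \eqn{B_q} mapping q-simplices to (q-1)-simplices
#' under the fixed vertex-index orientation; satisfies
#' \eqn{B_q B_{q+1} = 0}.
#'
#' @param K a \code{"FiltrationComplex"}.
#' @param q simplex dimension (1, 2 or 3).
#' @return numeric matrix with one row per (q-1)-simplex and one column per
#'   q-simplex (possibly with zero columns).
#' @export
boundaryMatrix <- function(K, q) {
  stopifnot(inherits(K, "FiltrationComplex"), q >= 1, q <= 3)
  lower <- K$simplices[[q]]
  upper <- K$simplices[[q + 1]]
  B <- matrix(0, nrow(lower), nrow(upper))
  if (nrow(upper) == 0L || nrow(lower) == 0L) return(B)
  lowKey <- apply(lower, 1, paste, collapse = ",")
  for (j in seq_len(nrow(upper))) {
    s <- upper[j, ]
    for (i in seq_along(s)) {
      face <- paste(s[-i], collapse = ",")
      B[match(face, lowKey), j] <- (-1)^(i + 1)
    }
  }
  B
}

#' Persistent Laplacian of a filtration snapshot
#'
#' \eqn{L_q = B_{q+1} B_{q+1}^T + B_q^T B_q}; for q = 0 the down-term is
#' empty and \eqn{L_0 = B_1 B_1^T}, the unweighted graph Laplacian of the
#' complex's 1-skeleton.  The kernel dimension of \eqn{L_q} equals the
#' Betti-q number of the snapshot.
#'
#' @param K a \code{"FiltrationComplex"}.
#' @param q dimension (0, 1 or 2).
#' @return symmetric positive semidefinite matrix, one row/column per
#'   q-simplex (0 x 0 when the complex has no q-simplices).
#' @export
persistentLaplacian <- function(K, q) {
  stopifnot(inherits(K, "FiltrationComplex"), q >= 0, q <= 2)
  nq <- nrow(K$simplices[[q + 1]])
  if (nq == 0L) return(matrix(0, 0, 0))
  up <- boundaryMatrix(K, q + 1)
  L <- up %*% t(up)
  if (q >= 1) {
    down <- boundaryMatrix(K, q)
    L <- L + t(down) %*% down
  }
  L
}

#' Eigen-spectrum of a (persistent) Laplacian, with Betti count
#'
#' @param L symmetric positive semidefinite matrix.
#' @param zeroTol eigenvalues below this are counted as zero; default 1e-8,
#'   far below the spectral gaps of integer-entried Laplacians at these
#'   sizes.
#' @return list of class \code{"SpectrumResult"}: \code{values} (ascending,
#'   clamped at 0), \code{betti} (number of zero eigenvalues), and
#'   \code{zeroTol}.
#' @export
laplacianSpectrum <- function(L, zeroTol = 1e-8) {
  if (!is.matrix(L) || nrow(L) != ncol(L))
    stop("L must be a square matrix")
  if (nrow(L) == 0L)
    return(structure(list(values = numeric(0), betti = 0L,
                          zeroTol = zeroTol), class = "SpectrumResult"))
  if (max(abs(L - t(L))) > 1e-10) stop("L must be symmetric")
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (min(ev) < -zeroTol) stop("L is not positive semidefinite")
  ev <- pmax(ev, 0)
  structure(list(values = ev, betti = sum(ev < zeroTol), zeroTol = zeroTol),
            class = "SpectrumResult")
}

#' Names of the 19 persistent-spectral features, in fixed order
#' @return character vector of length 19.
#' @export
psgFeatureNames <- function() {
  c("d1_sum", "d1_nonzero_min", "d1_variance", "d1_zero_count",
    "d2_sum", "d2_nonzero_min", "d2_max", "d2_mean", "d2_std",
    "d2_variance", "d2_zero_count",
    "d3_sum", "d3_nonzero_min", "d3_max", "d3_mean", "d3_std",
    "d3_variance", "d3_zero_count",
    "avg_degree")
}

#' The 19-dimensional persistent-spectral feature vector of a dual graph
#'
#' Statistics of the 0-th persistent-Laplacian spectrum at filtration values
#' d = 1, 2, 3: at d = 1 the sum, smallest nonzero eigenvalue, population
#' variance and number of zeros; at d = 2 and d = 3 additionally the
#' maximum, mean and standard deviation (7 statistics each).  The 19th
#' feature is the average self-loop degree
#' \eqn{Avg(Deg) = \sum_i A_{ii} / (2n)}, which restores the self-loop
#' information the distance filtration ignores.
#'
#' @param g a \linkS4class{DualGraph}.
#' @param includeZeros logical; when TRUE (default) sum/max/mean/std/variance
#'   are computed over the full spectrum including zero eigenvalues, when
#'   FALSE over the nonzero eigenvalues only.
#' @param zeroTol zero-eigenvalue tolerance.
#' @return named numeric vector of length 19 (see
#'   \code{\link{psgFeatureNames}}).
#' @examples
#' psgFeatures(DualGraph(rbind(c(0, 3), c(3, 0))))
#' @export
psgFeatures <- function(g, includeZeros = TRUE, zeroTol = 1e-8) {
  stopifnot(is(g, "DualGraph"))
  A <- adjacency(g)
  n <- nrow(A)
  out <- numeric(0)
  for (d in 1:3) {
    L <- persistentLaplacian(buildFiltration(g, d), 0)
    sp <- laplacianSpectrum(L, zeroTol)
    ev <- sp$values
    nz <- ev[ev >= zeroTol]
    pool <- if (includeZeros) ev else nz
    if (length(pool) == 0L) pool <- 0
    popvar <- mean((pool - mean(pool))^2)
    nzmin <- if (length(nz)) min(nz) else 0
    stats <- if (d == 1L) {
      c(sum = sum(pool), nonzero_min = nzmin, variance = popvar,
        zero_count = sp$betti)
    } else {
      c(sum = sum(pool), nonzero_min = nzmin, max = max(pool),
        mean = mean(pool), std = sqrt(popvar), variance = popvar,
        zero_count = sp$betti)
    }
    names(stats) <- paste0("d", d, "_", names(stats))
    out <- c(out, stats)
  }
  c(out, avg_degree = sum(diag(A)) / (2 * n))
}

#' Featurize a whole catalog
#'
#' @param catalog a \linkS4class{GraphCatalog}.
#' @param includeZeros,zeroTol passed to \code{\link{psgFeatures}}.
#' @return data.frame with column \code{id} followed by the 19 features in
#'   fixed order, one row per catalog member.
#' @export
featurizeCatalog <- function(catalog, includeZeros = TRUE, zeroTol = 1e-8) {
  stopifnot(is(catalog, "GraphCatalog"))
  F <- t(vapply(catalog@graphs, psgFeatures, numeric(19),
                includeZeros = includeZeros, zeroTol = zeroTol))
  data.frame(id = graphIds(catalog), F, check.names = FALSE,
             stringsAsFactors = FALSE)
}
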