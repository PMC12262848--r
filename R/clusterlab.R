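# Two-cluster partitioning with six algorithms, RNA-like designation,
# evaluation metrics, distance-to-center ranking, consensus and PCA.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Convert a feature table to a numeric matrix with ID rownames
#' @param features data.frame from \code{\link{featurizeCatalog}} (first
#'   column \code{id}) or a numeric matrix with rownames.
#' @return numeric matrix.
#' @export
featureMatrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(is.data.frame(features), "id" %in% names(features))
  m <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  if (!is.numeric(m)) stop("feature columns must be numeric")
  rownames(m) <- features$id
  m
}

#' Standardize features to zero mean and unit variance
#'
#' Per-column z-scoring; constant columns are mapped to zero.  The centering
#' and scaling vectors are stored as attributes so the transform can be
#' inverted or re-applied to new rows.
#'
#' @param features feature table or matrix.
#' @return numeric matrix with attributes \code{center} and \code{scale}.
#' @export
standardizeFeatures <- function(features) {
  m <- featureMatrix(features)
  if (any(!is.finite(m))) stop("features must be finite and non-missing")
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  scl[scl == 0] <- 1  # constant columns -> zeros after centering
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert a standardization
#' @param x matrix produced by \code{\link{standardizeFeatures}}.
#' @return matrix on the original feature scale.
#' @export
invertStandardization <- function(x) {
  ctr <- attr(x, "center"); scl <- attr(x, "scale")
  if (is.null(ctr) || is.null(scl)) stop("x carries no standardization")
  out <- sweep(sweep(x, 2, scl, "*"), 2, ctr, "+")
  attr(out, "center") <- NULL; attr(out, "scale") <- NULL
  out
}

#' The six clustering algorithm names
#' @return character vector.
#' @export
clusterMethods <- function() {
  c("kmeans", "minibatch_kmeans", "gmm", "ward", "spectral", "birch")
}

#' Run one of six two-cluster algorithms
#'
#' Partitions a (standardized) feature matrix into exactly two clusters.
#' All methods are deterministic given \code{seed}.  Hierarchical (ward)
#' clustering refuses datasets above \code{wardMaxRows} rows because of its
#' cubic time complexity.
#'
#' @param x numeric matrix (rows = graphs).
#' @param method one of \code{\link{clusterMethods}}.
#' @param seed integer random seed.
#' @param wardMaxRows size guard for ward clustering (default 30000).
#' @return integer vector of raw cluster indices (1 or 2), named by rownames
#'   of \code{x}.
#' @export
runClustering <- function(x, method = clusterMethods(), seed = 0,
                          wardMaxRows = 30000L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows to cluster")
  set.seed(as.integer(seed))
  cl <- switch(method,
    kmeans = stats::kmeans(x, centers = 2L, nstart = 10L,
                           iter.max = 100L)$cluster,
    minibatch_kmeans = .miniBatchKMeans(x, k = 2L, batchSize = 1024L),
    gmm = {
      fit <- mclust::Mclust(x, G = 2L, modelNames = "VVV", verbose = FALSE)
      if (is.null(fit))  # fall back to a simpler covariance model
        fit <- mclust::Mclust(x, G = 2L, verbose = FALSE)
      fit$classification
    },
    ward = {
      if (nrow(x) > wardMaxRows)
        stop("ward clustering refused: ", nrow(x), " rows exceed the ",
             wardMaxRows, "-row size guard")
      cutree(hclust(dist(x), method = "ward.D2"), k = 2L)
    },
    spectral = .spectralCluster(x, k = 2L),
    birch = .birchCluster(x, k = 2L))
  cl <- as.integer(cl)
  names(cl) <- rownames(x)
  cl
}

# Mini-batch k-means (k-means++ seeding, per-center learning rates).
.miniBatchKMeans <- function(x, k = 2L, batchSize = 1024L, iters = 150L) {
  n <- nrow(x)
  centers <- x[.kppInit(x, k), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(iters)) {
    batch <- if (n <= batchSize) seq_len(n) else
      sample.int(n, batchSize, replace = FALSE)
    xb <- x[batch, , drop = FALSE]
    a <- max.col(-.sqDistToCenters(xb, centers))
    for (j in seq_len(k)) {
      pts <- xb[a == j, , drop = FALSE]
      if (nrow(pts) == 0L) next
      counts[j] <- counts[j] + nrow(pts)
      eta <- nrow(pts) / counts[j]
      centers[j, ] <- (1 - eta) * centers[j, ] + eta * colMeans(pts)
    }
  }
  max.col(-.sqDistToCenters(x, centers))
}

.kppInit <- function(x, k) {
  n <- nrow(x)
  ids <- sample.int(n, 1L)
  while (length(ids) < k) {
    d2 <- pmax(apply(.sqDistToCenters(x, x[ids, , drop = FALSE]), 1, min), 0)
    if (sum(d2) == 0) ids <- c(ids, sample.int(n, 1L))
    else ids <- c(ids, sample.int(n, 1L, prob = d2))
  }
  ids
}

.sqDistToCenters <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 1, rowSums(x^2), "+"), 2,
        rowSums(centers^2), "+")
}

# Spectral clustering: kernlab's specc with an automatic Gaussian kernel;
# if specc fails on degenerate input, fall back to a plain normalized-cut
# implementation (Gaussian affinity with median-heuristic bandwidth,
# k-means on the leading eigenvectors of the normalized Laplacian).
.spectralCluster <- function(x, k = 2L) {
  res <- tryCatch(
    as.integer(kernlab::specc(as.matrix(x), centers = k)),
    error = function(e) NULL)
  if (!is.null(res) && length(unique(res)) == k) return(res)
  .normalizedCut(x, k)
}

.normalizedCut <- function(x, k = 2L) {
  n <- nrow(x)
  D2 <- .sqDistToCenters(x, x)
  D2[D2 < 0] <- 0
  sig2 <- stats::median(D2[upper.tri(D2)])
  if (sig2 <= 0) sig2 <- 1
  W <- exp(-D2 / (2 * sig2))
  diag(W) <- 0
  dg <- rowSums(W)
  dg[dg == 0] <- 1e-12
  S <- W / sqrt(dg %o% dg)
  V <- eigen(S, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  V <- V / pmax(sqrt(rowSums(V^2)), 1e-12)
  stats::kmeans(V, centers = k, nstart = 10L, iter.max = 100L)$cluster
}

# BIRCH-style clustering: stream points into clustering-feature (CF)
# subclusters under a merge threshold (rebuilt coarser when the leaf budget
# is exceeded), then group subcluster centroids by Ward linkage.
.birchCluster <- function(x, k = 2L, maxLeaves = 200L) {
  n <- nrow(x); p <- ncol(x)
  samp <- x[sample.int(n, min(n, 100L)), , drop = FALSE]
  thr <- stats::median(sqrt(pmax(.sqDistToCenters(samp, samp), 0))) / 4
  if (!is.finite(thr) || thr <= 0) thr <- 0.5
  repeat {
    cf_n <- integer(0)
    cf_sum <- matrix(0, 0, p)
    overflow <- FALSE
    memb <- integer(n)
    for (i in seq_len(n)) {
      if (nrow(cf_sum) == 0L) {
        cf_n <- 1L; cf_sum <- x[i, , drop = FALSE]; memb[i] <- 1L
        next
      }
      ctr <- cf_sum / cf_n
      d <- sqrt(pmax(.sqDistToCenters(x[i, , drop = FALSE], ctr), 0))
      j <- which.min(d)
      if (d[j] <= thr) {
        cf_n[j] <- cf_n[j] + 1L
        cf_sum[j, ] <- cf_sum[j, ] + x[i, ]
        memb[i] <- j
      } else {
        cf_n <- c(cf_n, 1L)
        cf_sum <- rbind(cf_sum, x[i, , drop = FALSE])
        memb[i] <- length(cf_n)
        if (length(cf_n) > maxLeaves) { overflow <- TRUE; break }
      }
    }
    if (!overflow) break
    thr <- thr * 1.5
  }
  ctr <- cf_sum / cf_n
  if (nrow(ctr) <= k) {
    leafCl <- seq_len(nrow(ctr))
  } else {
    leafCl <- cutree(hclust(dist(ctr), method = "ward.D2"), k = k)
  }
  as.integer(leafCl[memb])
}

#' Designate the RNA-like cluster from known-RNA labels
#'
#' The raw cluster holding the larger count of label-1 (known RNA) graphs
#' becomes the RNA-like cluster; a tied vote falls to the smaller cluster
#' and is flagged with a warning.  With \code{mode = "share"} the vote uses
#' the within-cluster percentage of labeled graphs instead of the raw
#' count.
#'
#' @param x feature matrix used for clustering (rownames = graph IDs).
#' @param assignment integer raw assignment from
#'   \code{\link{runClustering}}.
#' @param labels character vector of known-RNA graph IDs.
#' @param method clustering method name (metadata).
#' @param seed seed used (metadata).
#' @param mode \code{"majority"} (default) or \code{"share"}.
#' @return a \linkS4class{ClusterResult}.
#' @export
designateRnaLike <- function(x, assignment, labels, method = "unknown",
                             seed = 0L, mode = c("majority", "share")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) stop("feature matrix must carry graph IDs as rownames")
  stopifnot(length(assignment) == nrow(x))
  labeled <- ids %in% labels
  if (!any(labeled))
    stop("designation error: no labeled graph present in the feature table")
  votes <- vapply(1:2, function(k) sum(labeled & assignment == k), numeric(1))
  if (mode == "share") {
    sizes <- vapply(1:2, function(k) sum(assignment == k), numeric(1))
    votes <- ifelse(sizes > 0, votes / sizes, 0)
  }
  tie <- isTRUE(all.equal(votes[1], votes[2]))
  if (tie) {
    warning("RNA-like designation tied; choosing the smaller cluster")
    sizes <- vapply(1:2, function(k) sum(assignment == k), numeric(1))
    rna <- which.min(sizes)
  } else {
    rna <- which.max(votes)
  }
  centers <- rbind(colMeans(x[assignment == 1L, , drop = FALSE]),
                   colMeans(x[assignment == 2L, , drop = FALSE]))
  dists <- sqrt(pmax(.sqDistToCenters(x, centers), 0))
  new("ClusterResult", method = method, ids = ids, features = x,
      assignment = as.integer(assignment), rnaLikeCluster = as.integer(rna),
      centers = centers, distances = dists,
      labels = as.character(labels), seed = as.integer(seed), tie = tie)
}

#' @rdname ClusterResult-class
#' @param object a \code{ClusterResult}
#' @export
setGeneric("rnaLikeIds", function(object) standardGeneric("rnaLikeIds"))

#' @rdname ClusterResult-class
#' @export
setMethod("rnaLikeIds", "ClusterResult", function(object)
  object@ids[object@assignment == object@rnaLikeCluster])

setMethod("show", "ClusterResult", function(object) {
  nr <- sum(object@assignment == object@rnaLikeCluster)
  cat(sprintf(paste0("ClusterResult (%s, seed %d): %d graphs, ",
                     "%d in the RNA-like cluster (%.2f%%)\n"),
              object@method, object@seed, length(object@ids), nr,
              100 * nr / length(object@ids)))
})

#' Evaluate a two-way RNA-like clustering
#'
#' Sensitivity is the percentage of known-RNA graphs assigned to the
#' RNA-like cluster; the silhouette score measures cohesion versus
#' separation of the two clusters in feature space; homogeneity measures
#' how uniformly the known/hypothetical classes fall within clusters.  The
#' RNA-like share is reported both over all graphs and over hypothetical
#' graphs only.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @return one-row data.frame with columns \code{method},
#'   \code{sensitivity}, \code{silhouette}, \code{homogeneity},
#'   \code{rna_like_share}, \code{rna_like_share_hypothetical}.
#' @export
evaluateClustering <- function(result) {
  stopifnot(is(result, "ClusterResult"))
  labeled <- result@ids %in% result@labels
  inRna <- result@assignment == result@rnaLikeCluster
  sens <- 100 * sum(labeled & inRna) / sum(labeled)
  sil <- mean(cluster::silhouette(result@assignment,
                                  dist(result@features))[, "sil_width"])
  hom <- .homogeneity(classes = labeled, clusters = result@assignment)
  data.frame(method = result@method,
             sensitivity = sens,
             silhouette = sil,
             homogeneity = hom,
             rna_like_share = 100 * mean(inRna),
             rna_like_share_hypothetical =
               100 * sum(inRna & !labeled) / max(sum(!labeled), 1L),
             stringsAsFactors = FALSE)
}

# homogeneity score h = 1 - H(C|K)/H(C), natural logs; 1 when H(C) = 0
.homogeneity <- function(classes, clusters) {
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  n <- length(classes)
  hC <- ent(table(classes) / n)
  if (hC == 0) return(1)
  hCK <- 0
  for (k in unique(clusters)) {
    sel <- clusters == k
    hCK <- hCK + sum(sel) / n * ent(table(classes[sel]) / sum(sel))
  }
  1 - hCK / hC
}

#' Rank hypothetical graphs by distance to a cluster center
#'
#' The closer a hypothetical topology lies to the RNA-like cluster center,
#' the more RNA-like it is considered.  Only unlabeled (hypothetical)
#' members of the chosen cluster are ranked, by ascending Euclidean
#' distance; ties break by graph ID.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param which \code{"rna_like"} or \code{"non_rna_like"}.
#' @param k number of top graphs (default 15).
#' @return data.frame with columns \code{id}, \code{distance}.
#' @export
rankByCenter <- function(result, which = c("rna_like", "non_rna_like"),
                         k = 15L) {
  stopifnot(is(result, "ClusterResult"))
  which <- match.arg(which)
  cl <- if (which == "rna_like") result@rnaLikeCluster else
    3L - result@rnaLikeCluster
  sel <- result@assignment == cl & !(result@ids %in% result@labels)
  d <- result@distances[sel, cl]
  ids <- result@ids[sel]
  ord <- order(d, ids)
  if (sum(sel) < k)
    warning("only ", sum(sel), " hypothetical graphs in the ", which,
            " cluster; returning all of them")
  top <- head(ord, k)
  data.frame(id = ids[top], distance = unname(d[top]),
             stringsAsFactors = FALSE)
}

#' Consensus of per-method top-k rankings
#'
#' @param rankings list of rankings (data.frames from
#'   \code{\link{rankByCenter}} or character ID vectors), one per method.
#' @param minMethods minimum number of lists an ID must appear in.
#' @return data.frame with columns \code{id}, \code{count}, sorted by
#'   decreasing count then ID.
#' @export
consensusTop <- function(rankings, minMethods = 3L) {
  if (length(rankings) < minMethods)
    stop("need at least ", minMethods, " rankings")
  idsets <- lapply(rankings, function(r)
    unique(if (is.data.frame(r)) r$id else as.character(r)))
  tab <- table(unlist(idsets))
  keep <- tab[tab >= minMethods]
  out <- data.frame(id = names(keep), count = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$id), , drop = FALSE]
}

#' Two-component PCA embedding for visualization
#'
#' Clustering operates on the full 19-dimensional feature space; this
#' embedding is for plotting only.
#'
#' @param x numeric feature matrix (standardized).
#' @param components number of components (default 2).
#' @return score matrix (n x components) with attribute
#'   \code{explainedVariance}.
#' @export
pcaEmbed <- function(x, components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < components) stop("fewer rows than components")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(components, ncol(pc$x))
  out <- pc$x[, seq_len(k), drop = FALSE]
  attr(out, "explainedVariance") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Count later-confirmed graphs inside the RNA-like cluster
#'
#' Given a clustering trained with an earlier-vintage label set and a later
#' label set, counts the later-vintage-only IDs that fall in the RNA-like
#' cluster, grouped by vertex count.
#'
#' @param result a \linkS4class{ClusterResult} (trained on earlier labels).
#' @param laterLabels character vector of later-vintage known-RNA IDs.
#' @return data.frame with columns \code{vertices}, \code{confirmed}.
#' @export
validateAgainst <- function(result, laterLabels) {
  stopifnot(is(result, "ClusterResult"))
  newIds <- setdiff(laterLabels, result@labels)
  confirmed <- intersect(newIds, rnaLikeIds(result))
  nAll <- as.integer(sub("_.*", "", result@ids))
  tab <- table(factor(as.integer(sub("_.*", "", confirmed)),
                      levels = sort(unique(nAll))))
  data.frame(vertices = as.integer(names(tab)),
             confirmed = as.integer(tab))
}

#' Split a feature table into the vertex-grouped datasets
#'
#' Builds the analysis datasets grouped by vertex count: \code{"V4&5"}
#' (4- and 5-vertex graphs pooled against data imbalance), \code{"V6"} ..
#' \code{"V9"}, and \code{"All"} (union of 4..9).  Vertices 2 and 3 are
#' excluded from clustering analysis.
#'
#' @param features feature data.frame with an \code{id} column.
#' @param which dataset names to build (default: all six).
#' @param allowPartial when TRUE, \code{"All"} is the union of whatever
#'   vertex counts >= 4 are present instead of requiring the full 4..9
#'   range.
#' @return named list of feature data.frames.
#' @export
makeDatasets <- function(features,
                         which = c("V4&5", "V6", "V7", "V8", "V9", "All"),
                         allowPartial = FALSE) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  nv <- as.integer(sub("_.*", "", features$id))
  need <- list("V4&5" = 4:5, "V6" = 6L, "V7" = 7L, "V8" = 8L, "V9" = 9L,
               "All" = 4:9)
  out <- list()
  for (w in which) {
    if (!w %in% names(need)) stop("unknown dataset name: ", w)
    rng <- need[[w]]
    if (!allowPartial && !all(rng %in% nv))
      stop("dataset ", w, " needs vertex counts ",
           paste(rng, collapse = ","), " in the feature table")
    out[[w]] <- features[nv %in% rng, , drop = FALSE]
  }
  out
}
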