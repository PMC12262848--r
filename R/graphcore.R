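# Dual-graph data model: validity, canonical forms, enumeration, spectra.

# Returns NULL when A is a valid dual-graph adjacency matrix, otherwise a
# message describing the first violated invariant.  Structural errors
# (non-square, non-integer) raise immediately.
.dualGraphProblem <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix")
  if (nrow(A) < 2L) return("a dual graph has at least 2 vertices")
  if (!is.numeric(A) || any(!is.finite(A)) || any(A != round(A)))
    stop("adjacency must contain finite integer values")
  A <- round(A)
  n <- nrow(A)
  if (!isTRUE(all.equal(A, t(A)))) return("adjacency must be symmetric")
  if (!all(diag(A) %in% c(0, 2)))
    return("diagonal entries (self-loops) must be 0 or 2")
  off <- A[upper.tri(A)]
  if (any(off < 0) || any(off > 3))
    return("off-diagonal entries must lie in 0..3")
  deg <- rowSums(A)
  if (any(deg > 4)) return("per-vertex degree must not exceed 4")
  if (sum(A) != 4 * n - 2)
    return(sprintf("total degree must equal 4n - 2 = %d (got %d)",
                   4 * n - 2, sum(A)))
  if (!.cppIsConnected(.asIntMatrix(A))) return("graph must be connected")
  NULL
}

.asIntMatrix <- function(A) {
  storage.mode(A) <- "integer"
  A
}

#' Test whether a matrix is a valid dual-graph adjacency matrix
#'
#' A valid dual graph is a connected multigraph whose adjacency matrix is
#' symmetric with diagonal entries in \{0, 2\} (at most one self-loop per
#' vertex), off-diagonal entries in 0..3, per-vertex degree (row sum) at
#' most 4, and total degree exactly \eqn{4n - 2}.
#'
#' @param A square integer matrix.
#' @return \code{TRUE} or \code{FALSE}.  Non-square or non-integer input is
#'   an error.
#' @examples
#' isValidDualGraph(rbind(c(0, 3), c(3, 0)))  # TRUE: kissing hairpins
#' isValidDualGraph(rbind(c(0, 1), c(1, 0)))  # FALSE: degree sum too small
#' @export
isValidDualGraph <- function(A) {
  is.null(.dualGraphProblem(A))
}

#' Construct a DualGraph
#'
#' @param A square integer adjacency matrix satisfying the dual-graph
#'   invariants (see \code{\link{isValidDualGraph}}).
#' @param id optional graph ID string \code{"a_k"}.
#' @return a \linkS4class{DualGraph}.
#' @examples
#' g <- DualGraph(rbind(c(2, 1), c(1, 2)))
#' nVertices(g)
#' @export
DualGraph <- function(A, id = NA_character_) {
  msg <- .dualGraphProblem(A)
  if (!is.null(msg)) stop("invalid dual graph: ", msg)
  new("DualGraph", adjacency = .asIntMatrix(as.matrix(A)),
      id = as.character(id))
}

#' @describeIn DualGraph-class adjacency matrix accessor
#' @param object,x a \code{DualGraph}
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname DualGraph-class
#' @export
setMethod("adjacency", "DualGraph", function(object) object@adjacency)

#' @rdname DualGraph-class
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))

#' @rdname DualGraph-class
#' @export
setMethod("nVertices", "DualGraph", function(object) nrow(object@adjacency))

#' @rdname DualGraph-class
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname DualGraph-class
#' @export
setMethod("edgeCount", "DualGraph", function(object) {
  A <- object@adjacency
  as.integer(sum(A[upper.tri(A)]) + sum(diag(A)) / 2)
})

#' @rdname DualGraph-class
#' @export
setGeneric("graphId", function(object) standardGeneric("graphId"))

#' @rdname DualGraph-class
#' @export
setMethod("graphId", "DualGraph", function(object) object@id)

setMethod("show", "DualGraph", function(object) {
  n <- nVertices(object)
  cat(sprintf("DualGraph %s: %d vertices, %d edges, %d self-loop(s)\n",
              ifelse(is.na(object@id), "<unranked>", object@id),
              n, edgeCount(object), sum(diag(object@adjacency)) / 2))
  print(object@adjacency)
})

#' Canonical form of a dual graph
#'
#' Deterministic string key such that two dual graphs have equal keys if and
#' only if they are isomorphic as vertex-labeled multigraphs with
#' self-loops.  Computed as the lexicographically smallest upper-triangle
#' encoding over all vertex orderings compatible with an iterated
#' colour-refinement partition (a small canonical-labelling search).
#'
#' @param g a \linkS4class{DualGraph}, or a raw adjacency matrix.
#' @return character scalar key.
#' @examples
#' g <- DualGraph(rbind(c(0, 3), c(3, 0)))
#' canonicalForm(g)
#' @export
canonicalForm <- function(g) {
  A <- if (is(g, "DualGraph")) adjacency(g) else .asIntMatrix(as.matrix(g))
  .cppCanonicalKey(A)
}

#' Multigraph Laplacian of a dual graph
#'
#' Standard multigraph Laplacian \eqn{L = D - A_{off}}: self-loops cancel
#' (they contribute equally to degree and adjacency), multi-edges weight
#' entries by multiplicity.  Rows sum to zero and \eqn{L} is positive
#' semidefinite.
#'
#' @param g a \linkS4class{DualGraph}.
#' @return numeric symmetric matrix.
#' @examples
#' graphLaplacian(DualGraph(rbind(c(2, 1), c(1, 2))))
#' @export
graphLaplacian <- function(g) {
  A <- adjacency(g)
  Aoff <- A
  diag(Aoff) <- 0L
  diag(rowSums(Aoff)) - Aoff
}

#' Fiedler number (algebraic connectivity)
#'
#' Second-smallest eigenvalue of the multigraph Laplacian; strictly
#' positive for connected graphs.  Used to rank graph IDs within a vertex
#' count.
#'
#' @param g a \linkS4class{DualGraph}.
#' @return non-negative numeric scalar.
#' @examples
#' fiedlerNumber(DualGraph(rbind(c(0, 3), c(3, 0))))  # 6
#' @export
fiedlerNumber <- function(g) {
  ev <- eigen(graphLaplacian(g), symmetric = TRUE, only.values = TRUE)$values
  lambda2 <- sort(ev)[2]
  if (lambda2 < 1e-9)
    stop("Fiedler number is zero: graph is disconnected (contract violation)")
  lambda2
}

#' Enumerate all non-isomorphic dual-graph topologies
#'
#' Exhaustively generates every isomorphism class of valid dual graphs with
#' \code{n} vertices (backtracking over upper-triangle entries with degree
#' pruning; isomorph rejection by canonical form), then assigns graph IDs by
#' ascending Fiedler number via \code{\link{assignIds}}.
#'
#' @param n vertex count (>= 2; values up to 7 are routine, 8 and 9 are
#'   long-running batch jobs).
#' @param order ID ordering passed to \code{\link{assignIds}}.
#' @return a \linkS4class{GraphCatalog}.
#' @examples
#' cat2 <- enumerateDualGraphs(2)
#' length(cat2)  # 3
#' @export
enumerateDualGraphs <- function(n, order = c("ascending", "descending")) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("vertex count must be a single integer >= 2")
  order <- match.arg(order)
  mats <- .cppEnumerate(as.integer(n))
  graphs <- lapply(mats, DualGraph)
  cat0 <- new("GraphCatalog", graphs = graphs,
              ids = rep(NA_character_, length(graphs)),
              metadata = list(
                vertexRange = as.integer(n),
                rules = "connected; <=1 self-loop; multiplicity <= 3; degree <= 4; total degree 4n-2",
                idOrder = order,
                tool = paste0("DualGraphClust ",
                              as.character(utils::packageVersion("DualGraphClust")))))
  assignIds(cat0, order = order)
}

#' Assign graph IDs by Fiedler-number rank
#'
#' Within a single-vertex-count catalog, ranks graphs by Fiedler number
#' (ascending by default, so \code{a_1} is the topology with the smallest
#' algebraic connectivity).  Fiedler values equal within \code{tol} are
#' tie-broken by lexicographic comparison of the full sorted Laplacian
#' spectrum, then by canonical-form key, making the assignment deterministic
#' and independent of input order.
#'
#' @param catalog a \linkS4class{GraphCatalog} whose members share one
#'   vertex count.
#' @param order \code{"ascending"} (default) or \code{"descending"} Fiedler
#'   rank.
#' @param tol numeric tolerance for Fiedler comparison.
#' @return the catalog with IDs \code{"a_k"} assigned and members sorted by
#'   rank.
#' @export
assignIds <- function(catalog, order = c("ascending", "descending"),
                      tol = 1e-9) {
  stopifnot(is(catalog, "GraphCatalog"))
  order <- match.arg(order)
  ns <- vapply(catalog@graphs, nVertices, integer(1))
  if (length(unique(ns)) > 1L)
    stop("assignIds requires a catalog of a single vertex count")
  n <- ns[1]
  spectra <- lapply(catalog@graphs, function(g)
    sort(eigen(graphLaplacian(g), symmetric = TRUE, only.values = TRUE)$values))
  fiedler <- vapply(spectra, `[`, numeric(1), 2L)
  keys <- vapply(catalog@graphs, canonicalForm, character(1))
  # round Fiedler to the tie tolerance, then spectrum, then canonical key
  fbin <- round(fiedler / tol)
  specstr <- vapply(spectra, function(s)
    paste(sprintf("%.9f", s), collapse = ","), character(1))
  ord <- order(fbin, specstr, keys)
  if (order == "descending") ord <- rev(ord)
  graphs <- catalog@graphs[ord]
  ids <- sprintf("%d_%d", n, seq_along(graphs))
  graphs <- mapply(function(g, id) { g@id <- id; g },
                   graphs, ids, SIMPLIFY = FALSE)
  new("GraphCatalog", graphs = graphs, ids = ids,
      metadata = c(catalog@metadata[setdiff(names(catalog@metadata), "idOrder")],
                   list(idOrder = order)))
}

#' Combine single-vertex-count catalogs
#'
#' @param ... \linkS4class{GraphCatalog} objects with disjoint ID sets.
#' @return one \linkS4class{GraphCatalog}.
#' @export
combineCatalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1L && is.list(cats[[1]]) && !is(cats[[1]], "GraphCatalog"))
    cats <- cats[[1]]
  stopifnot(all(vapply(cats, is, logical(1), "GraphCatalog")))
  new("GraphCatalog",
      graphs = do.call(c, lapply(cats, slot, "graphs")),
      ids = do.call(c, lapply(cats, slot, "ids")),
      metadata = list(
        vertexRange = sort(unique(unlist(lapply(cats, function(x)
          x@metadata$vertexRange)))),
        rules = cats[[1]]@metadata$rules,
        idOrder = cats[[1]]@metadata$idOrder,
        tool = cats[[1]]@metadata$tool))
}

#' @rdname GraphCatalog-class
#' @param object,x a \code{GraphCatalog}
#' @export
setGeneric("graphIds", function(object) standardGeneric("graphIds"))

#' @rdname GraphCatalog-class
#' @export
setMethod("graphIds", "GraphCatalog", function(object) object@ids)

#' @rdname GraphCatalog-class
#' @export
setGeneric("vertexCounts", function(object) standardGeneric("vertexCounts"))

#' @rdname GraphCatalog-class
#' @export
setMethod("vertexCounts", "GraphCatalog", function(object)
  vapply(object@graphs, nVertices, integer(1)))

setMethod("length", "GraphCatalog", function(x) length(x@graphs))

setMethod("[[", "GraphCatalog", function(x, i) {
  if (is.character(i)) {
    j <- match(i, x@ids)
    if (is.na(j)) stop("no graph with ID '", i, "' in catalog")
    return(x@graphs[[j]])
  }
  x@graphs[[i]]
})

setMethod("show", "GraphCatalog", function(object) {
  ns <- vertexCounts(object)
  cat(sprintf("GraphCatalog: %d dual graphs, vertex counts %s\n",
              length(object),
              paste(range(ns), collapse = "..")))
  tab <- table(ns)
  cat("  per vertex count:",
      paste(sprintf("n=%s:%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})
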