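#' DualGraph: a coarse-grained RNA topology
#'
#' An RNA dual graph stores one vertex per double-helical stem and one edge
#' per connecting single strand.  The adjacency matrix follows the standard
#' dual-graph convention: diagonal entries are 2 for a vertex carrying a
#' self-loop (hairpin) and 0 otherwise; off-diagonal entries count the
#' strands connecting two stems (0 to 3).  A valid dual graph is connected,
#' has per-vertex degree (row sum) at most 4 -- a helix exposes four strand
#' ends -- and total degree exactly 4n - 2, because the chain 5' and 3'
#' termini carry no edge.
#'
#' @slot adjacency integer matrix, the symmetric adjacency matrix.
#' @slot id character, the graph ID \code{"a_k"} or \code{NA} when the graph
#'   has not been placed in a catalog.
#' @exportClass DualGraph
setClass("DualGraph",
  representation(adjacency = "matrix", id = "character"),
  prototype(adjacency = matrix(integer(0), 0, 0), id = NA_character_)
)

setValidity("DualGraph", function(object) {
  A <- object@adjacency
  msg <- .dualGraphProblem(A)
  if (!is.null(msg)) return(msg)
  if (length(object@id) != 1L) return("'id' must be a single character value")
  TRUE
})

#' GraphCatalog: an ID-indexed set of non-isomorphic dual graphs
#'
#' Ordered mapping from graph IDs (\code{"a_k"}) to \linkS4class{DualGraph}
#' objects, together with generation metadata.  Members of a catalog are
#' pairwise non-isomorphic.
#'
#' @slot graphs list of \linkS4class{DualGraph}.
#' @slot ids character vector of graph IDs, parallel to \code{graphs}.
#' @slot metadata list of generation parameters (vertex range, rule set,
#'   package version).
#' @exportClass GraphCatalog
setClass("GraphCatalog",
  representation(graphs = "list", ids = "character", metadata = "list"),
  prototype(graphs = list(), ids = character(0), metadata = list())
)

setValidity("GraphCatalog", function(object) {
  if (length(object@graphs) != length(object@ids))
    return("'graphs' and 'ids' must have equal length")
  if (anyDuplicated(object@ids[!is.na(object@ids)]))
    return("graph IDs must be unique")
  if (!all(vapply(object@graphs, is, logical(1), "DualGraph")))
    return("all members must be DualGraph objects")
  TRUE
})

#' ClusterResult: a two-way RNA-like partition of a feature table
#'
#' Produced by \code{\link{designateRnaLike}} from a raw two-cluster
#' assignment.  The RNA-like cluster is the one holding the majority of the
#' known-RNA (label 1) graphs; distances are Euclidean in the standardized
#' feature space.
#'
#' @slot method character, clustering algorithm name.
#' @slot ids character, graph IDs (row order of \code{features}).
#' @slot features matrix, the (standardized) feature matrix clustered.
#' @slot assignment integer, raw cluster index (1 or 2) per graph.
#' @slot rnaLikeCluster integer, which raw cluster is RNA-like.
#' @slot centers matrix, 2 x p cluster centroids in feature space.
#' @slot distances matrix, n x 2 Euclidean distances to both centers.
#' @slot labels character, the known-RNA graph IDs used for designation.
#' @slot seed integer, random seed used by the clustering run.
#' @slot tie logical, TRUE when the designation vote was tied.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(method = "character", ids = "character",
                 features = "matrix", assignment = "integer",
                 rnaLikeCluster = "integer", centers = "matrix",
                 distances = "matrix", labels = "character",
                 seed = "integer", tie = "logical")
)

setValidity("ClusterResult", function(object) {
  n <- length(object@ids)
  if (length(object@assignment) != n) return("assignment length mismatch")
  if (!all(object@assignment %in% c(1L, 2L)))
    return("assignment must take values 1 and 2")
  if (!object@rnaLikeCluster %in% c(1L, 2L))
    return("rnaLikeCluster must be 1 or 2")
  if (nrow(object@distances) != n || ncol(object@distances) != 2L)
    return("distances must be n x 2")
  if (any(object@distances < 0)) return("distances must be non-negative")
  TRUE
})

#' DecompositionResult: separability of a dual graph into sub-dual-graphs
#'
#' Records whether a dual graph can be partitioned into smaller valid dual
#' graphs by vertex-sharing splits (a split vertex is duplicated into both
#' parts) and, if so, the multiset of sub-dual-graphs collected at all
#' scales.
#'
#' @slot sourceId character, ID of the decomposed graph (or NA).
#' @slot separable logical.
#' @slot subgraphs list of \linkS4class{DualGraph} parts (all scales,
#'   deduplicated by canonical form).
#' @slot subgraphIds character, catalog IDs of the parts (NA when the part
#'   could not be resolved against a catalog).
#' @exportClass DecompositionResult
setClass("DecompositionResult",
  representation(sourceId = "character", separable = "logical",
                 subgraphs = "list", subgraphIds = "character")
)

setValidity("DecompositionResult", function(object) {
  if (object@separable != (length(object@subgraphs) > 0L))
    return("separable must match non-emptiness of the subgraph list")
  if (length(object@subgraphs) != length(object@subgraphIds))
    return("subgraphs and subgraphIds must have equal length")
  TRUE
})
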