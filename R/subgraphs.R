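# Separability of dual graphs into smaller valid dual graphs.
#
# Split model: vertex-sharing.  A split chooses a vertex v whose removal
# disconnects the rest; v is duplicated into both parts together with its
# edges to each side, so part sizes satisfy n1 + n2 = n + 1.  Because the
# two sides share no edges, no edge cut (in particular no pseudoknot
# 3-edge-cut) is severed: pseudoknotted pairs always land in one part.
# Degree bookkeeping of the shared vertex: a self-loop on v is retained in
# both parts; when v carries no self-loop, exactly one part gains a loop at
# v (the cut strands close into a hairpin), which is what the part degree
# sums 4k - 2 require.  Only splits whose two parts are both valid dual
# graphs are accepted.

# all single vertex-sharing splits of adjacency A into two valid parts;
# when firstOnly, return as soon as one is found
.validSplits <- function(A, firstOnly = FALSE) {
  n <- nrow(A)
  out <- list()
  if (n < 3L) return(out)
  for (v in seq_len(n)) {
    rest <- setdiff(seq_len(n), v)
    comp <- .componentsOf(A[rest, rest, drop = FALSE])
    if (max(comp) < 2L) next
    ncomp <- max(comp)
    # group components into two non-empty sides
    for (msk in seq_len(2^(ncomp - 1L) - 1L)) {
      side1 <- which(bitwAnd(msk, 2^(seq_len(ncomp) - 1L)) > 0)
      S <- rest[comp %in% side1]
      Tv <- rest[!comp %in% side1]
      loopOpts <- if (A[v, v] == 2L) list(c(2L, 2L)) else
        list(c(2L, 0L), c(0L, 2L))
      for (lo in loopOpts) {
        P1 <- A[c(S, v), c(S, v), drop = FALSE]
        P2 <- A[c(Tv, v), c(Tv, v), drop = FALSE]
        P1[length(S) + 1L, length(S) + 1L] <- lo[1]
        P2[length(Tv) + 1L, length(Tv) + 1L] <- lo[2]
        if (isValidDualGraph(P1) && isValidDualGraph(P2)) {
          out[[length(out) + 1L]] <- list(part1 = P1, part2 = P2)
          if (firstOnly) return(out)
        }
      }
    }
  }
  out
}

# connected components of a multigraph adjacency (labels 1..k)
.componentsOf <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(integer(0))
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    stack <- s
    comp[s] <- k
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- which(A[v, ] > 0 & comp == 0L & seq_len(n) != v)
      comp[nb] <- k
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Decompose a dual graph into sub-dual-graphs
#'
#' Searches vertex-sharing splits (the split vertex is duplicated into both
#' parts; self-loop bookkeeping follows the part degree sums) and keeps
#' only splits where both parts are valid dual graphs.  Valid parts are
#' decomposed recursively, so the result collects sub-dual-graphs at all
#' scales, deduplicated by canonical form.  A graph with no valid split is
#' irreducible.  Because the two sides of a split share no edges, junctions
#' and pseudoknot (3-edge-cut) blocks are preserved inside single parts.
#'
#' @param g a \linkS4class{DualGraph}.
#' @param catalog optional \linkS4class{GraphCatalog} used to resolve parts
#'   to graph IDs via canonical form.
#' @return a \linkS4class{DecompositionResult}.
#' @examples
#' decomposeGraph(DualGraph(rbind(c(0, 3), c(3, 0))))  # irreducible
#' @export
decomposeGraph <- function(g, catalog = NULL) {
  stopifnot(is(g, "DualGraph"))
  seen <- new.env(parent = emptyenv())
  collect <- list()
  recurse <- function(A) {
    for (sp in .validSplits(A)) {
      for (P in sp) {
        key <- canonicalForm(P)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          collect[[length(collect) + 1L]] <<- DualGraph(P)
          recurse(P)
        }
      }
    }
  }
  recurse(adjacency(g))
  ids <- rep(NA_character_, length(collect))
  if (!is.null(catalog) && length(collect)) {
    catKeys <- vapply(catalog@graphs, canonicalForm, character(1))
    ids <- graphIds(catalog)[match(
      vapply(collect, canonicalForm, character(1)), catKeys)]
    collect <- mapply(function(gg, id) { gg@id <- id; gg },
                      collect, ids, SIMPLIFY = FALSE)
  }
  # order parts by vertex count then id/key for stable output
  if (length(collect)) {
    ord <- order(vapply(collect, nVertices, integer(1)),
                 ifelse(is.na(ids), "~", ids),
                 vapply(collect, canonicalForm, character(1)))
    collect <- collect[ord]; ids <- ids[ord]
  }
  new("DecompositionResult", sourceId = graphId(g),
      separable = length(collect) > 0L,
      subgraphs = collect, subgraphIds = ids)
}

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("DecompositionResult for %s: %s\n",
              ifelse(is.na(object@sourceId), "<unranked>", object@sourceId),
              if (object@separable) "separable" else "irreducible"))
  if (object@separable)
    cat("  subgraphs:",
        paste(ifelse(is.na(object@subgraphIds),
                     sprintf("<%d-vertex>", vapply(object@subgraphs,
                                                   nVertices, integer(1))),
                     object@subgraphIds), collapse = ", "), "\n")
})

#' Is a dual graph separable?
#'
#' Cheap test that stops at the first valid vertex-sharing split.
#'
#' @param g a \linkS4class{DualGraph}.
#' @return logical.
#' @export
isSeparable <- function(g) {
  length(.validSplits(adjacency(g), firstOnly = TRUE)) > 0L
}

#' Separability profile of a graph collection
#'
#' @param graphs catalog, list of \linkS4class{DualGraph}, or single graph.
#' @return list with \code{flags} (data.frame \code{id},
#'   \code{separable}) and \code{fraction} (separable share in [0, 1]).
#' @export
separabilityProfile <- function(graphs) {
  gl <- .asGraphList(graphs)
  flags <- data.frame(
    id = vapply(gl, graphId, character(1)),
    separable = vapply(gl, isSeparable, logical(1)),
    stringsAsFactors = FALSE)
  list(flags = flags, fraction = mean(flags$separable))
}
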