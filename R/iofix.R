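# File formats, synthetic label fixtures and pipeline orchestration.

#' Write / read a graph catalog as TSV (+ JSON metadata sidecar)
#'
#' Columns: \code{id}, \code{n}, \code{adjacency} (row-major comma-separated
#' integers).  Generation metadata goes to \code{<path>.meta.json}.
#'
#' @param catalog a \linkS4class{GraphCatalog}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "GraphCatalog"))
  df <- data.frame(
    id = graphIds(catalog),
    n = vertexCounts(catalog),
    adjacency = vapply(catalog@graphs, function(g)
      paste(as.vector(t(adjacency(g))), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(catalog@metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character"))
  graphs <- mapply(function(id, n, adj) {
    v <- as.integer(strsplit(adj, ",")[[1]])
    if (length(v) != n * n) stop("bad adjacency length for ", id)
    DualGraph(matrix(v, n, n, byrow = TRUE), id = id)
  }, df$id, df$n, df$adjacency, SIMPLIFY = FALSE)
  meta <- list()
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath))
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  new("GraphCatalog", graphs = unname(graphs), ids = df$id, metadata = meta)
}

#' Read / write a single adjacency matrix file
#'
#' Whitespace-delimited integer matrix, one row per line.
#'
#' @param path file path.
#' @return \code{readGraphMatrix}: integer matrix.
#' @export
readGraphMatrix <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  vals <- suppressWarnings(lapply(rows, as.integer))
  if (any(vapply(vals, anyNA, logical(1))))
    stop("non-integer entry in matrix file ", path)
  if (length(unique(lengths(vals))) != 1L)
    stop("ragged rows in matrix file ", path)
  do.call(rbind, vals)
}

#' @rdname readGraphMatrix
#' @param A integer matrix to write.
#' @export
writeGraphMatrix <- function(A, path) {
  writeLines(apply(A, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read / write a known-RNA label list
#'
#' One graph ID (\code{"a_k"}) per line; \code{#} starts a comment; blank
#' lines are ignored.  Malformed IDs raise an error naming the line; when a
#' catalog is supplied, unknown IDs are reported with their line numbers.
#'
#' @param path file path.
#' @param catalog optional \linkS4class{GraphCatalog} to resolve IDs
#'   against.
#' @return character vector of graph IDs with attribute
#'   \code{"provenance"}.
#' @export
readLabelList <- function(path, catalog = NULL) {
  raw <- readLines(path)
  stripped <- trimws(sub("#.*$", "", raw))
  keep <- which(nzchar(stripped))
  ids <- stripped[keep]
  bad <- !grepl("^[0-9]+_[0-9]+$", ids)
  if (any(bad))
    stop("malformed graph ID '", ids[which(bad)[1]], "' at line ",
         keep[which(bad)[1]], " of ", path)
  if (!is.null(catalog)) {
    unknown <- !ids %in% graphIds(catalog)
    if (any(unknown))
      stop("unknown graph ID '", ids[which(unknown)[1]], "' at line ",
           keep[which(unknown)[1]], " of ", path)
  }
  structure(unique(ids), provenance = path)
}

#' @rdname readLabelList
#' @param labels character vector of graph IDs.
#' @export
writeLabelList <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Default per-vertex-count known-RNA label counts
#'
#' Sizes mirroring the per-vertex-count numbers of graphs matched to solved
#' RNA structures in the earlier (2021-vintage, 111 graphs over n = 4..9)
#' and later (2022-vintage increment) reference datasets.
#'
#' @param vintage \code{"earlier"} or \code{"increment"} (later-only
#'   additions).
#' @return named integer vector (names = vertex counts).
#' @export
defaultLabelCounts <- function(vintage = c("earlier", "increment")) {
  vintage <- match.arg(vintage)
  switch(vintage,
    earlier  = c(`4` = 17L, `5` = 20L, `6` = 22L, `7` = 21L, `8` = 14L,
                 `9` = 17L),
    increment = c(`4` = 5L, `5` = 9L, `6` = 15L, `7` = 13L, `8` = 6L,
                  `9` = 11L))
}

# per-graph sampling weights: bias toward separable, Betti-1-free graphs
.labelWeights <- function(catalog, biasSeparable, biasNoBetti1) {
  vapply(catalog@graphs, function(g) {
    w <- 0
    if (biasSeparable != 0 && isSeparable(g)) w <- w + biasSeparable
    if (biasNoBetti1 != 0) {
      b1 <- bettiNumbers(g, maxQ = 1L, grid = 1:3)["q1", ]
      if (all(b1 == 0L)) w <- w + biasNoBetti1
    }
    exp(w)
  }, numeric(1))
}

#' Generate a synthetic known-RNA label set
#'
#' Seeded sample of graph IDs emulating a known-RNA label list: per-vertex-
#' count counts (defaulting to the earlier-vintage reference sizes) and a
#' bias toward separable, Betti-1-free graphs, the two signatures real
#' RNA-matched topologies show.
#'
#' @param catalog a \linkS4class{GraphCatalog} covering the requested
#'   vertex counts.
#' @param counts named integer vector, labels per vertex count (names =
#'   vertex counts).  Defaults to the earlier-vintage sizes; the catalog
#'   must cover every requested count.
#' @param biasSeparable,biasNoBetti1 log-weight increments (0 = uniform).
#' @param seed integer seed.
#' @return character vector of graph IDs with attributes
#'   \code{"provenance"} and \code{"seed"}.
#' @export
generateSyntheticLabels <- function(catalog,
                                    counts = defaultLabelCounts("earlier"),
                                    biasSeparable = 1.5,
                                    biasNoBetti1 = 1.5,
                                    seed = 0) {
  stopifnot(is(catalog, "GraphCatalog"))
  nv <- vertexCounts(catalog)
  w <- .labelWeights(catalog, biasSeparable, biasNoBetti1)
  ids <- graphIds(catalog)
  set.seed(as.integer(seed))
  out <- character(0)
  for (nm in names(counts)) {
    k <- counts[[nm]]
    pool <- which(nv == as.integer(nm))
    if (length(pool) < k)
      stop("requested ", k, " labels for n = ", nm, " but only ",
           length(pool), " graphs are available")
    pick <- if (k > 0) pool[sample.int(length(pool), k, prob = w[pool])]
            else integer(0)
    out <- c(out, ids[pick])
  }
  structure(out, provenance = sprintf("synthetic(seed=%d)", seed),
            seed = as.integer(seed))
}

#' Extend a label set with a disjoint later-vintage sample
#'
#' Emulates a later reference dataset: the earlier labels plus a seeded
#' disjoint sample of additional graphs (same bias), sized by
#' \code{counts}.
#'
#' @param catalog a \linkS4class{GraphCatalog}.
#' @param earlier character vector of earlier-vintage IDs.
#' @param counts named integer vector of additional labels per vertex
#'   count.
#' @param biasSeparable,biasNoBetti1,seed as in
#'   \code{\link{generateSyntheticLabels}}.
#' @return character vector (earlier plus additions), attribute
#'   \code{"provenance"}.
#' @export
extendSyntheticLabels <- function(catalog, earlier,
                                  counts = defaultLabelCounts("increment"),
                                  biasSeparable = 1.5, biasNoBetti1 = 1.5,
                                  seed = 1) {
  stopifnot(is(catalog, "GraphCatalog"))
  nv <- vertexCounts(catalog)
  ids <- graphIds(catalog)
  w <- .labelWeights(catalog, biasSeparable, biasNoBetti1)
  set.seed(as.integer(seed))
  out <- character(0)
  for (nm in names(counts)) {
    k <- counts[[nm]]
    pool <- which(nv == as.integer(nm) & !ids %in% earlier)
    if (length(pool) < k)
      stop("requested ", k, " additional labels for n = ", nm,
           " but only ", length(pool), " unlabeled graphs are available")
    pick <- if (k > 0) pool[sample.int(length(pool), k, prob = w[pool])]
            else integer(0)
    out <- c(out, ids[pick])
  }
  structure(c(as.character(earlier), out),
            provenance = sprintf("synthetic-later(seed=%d)", seed))
}

#' Pipeline configuration
#'
#' @param vertexRange integer vector of vertex counts to enumerate (>= 2
#'   entries are allowed; clustering uses counts >= 4).
#' @param methods clustering methods to run.
#' @param seed master seed (also used for synthetic labels).
#' @param labelFile,laterLabelFile optional label list paths; when NULL,
#'   synthetic labels are generated.
#' @param labelCounts,laterLabelCounts synthetic label sizes per vertex
#'   count (defaults restricted to \code{vertexRange}).
#' @param standardize z-score features before clustering.
#' @param includeZeros include zero eigenvalues in spectral statistics.
#' @param topK top-list size for center rankings.
#' @param minMethods consensus threshold.
#' @param outDir output directory.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(vertexRange = 4:6,
                           methods = c("kmeans", "minibatch_kmeans", "gmm",
                                       "ward", "spectral", "birch"),
                           seed = 0,
                           labelFile = NULL, laterLabelFile = NULL,
                           labelCounts = NULL, laterLabelCounts = NULL,
                           standardize = TRUE, includeZeros = TRUE,
                           topK = 15L, minMethods = 3L,
                           outDir = tempfile("dualgraph_run_")) {
  cl <- intersect(vertexRange, 4:9)
  if (is.null(labelCounts))
    labelCounts <- defaultLabelCounts("earlier")[as.character(cl)]
  if (is.null(laterLabelCounts))
    laterLabelCounts <- defaultLabelCounts("increment")[as.character(cl)]
  structure(list(vertexRange = sort(unique(as.integer(vertexRange))),
                 methods = match.arg(methods, clusterMethods(),
                                     several.ok = TRUE),
                 seed = as.integer(seed),
                 labelFile = labelFile, laterLabelFile = laterLabelFile,
                 labelCounts = labelCounts,
                 laterLabelCounts = laterLabelCounts,
                 standardize = isTRUE(standardize),
                 includeZeros = isTRUE(includeZeros),
                 topK = as.integer(topK), minMethods = as.integer(minMethods),
                 outDir = outDir),
            class = "PipelineConfig")
}

#' Run the full enumeration-to-ranking pipeline
#'
#' Stages: enumerate catalogs for the vertex range; featurize; build
#' vertex-grouped datasets; obtain known-RNA labels (from files or the
#' synthetic generator); run each clustering method on each dataset;
#' designate RNA-like clusters and evaluate; rank top RNA-like and
#' non-RNA-like hypothetical graphs; form per-dataset consensus lists;
#' compute barcode pattern flags and separability for the consensus
#' graphs; validate against the later-vintage label set.  All stage
#' outputs are written under \code{config$outDir} with deterministic
#' names.
#'
#' @param config a \code{"PipelineConfig"} from \code{\link{pipelineConfig}}.
#' @param catalog optional pre-built \linkS4class{GraphCatalog} (skips
#'   enumeration).
#' @return invisible list with the main in-memory artifacts (catalog,
#'   features, labels, metrics, rankings, consensus, validation).
#' @export
runPipeline <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file.path(config$outDir, "pipeline.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = logCon, append = TRUE)
  logln("pipeline start; seed=%d; vertices=%s", config$seed,
        paste(config$vertexRange, collapse = ","))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(catalog)) {
    catalog <- stage("enumerate", combineCatalogs(
      lapply(config$vertexRange, enumerateDualGraphs)))
  }
  writeCatalog(catalog, file.path(config$outDir, "catalog.tsv"))
  logln("enumerated %d graphs", length(catalog))

  features <- stage("featurize",
    featurizeCatalog(catalog, includeZeros = config$includeZeros))
  writeFeatureTable(features, file.path(config$outDir, "features.tsv"))

  labels <- stage("labels", {
    if (!is.null(config$labelFile))
      readLabelList(config$labelFile, catalog)
    else generateSyntheticLabels(catalog, counts = config$labelCounts,
                                 seed = config$seed)
  })
  writeLabelList(labels, file.path(config$outDir, "labels.txt"))
  laterLabels <- stage("labels_later", {
    if (!is.null(config$laterLabelFile))
      readLabelList(config$laterLabelFile, catalog)
    else extendSyntheticLabels(catalog, labels,
                               counts = config$laterLabelCounts,
                               seed = config$seed + 1L)
  })
  writeLabelList(laterLabels, file.path(config$outDir, "labels_later.txt"))

  clusterable <- intersect(config$vertexRange, 4:9)
  groups <- list()
  if (all(4:5 %in% clusterable)) groups[["V4&5"]] <- "V4&5"
  for (n in intersect(6:9, clusterable)) groups[[paste0("V", n)]] <- paste0("V", n)
  datasets <- stage("datasets", makeDatasets(
    features[as.integer(sub("_.*", "", features$id)) %in% clusterable, ],
    which = unlist(groups), allowPartial = FALSE))
  # pooled dataset over everything clusterable
  pooled <- features[as.integer(sub("_.*", "", features$id)) %in%
                       clusterable, , drop = FALSE]
  datasets[["All"]] <- pooled

  metrics <- list(); rankings <- list(); consensus <- list()
  results <- list()
  for (ds in names(datasets)) {
    x <- featureMatrix(datasets[[ds]])
    if (config$standardize) x <- standardizeFeatures(x)
    for (m in config$methods) {
      res <- tryCatch({
        a <- runClustering(x, m, seed = config$seed)
        designateRnaLike(x, a, labels, method = m, seed = config$seed)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        logln("dataset %s method %s: NA (%s)", ds, m,
              conditionMessage(res))
        next
      }
      results[[ds]][[m]] <- res
      metrics[[length(metrics) + 1L]] <-
        cbind(dataset = ds, evaluateClustering(res))
      rankings[[ds]][[m]] <- list(
        rna = rankByCenter(res, "rna_like", config$topK),
        non = rankByCenter(res, "non_rna_like", config$topK))
    }
    if (!is.null(rankings[[ds]])) {
      mm <- min(config$minMethods, length(rankings[[ds]]))
      if (mm < config$minMethods)
        logln("dataset %s: consensus threshold lowered to %d (methods run)",
              ds, mm)
      consensus[[ds]] <- list(
        rna = consensusTop(lapply(rankings[[ds]], `[[`, "rna"), mm),
        non = consensusTop(lapply(rankings[[ds]], `[[`, "non"), mm))
    }
  }
  metrics <- do.call(rbind, metrics)
  utils::write.table(metrics, file.path(config$outDir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics, file.path(config$outDir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (ds in names(rankings)) {
    for (m in names(rankings[[ds]])) {
      utils::write.table(rankings[[ds]][[m]]$rna,
        file.path(config$outDir,
                  sprintf("top_rna_like_%s_%s.tsv", gsub("&", "", ds), m)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (ds in names(consensus)) {
    jsonlite::write_json(consensus[[ds]],
      file.path(config$outDir,
                sprintf("consensus_%s.json", gsub("&", "", ds))),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  # topological signatures + separability of the pooled consensus graphs
  patterns <- NULL
  consensusIds <- unique(unlist(lapply(consensus, function(co)
    c(co$rna$id, co$non$id))))
  if (length(consensusIds)) {
    gl <- lapply(consensusIds, function(i) catalog[[i]])
    patterns <- merge(bettiPatternReport(gl), separabilityProfile(gl)$flags,
                      by = "id")
    utils::write.table(patterns,
      file.path(config$outDir, "consensus_patterns.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  validation <- NULL
  if (!is.null(results[["All"]][["kmeans"]])) {
    validation <- validateAgainst(results[["All"]][["kmeans"]], laterLabels)
    utils::write.table(validation,
      file.path(config$outDir, "validation_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  logln("pipeline done")
  invisible(list(catalog = catalog, features = features, labels = labels,
                 laterLabels = laterLabels, datasets = datasets,
                 results = results, metrics = metrics, rankings = rankings,
                 consensus = consensus, patterns = patterns,
                 validation = validation, config = config))
}

#' Write / read a feature table
#' @param features data.frame from \code{\link{featurizeCatalog}}.
#' @param path TSV path.
#' @export
writeFeatureTable <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
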