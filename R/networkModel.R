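#' Load an undirected interaction network from an edge list or SIF file
#'
#' TSV rows name two node ids (optional header `from<TAB>to`); SIF rows are
#' `source<TAB>interaction<TAB>target1 [target2 ...]`. The result is a simple
#' undirected graph: parallel edges are collapsed and self-loops dropped
#' (with a message giving the count).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"sif"`.
#' @return an `igraph` undirected simple graph.
#' @export
loadEdgeList <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty edge file: ", path)
    return(make_empty_graph(directed = FALSE))
  }
  edges <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (format == "tsv") {
      if (i == 1L && identical(tolower(f[1:2]), c("from", "to"))) next
      if (length(f) < 2L)
        stop(sprintf("edge row %d in %s has fewer than 2 fields", i, path))
      edges[[length(edges) + 1L]] <- cbind(f[1], f[2])
    } else {
      if (length(f) == 1L) next            # isolated node in SIF
      if (length(f) < 3L)
        stop(sprintf("SIF row %d in %s has fewer than 3 fields", i, path))
      edges[[length(edges) + 1L]] <- cbind(f[1], f[-(1:2)])
    }
  }
  em <- do.call(rbind, edges)
  if (is.null(em)) return(make_empty_graph(directed = FALSE))
  g <- graph_from_edgelist(em, directed = FALSE)
  nLoops <- sum(em[, 1] == em[, 2])
  if (nLoops) message("loadEdgeList: dropped ", nLoops, " self-loop(s)")
  simplify(g)
}

#' Induced signature subgraph on the interaction network
#'
#' Restricts the network to catalog features and discards every feature not
#' connected to at least one other member of the signature, i.e. isolated
#' nodes of the induced subgraph are removed.
#'
#' @param network an `igraph` undirected graph.
#' @param catalog a [FeatureCatalog][FeatureCatalog-class] or character
#'   vector of gene ids.
#' @return the induced `igraph` subgraph with all nodes of degree >= 1.
#' @export
inducedSignatureSubgraph <- function(network, catalog) {
  ids <- if (is(catalog, "FeatureCatalog")) featureTable(catalog)$gene_id
         else as.character(catalog)
  keep <- intersect(V(network)$name, ids)
  sg <- induced_subgraph(network, keep)
  induced_subgraph(sg, V(sg)$name[degree(sg) > 0])
}

#' Highest k-core of a graph
#'
#' Returns the maximum k for which a non-empty k-core (maximal subgraph with
#' all degrees >= k) exists, together with that core's node set.
#'
#' @param graph an `igraph` graph with at least one node.
#' @return list with elements `k` (integer) and `core` (character node ids).
#' @export
highestKCore <- function(graph) {
  if (vcount(graph) == 0L) stop("highestKCore: empty graph")
  cn <- coreness(graph)
  k <- max(cn)
  list(k = as.integer(k), core = sort(V(graph)$name[cn == k]))
}

#' MCODE vertex weight
#'
#' The MCODE weight of a vertex is `k * density(C)` where `C` is the highest
#' k-core of the closed neighborhood of the vertex (the vertex plus its
#' neighbors) and density uses the simple-graph formula
#' `2|E| / (|V| (|V| - 1))`. Isolated vertices have weight 0.
#'
#' @param graph an `igraph` graph.
#' @param v node name(s); default all vertices.
#' @return named numeric vector of weights.
#' @export
mcodeVertexWeight <- function(graph, v = NULL) {
  nodes <- V(graph)$name
  if (is.null(nodes)) stop("graph vertices must be named")
  if (is.null(v)) v <- nodes
  if (!all(v %in% nodes)) stop("vertex not in graph: ",
                               paste(setdiff(v, nodes), collapse = ", "))
  w <- vapply(v, function(vi) {
    nb <- as_ids(neighbors(graph, vi))
    if (!length(nb)) return(0)
    sub <- induced_subgraph(graph, c(vi, nb))
    cn <- coreness(sub)
    k <- max(cn)
    core <- induced_subgraph(sub, V(sub)$name[cn == k])
    nv <- vcount(core)
    dens <- if (nv < 2L) 0 else 2 * ecount(core) / (nv * (nv - 1))
    k * dens
  }, numeric(1))
  names(w) <- v
  w
}

#' MCODE parameters
#'
#' Canonical defaults of the published algorithm: vertex weight percentage
#' 0.2, haircut on (clusters trimmed to their own 2-core), fluff off,
#' maximum expansion depth 100.
#'
#' @param vwp vertex weight percentage in `[0, 1)`.
#' @param haircut logical; trim each cluster to its 2-core.
#' @param fluff logical; fluff post-processing is not supported and must
#'   stay `FALSE`.
#' @param fluffDensityThreshold retained for interface completeness.
#' @param maxDepth integer BFS expansion depth limit.
#' @return list of parameters, class `"McodeParams"`.
#' @export
mcodeParams <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                        fluffDensityThreshold = 0.2, maxDepth = 100L) {
  stopifnot(vwp >= 0, vwp < 1,
            fluffDensityThreshold > 0, fluffDensityThreshold <= 1,
            maxDepth >= 1)
  if (isTRUE(fluff))
    stop("fluff post-processing is not supported; set fluff = FALSE")
  structure(list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluffDensityThreshold = fluffDensityThreshold,
                 maxDepth = as.integer(maxDepth)),
            class = "McodeParams")
}

.graphDensity <- function(graph) {
  nv <- vcount(graph)
  if (nv < 2L) return(0)
  2 * ecount(graph) / (nv * (nv - 1))
}

#' MCODE molecular complex detection
#'
#' Seeds are taken in descending vertex-weight order (ties broken by
#' lexicographic node id). From each unassigned seed, breadth-first
#' expansion includes a neighbor if it is unassigned and its weight is at
#' least `seed_weight * (1 - vwp)`. With haircut on, each candidate cluster
#' is trimmed to its own 2-core; clusters with fewer than 3 nodes are
#' discarded. Clusters are scored `density * size` and returned in
#' decreasing score order; every node belongs to at most one cluster.
#'
#' @param graph an `igraph` undirected simple graph with named vertices.
#' @param params a list from [mcodeParams()].
#' @return data.frame (rank, score, size, members) where `members` is a
#'   list-column of node-id vectors.
#' @export
mcodeComplexes <- function(graph, params = mcodeParams()) {
  if (vcount(graph) == 0L) stop("mcodeComplexes: empty graph")
  w <- mcodeVertexWeight(graph)
  ord <- names(w)[order(-w, names(w))]
  assigned <- setNames(rep(FALSE, length(w)), names(w))
  clusters <- list()
  for (seed in ord) {
    if (assigned[seed] || w[seed] <= 0) next
    thr <- w[seed] * (1 - params$vwp)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$maxDepth) {
      nxt <- character()
      for (v in frontier) {
        nb <- sort(as_ids(neighbors(graph, v)))
        for (u in nb) {
          if (!assigned[u] && w[u] >= thr) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- induced_subgraph(graph, members)
    if (params$haircut) {
      cn <- coreness(sub)
      members <- V(sub)$name[cn >= 2]
      if (length(members)) sub <- induced_subgraph(graph, members)
    }
    if (length(members) < 3L) next
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(members), score = .graphDensity(sub) * length(members))
  }
  if (!length(clusters))
    return(data.frame(rank = integer(), score = numeric(), size = integer(),
                      members = I(list())))
  scores <- vapply(clusters, `[[`, numeric(1), "score")
  sizes <- vapply(clusters, function(x) length(x$members), integer(1))
  first <- vapply(clusters, function(x) x$members[1], character(1))
  o <- order(-scores, -sizes, first)
  data.frame(rank = seq_along(o), score = scores[o], size = sizes[o],
             members = I(lapply(clusters[o], `[[`, "members")),
             row.names = NULL)
}

#' Build the donor organ status molecular model
#'
#' Runs the construction workflow: induced signature subgraph of the catalog
#' on the interaction network, MCODE clustering of the subgraph into
#' molecular processes, and overrepresentation analysis of the cluster
#' member union against an annotation set. Stage counts are recorded for
#' reporting.
#'
#' @param network an `igraph` interaction network.
#' @param catalog a [FeatureCatalog][FeatureCatalog-class] or gene id vector.
#' @param annotations an [AnnotationSet][AnnotationSet-class], or `NULL` to
#'   skip enrichment.
#' @param params MCODE parameters from [mcodeParams()].
#' @param qThreshold FDR threshold for the enrichment flag.
#' @param mode hypergeometric mode, `"standard"` or `"ease"`.
#' @param background `"annotation"` (all genes of the annotation file,
#'   DAVID-like default) or `"network"` (interaction-network nodes).
#' @return a [MolecularModel][MolecularModel-class].
#' @export
buildMolecularModel <- function(network, catalog, annotations = NULL,
                                params = mcodeParams(), qThreshold = 0.05,
                                mode = c("standard", "ease"),
                                background = c("annotation", "network")) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  nInput <- if (is(catalog, "FeatureCatalog")) catalogSize(catalog)
            else length(unique(catalog))
  sg <- inducedSignatureSubgraph(network, catalog)
  emptyEnr <- data.frame(term = character(), k = integer(), n = integer(),
                         K = integer(), N = integer(), p = numeric(),
                         q = numeric(), flag = logical())
  if (vcount(sg) == 0L) {
    warning("buildMolecularModel: empty signature subgraph")
    return(new("MolecularModel", subgraph = sg, clusters = list(),
               scores = numeric(), enrichment = emptyEnr,
               stageCounts = c(input_features = as.integer(nInput),
                               connected_features = 0L, clusters = 0L,
                               cluster_members = 0L, enriched_terms = 0L)))
  }
  cl <- mcodeComplexes(sg, params)
  members <- sort(unique(unlist(cl$members, use.names = FALSE)))
  enr <- emptyEnr
  if (!is.null(annotations) && length(members)) {
    ann <- annotations
    if (background == "network")
      ann <- annotationSet(
        lapply(annotationTerms(ann), intersect, V(network)$name),
        background = intersect(annotationBackground(ann), V(network)$name),
        dropEmpty = TRUE)
    qm <- intersect(members, annotationBackground(ann))
    if (length(qm)) enr <- enrichTerms(qm, ann, qThreshold = qThreshold,
                                      mode = mode)
  }
  new("MolecularModel", subgraph = sg,
      clusters = unclass(cl$members), scores = cl$score, enrichment = enr,
      stageCounts = c(input_features = as.integer(nInput),
                      connected_features = as.integer(vcount(sg)),
                      clusters = as.integer(nrow(cl)),
                      cluster_members = as.integer(length(members)),
                      enriched_terms = as.integer(sum(enr$flag))))
}

#' Write MCODE clusters to TSV
#'
#' @param clusters data.frame from [mcodeComplexes()] or a
#'   [MolecularModel][MolecularModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClusters <- function(clusters, path) {
  if (is(clusters, "MolecularModel"))
    clusters <- data.frame(rank = seq_along(clusters@clusters),
                           score = clusters@scores,
                           size = lengths(clusters@clusters),
                           members = I(clusters@clusters))
  out <- data.frame(cluster_rank = clusters$rank, score = clusters$score,
                    size = clusters$size,
                    members = vapply(clusters$members, paste, character(1),
                                     collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
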