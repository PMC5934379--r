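#' FeatureCatalog: deduplicated gene features with per-source provenance
#'
#' A catalog of unique gene features merged from several evidence sources
#' (e.g. a literature-mined chronic allograft nephropathy set plus several
#' transcriptomics signatures). Each feature keeps the set of source tags it
#' was seen in; `provenance` records the original size of every input set.
#'
#' @slot features data.frame with columns `gene_id`, `symbol`, `sources`
#'   (semicolon-joined source tags), one row per unique gene.
#' @slot provenance named integer vector, source tag -> original set size.
#'
#' @seealso [mergeFeatureSets()], [catalogSize()], [featureTable()]
#' @exportClass FeatureCatalog
setClass("FeatureCatalog",
  representation(features = "data.frame", provenance = "integer"))

setValidity("FeatureCatalog", function(object) {
  ft <- object@features
  msg <- character()
  need <- c("gene_id", "symbol", "sources")
  if (!all(need %in% names(ft)))
    msg <- c(msg, sprintf("features must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(ft$gene_id))
      msg <- c(msg, "gene_id must be unique within a catalog")
    if (nrow(ft) && any(!nzchar(ft$gene_id)))
      msg <- c(msg, "gene_id must be non-empty")
    if (nrow(ft) && any(!nzchar(ft$sources)))
      msg <- c(msg, "every feature needs at least one source tag")
    tags <- unique(unlist(strsplit(ft$sources, ";", fixed = TRUE)))
    if (length(tags) && !all(tags %in% names(object@provenance)))
      msg <- c(msg, "all source tags must appear in provenance")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: term-to-gene annotations over a background population
#'
#' GO-style annotation sets used for overrepresentation analysis. Every
#' annotated gene must be part of the background population.
#'
#' @slot terms named list, term -> character vector of gene ids.
#' @slot background character vector of population gene ids.
#'
#' @seealso [annotationSet()], [enrichTerms()]
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(terms = "list", background = "character"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@terms)) {
    if (is.null(names(object@terms)) || any(!nzchar(names(object@terms))))
      msg <- c(msg, "terms must be named")
    if (any(lengths(object@terms) == 0L))
      msg <- c(msg, "terms must be non-empty gene sets")
    ann <- unique(unlist(object@terms, use.names = FALSE))
    if (!all(ann %in% object@background))
      msg <- c(msg, "every annotated gene must be in the background")
  }
  if (anyDuplicated(object@background))
    msg <- c(msg, "background gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' MolecularModel: MCODE clusters plus enrichment over a signature subgraph
#'
#' The donor organ status molecular model: the induced interaction subgraph
#' of the feature catalog, its MCODE clusters ("molecular processes"),
#' the union of cluster members, the overrepresented annotation terms, and
#' the stage counts of the construction workflow.
#'
#' @slot subgraph igraph; the induced signature subgraph (isolates removed).
#' @slot clusters list of character vectors (cluster member ids), ordered by
#'   decreasing MCODE score.
#' @slot scores numeric MCODE scores (density x size), parallel to clusters.
#' @slot enrichment data.frame of enriched terms
#'   (term, k, n, K, N, p, q, flag).
#' @slot stageCounts named integer: input_features, connected_features,
#'   clusters, cluster_members, enriched_terms.
#'
#' @seealso [buildMolecularModel()], [modelClusters()], [clusterMembers()]
#' @exportClass MolecularModel
setClass("MolecularModel",
  representation(subgraph = "ANY", clusters = "list", scores = "numeric",
                 enrichment = "data.frame", stageCounts = "integer"))

setValidity("MolecularModel", function(object) {
  msg <- character()
  if (length(object@clusters) != length(object@scores))
    msg <- c(msg, "clusters and scores must be parallel")
  if (is.unsorted(rev(object@scores)))
    msg <- c(msg, "clusters must be sorted by decreasing score")
  if (length(object@clusters) && igraph::is_igraph(object@subgraph)) {
    nodes <- igraph::V(object@subgraph)$name
    if (!all(unlist(object@clusters) %in% nodes))
      msg <- c(msg, "every cluster node must be in the subgraph")
  }
  if (length(msg)) msg else TRUE
})

#' ModelFit: a fitted linear model with LOOCV diagnostics
#'
#' Ordinary least-squares fit of the eGFR outcome on a design matrix, with
#' per-coefficient t-tests, the overall F-test, adjusted R-squared and the
#' PRESS-based leave-one-out cross-validation statistics used for model
#' selection.
#'
#' @slot predictors character, non-intercept predictor names.
#' @slot coefficients matrix with columns estimate, se, t, p; first row is
#'   the intercept.
#' @slot r2,adjR2 numeric R-squared and adjusted R-squared.
#' @slot fStatistic,fPValue overall F test (NA for intercept-only fits).
#' @slot loocvRMSE,loocvR2 PRESS-based leave-one-out statistics.
#' @slot rss residual sum of squares.
#' @slot n,df observations and residual degrees of freedom.
#' @slot design,response the model matrix (with intercept) and outcome used.
#' @slot hat leverage values.
#' @slot residuals OLS residuals.
#' @slot rows integer indices of the source-table rows retained after
#'   complete-case filtering (empty when unknown).
#'
#' @seealso [fitOLS()], [fitModel()], [pressLOOCV()], [anovaNested()]
#' @exportClass ModelFit
setClass("ModelFit",
  representation(predictors = "character", coefficients = "matrix",
                 r2 = "numeric", adjR2 = "numeric",
                 fStatistic = "numeric", fPValue = "numeric",
                 loocvRMSE = "numeric", loocvR2 = "numeric",
                 rss = "numeric", n = "integer", df = "integer",
                 design = "matrix", response = "numeric",
                 hat = "numeric", residuals = "numeric", rows = "integer"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (object@df != object@n - nrow(object@coefficients))
    msg <- c(msg, "df must equal n - number of coefficients")
  if (length(object@loocvRMSE) && !is.na(object@loocvRMSE) &&
      object@loocvRMSE < 0)
    msg <- c(msg, "LOOCV RMSE must be non-negative")
  if (length(msg)) msg else TRUE
})
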