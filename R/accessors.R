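#' @rdname FeatureCatalog-class
#' @aliases catalogSize,FeatureCatalog-method
setMethod("catalogSize", "FeatureCatalog", function(x) nrow(x@features))

#' @rdname FeatureCatalog-class
#' @aliases featureTable,FeatureCatalog-method
setMethod("featureTable", "FeatureCatalog", function(x) x@features)

#' @rdname FeatureCatalog-class
#' @aliases provenance,FeatureCatalog-method
setMethod("provenance", "FeatureCatalog", function(x) x@provenance)

setMethod("show", "FeatureCatalog", function(object) {
  cat("FeatureCatalog with", nrow(object@features), "unique features from",
      length(object@provenance), "sources\n")
  pv <- object@provenance
  cat("  sources:", paste(sprintf("%s (%d)", names(pv), pv), collapse = ", "),
      "\n")
  invisible(NULL)
})

#' @rdname MolecularModel-class
#' @aliases modelClusters,MolecularModel-method
setMethod("modelClusters", "MolecularModel", function(x) x@clusters)

#' @rdname MolecularModel-class
#' @aliases clusterScores,MolecularModel-method
setMethod("clusterScores", "MolecularModel", function(x) x@scores)

#' @rdname MolecularModel-class
#' @aliases clusterMembers,MolecularModel-method
setMethod("clusterMembers", "MolecularModel",
          function(x) sort(unique(unlist(x@clusters, use.names = FALSE))))

#' @rdname MolecularModel-class
#' @aliases enrichedTerms,MolecularModel-method
setMethod("enrichedTerms", "MolecularModel", function(x) x@enrichment)

#' @rdname MolecularModel-class
#' @aliases stageCounts,MolecularModel-method
setMethod("stageCounts", "MolecularModel", function(x) x@stageCounts)

#' @rdname MolecularModel-class
#' @aliases modelSubgraph,MolecularModel-method
setMethod("modelSubgraph", "MolecularModel", function(x) x@subgraph)

setMethod("show", "MolecularModel", function(object) {
  sc <- object@stageCounts
  cat("MolecularModel (donor organ status)\n")
  cat(sprintf("  input features:     %d\n", sc[["input_features"]]))
  cat(sprintf("  connected features: %d\n", sc[["connected_features"]]))
  cat(sprintf("  clusters:           %d\n", sc[["clusters"]]))
  cat(sprintf("  cluster members:    %d\n", sc[["cluster_members"]]))
  cat(sprintf("  enriched terms:     %d\n", sc[["enriched_terms"]]))
  invisible(NULL)
})

#' @rdname ModelFit-class
#' @aliases predictorNames,ModelFit-method
setMethod("predictorNames", "ModelFit", function(x) x@predictors)

#' @rdname ModelFit-class
#' @aliases coefTable,ModelFit-method
setMethod("coefTable", "ModelFit", function(x) x@coefficients)

#' @rdname ModelFit-class
#' @aliases adjR2,ModelFit-method
setMethod("adjR2", "ModelFit", function(x) x@adjR2)

#' @rdname ModelFit-class
#' @aliases loocvRMSE,ModelFit-method
setMethod("loocvRMSE", "ModelFit", function(x) x@loocvRMSE)

#' @rdname ModelFit-class
#' @aliases loocvR2,ModelFit-method
setMethod("loocvR2", "ModelFit", function(x) x@loocvR2)

#' @rdname ModelFit-class
#' @aliases fitPValue,ModelFit-method
setMethod("fitPValue", "ModelFit", function(x) x@fPValue)

setMethod("show", "ModelFit", function(object) {
  cat(sprintf(
    "ModelFit: %d predictor(s), n = %d\n",
    length(object@predictors), object@n))
  cat(sprintf(
    "  adj R2 = %.4f, LOOCV R2 = %.4f, LOOCV RMSE = %.4f, overall p = %s\n",
    object@adjR2, object@loocvR2, object@loocvRMSE,
    format.pval(object@fPValue, digits = 3)))
  print(round(object@coefficients, 4))
  invisible(NULL)
})

#' @rdname AnnotationSet-class
#' @aliases annotationTerms,AnnotationSet-method
setMethod("annotationTerms", "AnnotationSet", function(x) x@terms)

#' @rdname AnnotationSet-class
#' @aliases annotationBackground,AnnotationSet-method
setMethod("annotationBackground", "AnnotationSet", function(x) x@background)

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@terms), "terms over a background of",
      length(object@background), "genes\n")
  invisible(NULL)
})
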