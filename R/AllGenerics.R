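#' @rdname FeatureCatalog-class
#' @param object,x a \code{FeatureCatalog}
#' @export
setGeneric("catalogSize", function(x) standardGeneric("catalogSize"))

#' @rdname FeatureCatalog-class
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname FeatureCatalog-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname MolecularModel-class
#' @export
setGeneric("modelClusters", function(x) standardGeneric("modelClusters"))

#' @rdname MolecularModel-class
#' @export
setGeneric("clusterScores", function(x) standardGeneric("clusterScores"))

#' @rdname MolecularModel-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname MolecularModel-class
#' @export
setGeneric("enrichedTerms", function(x) standardGeneric("enrichedTerms"))

#' @rdname MolecularModel-class
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname MolecularModel-class
#' @export
setGeneric("modelSubgraph", function(x) standardGeneric("modelSubgraph"))

#' @rdname ModelFit-class
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))

#' @rdname ModelFit-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname ModelFit-class
#' @export
setGeneric("adjR2", function(x) standardGeneric("adjR2"))

#' @rdname ModelFit-class
#' @export
setGeneric("loocvRMSE", function(x) standardGeneric("loocvRMSE"))

#' @rdname ModelFit-class
#' @export
setGeneric("loocvR2", function(x) standardGeneric("loocvR2"))

#' @rdname ModelFit-class
#' @export
setGeneric("fitPValue", function(x) standardGeneric("fitPValue"))

#' @rdname AnnotationSet-class
#' @param x an \code{AnnotationSet}
#' @export
setGeneric("annotationTerms", function(x) standardGeneric("annotationTerms"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("annotationBackground",
           function(x) standardGeneric("annotationBackground"))
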