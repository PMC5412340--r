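#' @rdname SymptomDataset-class
#' @param object,x a package object
#' @export
setGeneric("symptom", function(x) standardGeneric("symptom"))

#' @rdname SymptomDataset-class
#' @export
setGeneric("severity", function(x) standardGeneric("severity"))

#' @rdname SymptomDataset-class
#' @export
setGeneric("occurrence", function(x) standardGeneric("occurrence"))

#' @rdname SymptomDataset-class
#' @export
setGeneric("drugOf", function(x) standardGeneric("drugOf"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerScores", function(x) standardGeneric("markerScores"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerPvalues", function(x) standardGeneric("markerPvalues"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerMethod", function(x) standardGeneric("markerMethod"))

#' @rdname SldaModel-class
#' @export
setGeneric("sldaDirections", function(x) standardGeneric("sldaDirections"))

#' @rdname SldaModel-class
#' @export
setGeneric("sldaScores", function(x) standardGeneric("sldaScores"))

#' @rdname SldaModel-class
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))

#' @rdname EnsembleModel-class
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))

#' @rdname EnsembleModel-class
#' @export
setGeneric("subsampleLog", function(x) standardGeneric("subsampleLog"))

#' @rdname EnsembleModel-class
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Predict continuous severity for query samples
#'
#' @param object an [EnsembleModel-class]
#' @param X expression for the query samples: either a genes x samples
#'   matrix containing all marker genes in its rows, or a
#'   [SymptomDataset-class]
#' @param ... unused
#' @return numeric vector of predicted severities (mean over the ensemble
#'   members; continuous and unclipped)
#' @export
setGeneric("predictSeverity",
           function(object, X, ...) standardGeneric("predictSeverity"))

#' @rdname FoldPlan-class
#' @export
setGeneric("foldOfDrug", function(x) standardGeneric("foldOfDrug"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("pooledSCC", function(x) standardGeneric("pooledSCC"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("perFoldSCC", function(x) standardGeneric("perFoldSCC"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("oofPredictions", function(x) standardGeneric("oofPredictions"))

#' @rdname AnnotationTable-class
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname AnnotationTable-class
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))
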