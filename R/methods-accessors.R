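#' @rdname SymptomDataset-class
#' @aliases symptom severity occurrence drugOf
#' @export
setMethod("symptom", "SymptomDataset", function(x) x@symptom)

#' @rdname SymptomDataset-class
#' @export
setMethod("severity", "SymptomDataset",
          function(x) as.integer(colData(x)$severity))

#' @rdname SymptomDataset-class
#' @export
setMethod("occurrence", "SymptomDataset",
          function(x) as.logical(colData(x)$occurrence))

#' @rdname SymptomDataset-class
#' @export
setMethod("drugOf", "SymptomDataset",
          function(x) as.character(colData(x)$drug))

#' @rdname MarkerSet-class
#' @export
setMethod("markerGenes", "MarkerSet", function(x) x@genes)

#' @rdname MarkerSet-class
#' @export
setMethod("markerScores", "MarkerSet",
          function(x) stats::setNames(x@scores, x@genes))

#' @rdname MarkerSet-class
#' @export
setMethod("markerPvalues", "MarkerSet", function(x) {
  if (!length(x@pvalues)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(x@pvalues, x@genes)
})

#' @rdname MarkerSet-class
#' @export
setMethod("markerMethod", "MarkerSet", function(x) x@method)

#' @rdname SldaModel-class
#' @export
setMethod("sldaDirections", "SldaModel", function(x) x@directions)

#' @rdname SldaModel-class
#' @export
setMethod("sldaScores", "SldaModel", function(x) x@scores)

#' @rdname SldaModel-class
#' @export
setMethod("classLevels", "SldaModel", function(x) x@classLevels)

#' @rdname EnsembleModel-class
#' @export
setMethod("ensembleMembers", "EnsembleModel", function(x) x@members)

#' @rdname EnsembleModel-class
#' @export
setMethod("subsampleLog", "EnsembleModel", function(x) x@subsampleLog)

#' @rdname EnsembleModel-class
#' @export
setMethod("nModels", "EnsembleModel", function(x) x@nModels)

#' @rdname FoldPlan-class
#' @export
setMethod("foldOfDrug", "FoldPlan", function(x) x@foldOfDrug)

#' @rdname EvaluationResult-class
#' @export
setMethod("pooledSCC", "EvaluationResult", function(x) x@pooledSCC)

#' @rdname EvaluationResult-class
#' @export
setMethod("perFoldSCC", "EvaluationResult", function(x) x@perFoldSCC)

#' @rdname EvaluationResult-class
#' @export
setMethod("rocPoints", "EvaluationResult", function(x) x@rocPoints)

#' @rdname EvaluationResult-class
#' @export
setMethod("aucValue", "EvaluationResult", function(x) x@auc)

#' @rdname EvaluationResult-class
#' @export
setMethod("oofPredictions", "EvaluationResult", function(x) x@predictions)

#' @rdname AnnotationTable-class
#' @export
setMethod("termIds", "AnnotationTable", function(x) x@termId)

#' @rdname AnnotationTable-class
#' @export
setMethod("termGenes", "AnnotationTable",
          function(x) stats::setNames(x@genes, x@termId))

#' @rdname AnnotationTable-class
#' @export
setMethod("length", "AnnotationTable", function(x) length(x@termId))

setMethod("show", "SymptomDataset", function(object) {
  cat("SymptomDataset for symptom:", object@symptom, "\n")
  cat(" ", nrow(object), "genes x", ncol(object), "samples;",
      sum(occurrence(object)), "cases /", sum(!occurrence(object)),
      "controls;", length(unique(drugOf(object))), "drugs\n")
  cat("  severity grades:",
      paste(names(table(severity(object))), table(severity(object)),
            sep = ":", collapse = " "), "\n")
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet (%s, symptom '%s'): %d of m=%d genes\n",
              object@method, object@symptom, length(object@genes), object@m))
  n <- min(5L, length(object@genes))
  if (n) cat("  top:", paste(object@genes[seq_len(n)], collapse = ", "), "\n")
})

setMethod("show", "SldaModel", function(object) {
  cat(sprintf(
    "SldaModel: %d directions over %d classes (%s); cardinality m=%d, lambda2=%g\n",
    ncol(object@directions), length(object@classLevels),
    paste(object@classLevels, collapse = ","), object@m, object@lambda2))
  cat("  non-zero loadings per direction:",
      paste(colSums(object@directions != 0), collapse = ", "),
      "| converged:", paste(object@converged, collapse = ", "), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf(
    "EnsembleModel: %d balanced members, %d trees each, %d marker features\n",
    object@nModels, object@rfParams$nTrees, length(object@markerGenes)))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d drugs dealt into %d folds (seed %d)\n",
              length(object@foldOfDrug), object@k, object@seed))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult (%s, m=%d, symptom '%s')\n",
              object@method, object@m, object@symptom))
  cat(sprintf("  pooled SCC: %.3f | mean per-fold SCC: %.3f | AUC: %.3f\n",
              object@pooledSCC, object@meanFoldSCC, object@auc))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d gene sets (sizes %s)\n",
              length(object@termId),
              paste(range(vapply(object@genes, length, integer(1))),
                    collapse = "-")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d planted markers (weak pair: %s) over %d genes; %d/%d toxic drugs\n",
    length(object@markerGenes), paste(object@weakPair, collapse = "+"),
    length(object@geneIds), sum(object@drugGrade > 0),
    length(object@drugGrade)))
})
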