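#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SymptomDataset: modeling dataset for one toxicity symptom
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying the expression
#' matrix (genes in rows, samples in columns, assay `"exprs"`) restricted to
#' the samples retained for one symptom, together with per-sample metadata in
#' `colData`: `drug` (compound identifier), `severity` (ordinal pathology
#' grade 0--4) and `occurrence` (`severity >= 1`). Spontaneous positive
#' findings have already been removed by [buildDataset()].
#'
#' @slot symptom single string, the symptom this dataset was assembled for.
#'
#' @seealso [buildDataset()], [zscoreGenes()]
#' @export
setClass("SymptomDataset",
  contains = "SummarizedExperiment",
  slots = c(symptom = "character")
)

setValidity("SymptomDataset", function(object) {
  cd <- colData(object)
  msg <- character()
  need <- c("drug", "severity", "occurrence")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain columns:", paste(need, collapse = ", ")))
  if (length(object@symptom) != 1L || is.na(object@symptom))
    msg <- c(msg, "symptom must be a single string")
  sev <- cd$severity
  if (!all(sev %in% 0:4))
    msg <- c(msg, "severity grades must lie in {0,...,4}")
  if (!identical(as.logical(sev >= 1L), as.logical(cd$occurrence)))
    msg <- c(msg, "occurrence must equal severity >= 1")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' MarkerSet: a ranked set of candidate marker genes
#'
#' Result of one marker-selection run for one symptom. `genes` are ordered
#' from strongest (rank 1) downwards. `scores` holds the method's statistic
#' per gene (max |loading| for sLDA, F for ANOVA, |t| for the t-test);
#' `pvalues` is filled for the p-value-ranked methods (ANOVA, t-test) and
#' empty for sLDA. Ranking is by the method's criterion: ascending p-value
#' where `pvalues` is present, descending score otherwise, ties broken by
#' gene id.
#'
#' @slot symptom,method single strings; `method` is one of
#'   `"slda"`, `"anova"`, `"ttest"`.
#' @slot genes character vector of gene ids, rank order.
#' @slot scores numeric, aligned to `genes`.
#' @slot pvalues numeric, aligned to `genes`, or length 0.
#' @slot m integer, the requested set size.
#' @export
setClass("MarkerSet",
  slots = c(symptom = "character", method = "character",
            genes = "character", scores = "numeric",
            pvalues = "numeric", m = "integer")
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  if (!object@method %in% c("slda", "anova", "ttest"))
    msg <- c(msg, "method must be one of slda/anova/ttest")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "genes must be unique")
  if (length(object@scores) != length(object@genes))
    msg <- c(msg, "scores must align with genes")
  np <- length(object@pvalues)
  if (np && np != length(object@genes))
    msg <- c(msg, "pvalues must align with genes or be empty")
  if (length(object@genes) > max(object@m, 0L))
    msg <- c(msg, "more genes than the requested size m")
  tol <- 1e-12
  if (np) {
    if (is.unsorted(object@pvalues, strictly = FALSE))
      msg <- c(msg, "pvalues must be non-decreasing along the ranking")
  } else if (length(object@scores) > 1L) {
    if (any(diff(object@scores) > tol))
      msg <- c(msg, "scores must be non-increasing along the ranking")
  }
  if (length(msg)) msg else TRUE
})

#' SldaModel: fitted sparse discriminant model (penalized optimal scoring)
#'
#' @slot directions genes x q matrix B of sparse discriminant vectors; each
#'   column has at most `m` non-zero entries. Row names are gene ids.
#' @slot scores K x q matrix of optimal class scores (theta), rows ordered as
#'   `classLevels`; columns are D-orthonormal where D = diag(class
#'   frequencies).
#' @slot classLevels integer severity grades present in the training labels.
#' @slot classFreq numeric, empirical class frequencies (diagonal of D).
#' @slot lambda2 ridge penalty used in the elastic-net subproblems.
#' @slot m per-direction cardinality bound.
#' @slot iterations,converged per-direction diagnostics.
#' @export
setClass("SldaModel",
  slots = c(directions = "matrix", scores = "matrix",
            classLevels = "integer", classFreq = "numeric",
            lambda2 = "numeric", m = "integer",
            iterations = "integer", converged = "logical")
)

setValidity("SldaModel", function(object) {
  msg <- character()
  q <- ncol(object@directions)
  K <- length(object@classLevels)
  if (q > K - 1L)
    msg <- c(msg, "at most K - 1 discriminant directions are allowed")
  if (ncol(object@scores) != q || nrow(object@scores) != K)
    msg <- c(msg, "scores must be K x q")
  if (any(colSums(object@directions != 0) > object@m))
    msg <- c(msg, "a direction exceeds the cardinality bound m")
  if (q >= 1L && length(object@classFreq) == K) {
    G <- t(object@scores) %*% (object@classFreq * object@scores)
    if (max(abs(G - diag(1, q))) > 1e-8)
      msg <- c(msg, "score columns must be D-orthonormal (tol 1e-8)")
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleModel: balanced ensemble of regression forests
#'
#' `n_models` regression forests, each trained on all case samples plus an
#' equal-size random subset of controls; the ensemble prediction is the
#' arithmetic mean of the member predictions. Counters the control-heavy
#' class imbalance of toxicogenomics cohorts.
#'
#' @slot members list of fitted forests (internal representation).
#' @slot markerGenes feature genes, in the order used for training.
#' @slot nModels number of members.
#' @slot rfParams list with `nTrees` and `maxDepth` (0 = unlimited).
#' @slot subsampleLog per-member list with `case` and `control` sample ids.
#' @slot seed integer seed the ensemble was drawn with.
#' @export
setClass("EnsembleModel",
  slots = c(members = "list", markerGenes = "character",
            nModels = "integer", rfParams = "list",
            subsampleLog = "list", seed = "integer")
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) != object@nModels)
    msg <- c(msg, "number of members must equal nModels")
  if (length(object@subsampleLog) != object@nModels)
    msg <- c(msg, "subsampleLog must have one entry per member")
  bal <- vapply(object@subsampleLog, function(s)
    length(s$case) == length(s$control), logical(1))
  if (!all(bal))
    msg <- c(msg, "every member must train on equal case and control counts")
  if (length(msg)) msg else TRUE
})

#' FoldPlan: drug-unit cross-validation fold assignment
#'
#' Folds partition *drugs*, not samples: all samples of a drug share a fold,
#' so no compound leaks between training and test data.
#'
#' @slot k number of folds.
#' @slot foldOfDrug named integer vector, drug id -> fold in 1..k.
#' @slot seed integer seed used for the drug shuffle.
#' @export
setClass("FoldPlan",
  slots = c(k = "integer", foldOfDrug = "integer", seed = "integer")
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  f <- object@foldOfDrug
  if (is.null(names(f)) || anyDuplicated(names(f)))
    msg <- c(msg, "foldOfDrug must be named by unique drug ids")
  if (length(f) && (min(f) < 1L || max(f) > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(f)) {
    sizes <- tabulate(f, nbins = object@k)
    if (diff(range(sizes)) > 1L)
      msg <- c(msg, "fold sizes (in drugs) must differ by at most 1")
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: cross-validated severity / occurrence performance
#'
#' @slot symptom,method single strings; @slot m marker count.
#' @slot perFoldSCC Spearman correlation per fold (NA where undefined).
#' @slot meanFoldSCC mean over the defined per-fold values.
#' @slot pooledSCC Spearman correlation over the concatenated out-of-fold
#'   predictions (the primary summary).
#' @slot rocPoints data.frame with columns threshold, fpr, tpr.
#' @slot auc area under the ROC curve (Mann-Whitney convention, ties 1/2).
#' @slot predictions per-sample out-of-fold table: sample_id, drug, fold,
#'   actual, occurrence, predicted.
#' @export
setClass("EvaluationResult",
  slots = c(symptom = "character", method = "character", m = "integer",
            perFoldSCC = "numeric", meanFoldSCC = "numeric",
            pooledSCC = "numeric", rocPoints = "data.frame",
            auc = "numeric", predictions = "data.frame")
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (length(object@auc) == 1L && !is.na(object@auc) &&
      (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "AUC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' AnnotationTable: gene-set annotation (GMT-style)
#'
#' @slot termId unique term identifiers.
#' @slot termName human-readable term names.
#' @slot genes list of character vectors, member gene ids per term
#'   (deduplicated, non-empty).
#' @export
setClass("AnnotationTable",
  slots = c(termId = "character", termName = "character", genes = "list")
)

setValidity("AnnotationTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@termId))
    msg <- c(msg, "term ids must be unique")
  if (length(object@termName) != length(object@termId) ||
      length(object@genes) != length(object@termId))
    msg <- c(msg, "termId, termName and genes must align")
  if (length(object@genes)) {
    n <- vapply(object@genes, length, integer(1))
    if (any(n == 0L)) msg <- c(msg, "member gene sets must be non-empty")
    dup <- vapply(object@genes, anyDuplicated, integer(1))
    if (any(dup > 0L)) msg <- c(msg, "member gene sets must be deduplicated")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a simulated cohort
#'
#' @slot markerGenes ordered ids of the planted severity-monotone markers.
#' @slot directions named numeric (+1/-1), per-marker effect direction.
#' @slot weakPair the two marker ids forming the correlated weak pair
#'   (strongly mutually correlated, effect split across the pair).
#' @slot drugGrade named integer, drug id -> max induced grade (0 for
#'   non-toxic drugs).
#' @slot geneIds full simulated gene universe.
#' @slot plantedTermId id of the planted enriched term ("" until
#'   [simulateAnnotation()] has been run).
#' @export
setClass("GroundTruth",
  slots = c(markerGenes = "character", directions = "numeric",
            weakPair = "character", drugGrade = "integer",
            geneIds = "character", plantedTermId = "character")
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@markerGenes %in% object@geneIds))
    msg <- c(msg, "marker genes must be a subset of the gene universe")
  if (!all(object@weakPair %in% object@markerGenes))
    msg <- c(msg, "the weak pair must consist of marker genes")
  if (length(msg)) msg else TRUE
})
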