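#' Train a balanced ensemble of regression forests
#'
#' Counters the control-heavy imbalance of toxicogenomics cohorts (e.g.,
#' a few hundred case samples against >13,000 controls): each of the
#' `nModels` members is trained on *all* case samples (severity >= 1) plus an
#' equal-size uniform random subset of controls drawn without replacement,
#' independently across members. Members are regression forests over the
#' marker-gene features predicting the integer severity grade; every marker
#' is a candidate feature at every split and trees grow to unlimited depth by
#' default. Fully deterministic given `seed`.
#'
#' If controls are fewer than cases, control sampling falls back to
#' with-replacement and a warning is emitted.
#'
#' @param ds a [SymptomDataset-class]
#' @param markers a [MarkerSet-class] or character vector of gene ids
#' @param nModels number of ensemble members (default 100)
#' @param rfParams list with `nTrees` (default 10) and `maxDepth`
#'   (0 = unlimited, the default)
#' @param seed integer seed
#' @return an [EnsembleModel-class]
#' @export
trainBalancedEnsemble <- function(ds, markers, nModels = 100L,
                                  rfParams = list(nTrees = 10L, maxDepth = 0L),
                                  seed = 1L) {
  stopifnot(is(ds, "SymptomDataset"))
  genes <- if (is(markers, "MarkerSet")) markerGenes(markers)
           else as.character(markers)
  X <- SummarizedExperiment::assay(ds, "exprs")
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("marker gene(s) missing from the expression matrix: ",
         paste(miss, collapse = ", "))
  sev <- severity(ds)
  case <- which(sev >= 1L)
  ctrl <- which(sev == 0L)
  if (!length(case)) stop("degenerate dataset: no case samples")
  if (!length(ctrl)) stop("degenerate dataset: no control samples")
  nTrees <- as.integer(rfParams$nTrees %||% 10L)
  maxDepth <- as.integer(rfParams$maxDepth %||% 0L)
  Xf <- t(X[genes, , drop = FALSE])  # samples x features
  replaceFlag <- length(ctrl) < length(case)
  if (replaceFlag)
    warning("fewer controls than cases; sampling controls with replacement")
  ids <- colnames(X)

  withLocalSeed(seed, {
    members <- vector("list", nModels)
    logL <- vector("list", nModels)
    for (b in seq_len(nModels)) {
      csel <- if (replaceFlag) sample(ctrl, length(case), replace = TRUE)
              else sample(ctrl, length(case))
      idx <- c(case, csel)
      nb <- length(idx)
      boot <- matrix(sample.int(nb, nb * nTrees, replace = TRUE),
                     nrow = nTrees)
      members[[b]] <- cpp_grow_forest(Xf[idx, , drop = FALSE],
                                      as.numeric(sev[idx]), boot,
                                      2L, maxDepth)
      logL[[b]] <- list(case = ids[case], control = ids[csel])
    }
    new("EnsembleModel", members = members, markerGenes = genes,
        nModels = as.integer(nModels),
        rfParams = list(nTrees = nTrees, maxDepth = maxDepth),
        subsampleLog = logL, seed = as.integer(seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.predictMatrix <- function(object, X) {
  miss <- setdiff(object@markerGenes, rownames(X))
  if (length(miss))
    stop("marker gene(s) missing from the query expression: ",
         paste(miss, collapse = ", "))
  Xq <- t(X[object@markerGenes, , drop = FALSE])
  preds <- vapply(object@members,
                  function(f) as.numeric(cpp_predict_forest(f, Xq)),
                  numeric(nrow(Xq)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' @rdname predictSeverity
#' @export
setMethod("predictSeverity", c("EnsembleModel", "matrix"),
          function(object, X, ...) .predictMatrix(object, X))

#' @rdname predictSeverity
#' @export
setMethod("predictSeverity", c("EnsembleModel", "SymptomDataset"),
          function(object, X, ...)
            .predictMatrix(object, SummarizedExperiment::assay(X, "exprs")))
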