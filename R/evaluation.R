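#' Plan drug-unit cross-validation folds
#'
#' Drugs are shuffled with `seed` and dealt round-robin into `k` folds, so
#' fold sizes (measured in drugs) differ by at most one and every sample
#' inherits its drug's fold -- no compound's samples ever span folds.
#'
#' @param ds a [SymptomDataset-class]
#' @param k number of folds (default 10)
#' @param seed integer seed for the shuffle
#' @return a [FoldPlan-class]
#' @export
makeDrugFolds <- function(ds, k = 10L, seed = 1L) {
  stopifnot(is(ds, "SymptomDataset"))
  drugs <- unique(drugOf(ds))
  k <- as.integer(k)
  if (length(drugs) < k)
    stop(sprintf("need at least k=%d distinct drugs, got %d",
                 k, length(drugs)))
  withLocalSeed(seed, {
    shuffled <- sample(drugs)
    folds <- rep(seq_len(k), length.out = length(shuffled))
    new("FoldPlan", k = k,
        foldOfDrug = stats::setNames(folds, shuffled),
        seed = as.integer(seed))
  })
}

#' Spearman correlation between actual and predicted severities
#'
#' Pearson correlation of average-fractional ranks (standard tie handling).
#' Undefined when the actual severities are constant: returns `NA` with a
#' warning.
#'
#' @param actual,predicted numeric vectors of equal length >= 3
#' @return Spearman's correlation coefficient, or NA when undefined
#' @export
spearmanCor <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (length(actual) < 3L)
    stop("need at least 3 observations")
  if (stats::sd(actual) == 0) {
    warning("Spearman correlation undefined: actual severities are constant")
    return(NA_real_)
  }
  suppressWarnings(stats::cor(actual, predicted, method = "spearman"))
}

#' ROC curve and AUC by threshold sweep over predicted severity
#'
#' A sample is called positive when its predicted severity is greater than or
#' equal to the threshold; thresholds sweep the distinct predicted values
#' (plus Inf for the empty call set). AUC is the trapezoid area under the
#' resulting curve, which equals the Mann-Whitney statistic with ties
#' credited 1/2.
#'
#' @param predicted numeric vector of predicted severities
#' @param occurrence logical vector (TRUE = case)
#' @return list with `points` (data.frame threshold, fpr, tpr) and `auc`
#' @export
rocAuc <- function(predicted, occurrence) {
  stopifnot(length(predicted) == length(occurrence))
  occurrence <- as.logical(occurrence)
  n1 <- sum(occurrence); n0 <- sum(!occurrence)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: only one occurrence class present")
  thr <- c(Inf, sort(unique(predicted), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(predicted >= t & occurrence) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(predicted >= t & !occurrence) / n0,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Drug-unit cross-validated evaluation of a marker-selection method
#'
#' For each fold of a drug-unit [makeDrugFolds()] plan: markers are selected
#' on the training folds only, a balanced forest ensemble is trained on the
#' training folds, and severity is predicted for the held-out fold. Reports
#' the Spearman correlation per fold and pooled over the concatenated
#' out-of-fold predictions (the primary summary), plus the threshold-swept
#' ROC/AUC for occurrence.
#'
#' Gene z-scoring is global by default, matching the original analysis
#' (normalization before modeling, a mild train/test leakage accepted for
#' fidelity); `normalize = "perfold"` standardizes with training-fold means
#' and SDs instead. A fold whose held-out samples have constant severity
#' (e.g. no cases) gets an `NA` per-fold correlation, excluded from the
#' per-fold mean with a warning.
#'
#' Ensemble seeds are derived per fold from `seed` by a fixed counter scheme,
#' independent of the selection method, so method comparisons at the same
#' seed are paired: identical marker sets give identical predictions.
#'
#' @param ds a [SymptomDataset-class]
#' @param method `"slda"`, `"anova"` or `"ttest"`
#' @param m marker count
#' @param k number of folds (default 10)
#' @param nModels ensemble members per fold (default 100)
#' @param rfParams forest parameters, see [trainBalancedEnsemble()]
#' @param lambda2 sLDA ridge penalty
#' @param variant t-test variant
#' @param normalize `"global"` (default) or `"perfold"`
#' @param seed integer seed (fold plan and ensembles)
#' @param selectionHook optional `function(fold, trainSampleIds)` called
#'   before each fold's marker selection; instrumentation for leakage audits
#' @return an [EvaluationResult-class]
#' @export
crossValidate <- function(ds, method = c("slda", "anova", "ttest"), m,
                          k = 10L, nModels = 100L,
                          rfParams = list(nTrees = 10L, maxDepth = 0L),
                          lambda2 = 1e-3, variant = "welch",
                          normalize = c("global", "perfold"),
                          seed = 1L, selectionHook = NULL) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  stopifnot(is(ds, "SymptomDataset"))
  plan <- makeDrugFolds(ds, k = k, seed = seed)
  foldOfSample <- unname(plan@foldOfDrug[drugOf(ds)])
  Xraw <- SummarizedExperiment::assay(ds, "exprs")
  Xglobal <- if (normalize == "global")
    suppressWarnings(zscoreGenes(Xraw)) else NULL
  sev <- severity(ds)
  occ <- occurrence(ds)
  ids <- colnames(Xraw)
  n <- length(sev)
  preds <- rep(NA_real_, n)
  perFold <- rep(NA_real_, k)

  for (f in seq_len(k)) {
    tr <- which(foldOfSample != f)
    te <- which(foldOfSample == f)
    if (!length(te)) next
    if (normalize == "global") {
      Xtr <- Xglobal[, tr, drop = FALSE]
      Xte <- Xglobal[, te, drop = FALSE]
    } else {
      mu <- rowMeans(Xraw[, tr, drop = FALSE])
      ctr <- Xraw[, tr, drop = FALSE] - mu
      sdp <- sqrt(rowMeans(ctr^2))
      sdp[sdp == 0] <- 1
      Xtr <- ctr / sdp
      Xte <- (Xraw[, te, drop = FALSE] - mu) / sdp
    }
    if (length(unique(sev[tr])) < 2L || !any(sev[tr] >= 1L) ||
        !any(sev[tr] == 0L)) {
      warning(sprintf(
        "fold %d: training folds lack two severity classes; fold left unpredicted", f))
      next
    }
    if (!is.null(selectionHook)) selectionHook(f, ids[tr])
    markers <- switch(method,
      slda = selectMarkersSlda(
        fitSlda(t(Xtr), sev[tr], m = m, lambda2 = lambda2),
        m, symptom = symptom(ds)),
      anova = selectMarkersAnova(Xtr, sev[tr], m, symptom = symptom(ds)),
      ttest = selectMarkersTtest(Xtr, occ[tr], m, symptom = symptom(ds),
                                 variant = variant))
    dsTr <- ds[, tr]
    SummarizedExperiment::assay(dsTr, "exprs") <- Xtr
    ens <- trainBalancedEnsemble(dsTr, markers, nModels = nModels,
                                 rfParams = rfParams,
                                 seed = seed + 1000L + f)
    preds[te] <- predictSeverity(ens, Xte)
    if (length(te) >= 3L && stats::sd(sev[te]) > 0) {
      perFold[f] <- spearmanCor(sev[te], preds[te])
    } else {
      warning(sprintf(
        "fold %d: per-fold SCC undefined (constant or too few severities); excluded from the per-fold mean", f))
    }
  }

  ok <- !is.na(preds)
  pooled <- spearmanCor(sev[ok], preds[ok])
  roc <- rocAuc(preds[ok], occ[ok])
  new("EvaluationResult",
      symptom = symptom(ds), method = method, m = as.integer(m),
      perFoldSCC = perFold,
      meanFoldSCC = mean(perFold, na.rm = TRUE),
      pooledSCC = pooled,
      rocPoints = roc$points, auc = roc$auc,
      predictions = data.frame(sample_id = ids, drug = drugOf(ds),
                               fold = foldOfSample, actual = sev,
                               occurrence = occ, predicted = preds,
                               stringsAsFactors = FALSE))
}
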