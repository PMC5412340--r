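#' Row-wise one-way ANOVA F statistics across severity groups
#'
#' Vectorized over genes. Severity groups with fewer than 2 members are
#' excluded. Genes whose within-group sum of squares is (numerically) zero
#' while group means differ are maximally discriminative: they get `F = Inf`
#' and `p = 0`; genes with identical group means get `F = 0`, `p = 1`.
#'
#' @param X genes x samples matrix
#' @param labels severity grades, one per column
#' @return data.frame with columns gene, F, p
#' @export
rowAnova <- function(X, labels) {
  stopifnot(is.matrix(X), ncol(X) == length(labels))
  tab <- table(labels)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L)
    stop("degenerate labels: fewer than 2 severity groups with >= 2 members")
  keep <- labels %in% as.numeric(usable)
  Xk <- X[, keep, drop = FALSE]
  lk <- labels[keep]
  groups <- sort(unique(lk))
  k <- length(groups)
  n <- ncol(Xk)
  Ind <- outer(lk, groups, "==") * 1  # n x k
  ng <- colSums(Ind)
  Mg <- (Xk %*% Ind) / rep(ng, each = nrow(Xk))  # group means, genes x k
  grand <- rowMeans(Xk)
  SSB <- drop((Mg - grand)^2 %*% ng)
  SST <- rowSums((Xk - grand)^2)
  SSW <- pmax(SST - SSB, 0)
  Fst <- (SSB / (k - 1)) / (SSW / (n - k))
  zeroW <- SSW <= 1e-12 * pmax(SST, 1e-300)
  Fst[zeroW & SSB > 0] <- Inf
  Fst[SSB <= 1e-12 * pmax(SST, 1e-300)] <- 0
  p <- stats::pf(Fst, k - 1, n - k, lower.tail = FALSE)
  p[is.infinite(Fst)] <- 0
  p[Fst == 0] <- 1
  data.frame(gene = rownames(X), F = Fst, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Row-wise two-sample t statistics for occurrence groups
#'
#' Welch's unequal-variance t (Satterthwaite degrees of freedom) by default;
#' the pooled-variance Student form is available via `variant = "pooled"`.
#' Vectorized over genes.
#'
#' @param X genes x samples matrix
#' @param occurrence logical vector, one per column (TRUE = case)
#' @param variant `"welch"` (default) or `"pooled"`
#' @return data.frame with columns gene, t, df, p
#' @export
rowTtest <- function(X, occurrence, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(X), ncol(X) == length(occurrence))
  occurrence <- as.logical(occurrence)
  n1 <- sum(occurrence); n0 <- sum(!occurrence)
  if (n1 < 2L || n0 < 2L)
    stop("degenerate labels: each occurrence group needs >= 2 members")
  X1 <- X[, occurrence, drop = FALSE]
  X0 <- X[, !occurrence, drop = FALSE]
  m1 <- rowMeans(X1); m0 <- rowMeans(X0)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((X0 - m0)^2) / (n0 - 1)
  d <- m1 - m0
  if (variant == "welch") {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2, nrow(X))
  }
  t <- d / sqrt(se2)
  zero <- se2 <= 1e-300
  t[zero & d == 0] <- 0
  t[zero & d != 0] <- sign(d[zero & d != 0]) * Inf
  df[zero] <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[is.infinite(t)] <- 0
  data.frame(gene = rownames(X), t = t, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select markers by one-way ANOVA on severity groups
#'
#' Genes are ranked in increasing order of the one-way F-test p-value across
#' severity groups (equivalently decreasing F, since all genes share the same
#' degrees of freedom); ties are broken by gene id; the top `m` are returned.
#'
#' @param X genes x samples matrix
#' @param labels severity grades per sample
#' @param m requested set size
#' @param symptom symptom tag
#' @return a [MarkerSet-class] with `method = "anova"`, scores = F
#' @export
selectMarkersAnova <- function(X, labels, m, symptom = "unspecified") {
  res <- rowAnova(X, labels)
  ord <- order(-res$F, res$gene)
  sel <- utils::head(ord, m)
  new("MarkerSet", symptom = symptom, method = "anova",
      genes = res$gene[sel], scores = res$F[sel],
      pvalues = res$p[sel], m = as.integer(m))
}

#' Select markers by a two-sample t-test on occurrence groups
#'
#' The t-test cannot use the multi-grade severity label, so groups are
#' defined by occurrence (grade >= 1 versus grade 0). Genes are ranked in
#' increasing order of p-value, ties broken by gene id.
#'
#' @inheritParams rowTtest
#' @param m requested set size
#' @param symptom symptom tag
#' @return a [MarkerSet-class] with `method = "ttest"`, scores = |t|
#' @export
selectMarkersTtest <- function(X, occurrence, m, symptom = "unspecified",
                               variant = c("welch", "pooled")) {
  res <- rowTtest(X, occurrence, variant = match.arg(variant))
  ord <- order(res$p, res$gene)
  sel <- utils::head(ord, m)
  new("MarkerSet", symptom = symptom, method = "ttest",
      genes = res$gene[sel], scores = abs(res$t[sel]),
      pvalues = res$p[sel], m = as.integer(m))
}

#' Select markers from a SymptomDataset by any of the three methods
#'
#' Convenience front end used by the cross-validation driver. Expression is
#' z-scored (population SD) before sparse-discriminant fitting unless
#' `standardize = FALSE`; the F and t statistics are location/scale invariant
#' per gene, so standardization does not affect the other two methods.
#'
#' @param ds a [SymptomDataset-class]
#' @param method one of `"slda"`, `"anova"`, `"ttest"`
#' @param m requested marker count
#' @param lambda2 ridge penalty for sLDA
#' @param variant t-test variant, see [rowTtest()]
#' @param standardize z-score genes before sLDA fitting
#' @param ... passed on to [fitSlda()]
#' @return a [MarkerSet-class]
#' @export
selectMarkers <- function(ds, method = c("slda", "anova", "ttest"), m,
                          lambda2 = 1e-3, variant = "welch",
                          standardize = TRUE, ...) {
  method <- match.arg(method)
  stopifnot(is(ds, "SymptomDataset"))
  X <- SummarizedExperiment::assay(ds, "exprs")
  if (standardize && method == "slda")
    X <- suppressWarnings(zscoreGenes(X))
  switch(method,
    slda = {
      model <- fitSlda(t(X), severity(ds), m = m, lambda2 = lambda2, ...)
      selectMarkersSlda(model, m, symptom = symptom(ds))
    },
    anova = selectMarkersAnova(X, severity(ds), m, symptom = symptom(ds)),
    ttest = selectMarkersTtest(X, occurrence(ds), m, symptom = symptom(ds),
                               variant = variant))
}
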