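test_that("drug folds partition drugs evenly and deterministically", {
  ds <- plantedDataset(nDrugs = 20, perDrug = 4, p = 10, seed = 1)
  plan <- makeDrugFolds(ds, k = 10, seed = 3)
  f <- foldOfDrug(plan)
  expect_equal(length(f), 20L)
  expect_true(all(table(f) == 2L))          # 20 drugs, k=10 -> 2 each
  expect_true(validObject(plan))
  expect_identical(foldOfDrug(makeDrugFolds(ds, k = 10, seed = 3)), f)
  # samples inherit their drug's fold: no drug spans folds by construction
  fold_of_sample <- f[drugOf(ds)]
  expect_true(all(tapply(fold_of_sample, drugOf(ds),
                         function(v) length(unique(v))) == 1L))
  expect_error(makeDrugFolds(ds, k = 21, seed = 1), "at least")
})

test_that("Spearman correlation matches a rank-then-Pearson oracle, with ties", {
  expect_equal(spearmanCor(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearmanCor(1:3, c(3, 2, 1)), -1.0)
  tied_a <- c(0, 0, 1, 2)
  tied_p <- c(0.1, 0.2, 0.9, 1.5)
  expect_equal(spearmanCor(tied_a, tied_p), oracleSpearman(tied_a, tied_p),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    a <- sample(0:3, 12, replace = TRUE)
    p <- round(rnorm(12), 1)  # induces ties
    if (sd(a) == 0) next
    expect_equal(spearmanCor(a, p), oracleSpearman(a, p), tolerance = 1e-12)
  }
  expect_error(spearmanCor(1:4, 1:3), "equal length")
  expect_error(spearmanCor(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(r <- spearmanCor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  # invariance under strictly increasing transforms of the predictions
  a <- c(0, 1, 1, 2, 3, 0, 2)
  p <- c(0.2, 0.9, 1.4, 1.1, 2.5, -0.3, 2.0)
  expect_equal(spearmanCor(a, exp(p) + 5), spearmanCor(a, p))
})

test_that("threshold-swept ROC/AUC equals exhaustive pair counting with half-tie credit", {
  # perfectly separated
  expect_equal(rocAuc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1.0)
  # all-equal predictions -> diagonal, AUC 0.5
  expect_equal(rocAuc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # random fixtures vs the brute-force oracle, exactly
  set.seed(13)
  for (i in 1:10) {
    occ <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 6, replace = TRUE))
    pred <- sample(seq(0, 2, by = 0.5), 8, replace = TRUE)  # with ties
    r <- rocAuc(pred, occ)
    expect_equal(r$auc, oracleAuc(pred, occ), tolerance = 1e-12)
    # curve is monotone in both coordinates as the threshold relaxes
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    # complement symmetry for tie-free inputs
    predu <- rank(pred, ties.method = "first")  # break ties
    expect_equal(rocAuc(predu, occ)$auc + rocAuc(-predu, occ)$auc, 1.0,
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, rep(TRUE, 4)), "one occurrence class")
})

test_that("cross-validation keeps drugs disjoint and selection blind to held-out folds", {
  ds <- plantedDataset(nDrugs = 12, perDrug = 10, p = 60, nsig = 4,
                       es = 1.2, seed = 3)
  seen <- list()
  hook <- function(fold, train_ids) seen[[fold]] <<- train_ids
  ev <- suppressWarnings(
    crossValidate(ds, "anova", m = 8, k = 4, nModels = 3,
                  rfParams = list(nTrees = 5, maxDepth = 0),
                  seed = 21, selectionHook = hook))
  pred <- oofPredictions(ev)
  for (f in 1:4) {
    te_ids <- pred$sample_id[pred$fold == f]
    # leakage guard: selection never saw held-out samples
    expect_length(intersect(seen[[f]], te_ids), 0)
    # drug disjointness between train and test
    expect_length(intersect(unique(pred$drug[pred$fold == f]),
                            unique(pred$drug[pred$fold != f])), 0)
  }
  expect_true(all(!is.na(pred$predicted)))
  expect_true(validObject(ev))
  expect_equal(pooledSCC(ev),
               spearmanCor(pred$actual, pred$predicted))
  # determinism of the whole procedure
  ev2 <- suppressWarnings(
    crossValidate(ds, "anova", m = 8, k = 4, nModels = 3,
                  rfParams = list(nTrees = 5, maxDepth = 0), seed = 21))
  expect_identical(oofPredictions(ev2)$predicted, pred$predicted)
})

test_that("cross-validation detects planted signal and not permuted labels", {
  ds <- plantedDataset(nDrugs = 12, perDrug = 10, p = 80, nsig = 5,
                       es = 1.2, seed = 6)
  ev <- suppressWarnings(
    crossValidate(ds, "anova", m = 8, k = 4, nModels = 5, seed = 2,
                  rfParams = list(nTrees = 5, maxDepth = 0)))
  expect_gt(pooledSCC(ev), 0.4)
  expect_gt(aucValue(ev), 0.7)
  # permuted labels -> no signal (mean over a few seeds close to 0)
  sccs <- vapply(1:5, function(s) {
    dsp <- ds
    set.seed(100 + s)
    perm <- sample(ncol(ds))
    SummarizedExperiment::colData(dsp)$severity <-
      SummarizedExperiment::colData(ds)$severity[perm]
    SummarizedExperiment::colData(dsp)$occurrence <-
      SummarizedExperiment::colData(ds)$occurrence[perm]
    pooledSCC(suppressWarnings(
      crossValidate(dsp, "anova", m = 8, k = 4, nModels = 3, seed = s,
                    rfParams = list(nTrees = 5, maxDepth = 0))))
  }, numeric(1))
  expect_lt(abs(mean(sccs)), 0.15)
})
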