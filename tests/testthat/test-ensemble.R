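test_that("every ensemble member trains on balanced case/control subsamples", {
  ds <- plantedDataset(seed = 2)
  mk <- sprintf("g%03d", 1:6)
  ens <- trainBalancedEnsemble(ds, mk, nModels = 7, seed = 3)
  expect_equal(nModels(ens), 7L)
  expect_true(validObject(ens))
  n_case <- sum(occurrence(ds))
  cases <- colnames(ds)[occurrence(ds)]
  for (s in subsampleLog(ens)) {
    expect_setequal(s$case, cases)              # all cases, every member
    expect_equal(length(s$control), n_case)      # matched control count
    expect_false(anyDuplicated(s$control) > 0)   # without replacement
    expect_true(all(!s$control %in% cases))
  }
  # control draws differ across members
  expect_gt(length(unique(lapply(subsampleLog(ens), `[[`, "control"))), 1L)
})

test_that("the paper-scale imbalance yields 2 x cases per member", {
  # 400 cases vs 13,743 controls -> every member trains on 800 samples
  set.seed(10)
  n <- 14143L
  sev <- integer(n)
  sev[sample(n, 400)] <- sample(1:4, 400, replace = TRUE)
  X <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("g", 1:3), paste0("s", seq_len(n))))
  ds <- makeDataset(X, rep(sprintf("D%03d", 1:160), length.out = n), sev)
  ens <- trainBalancedEnsemble(ds, paste0("g", 1:3), nModels = 2,
                               rfParams = list(nTrees = 2, maxDepth = 4),
                               seed = 1)
  for (s in subsampleLog(ens))
    expect_equal(length(s$case) + length(s$control), 800L)
})

test_that("ensembles are deterministic given the seed", {
  ds <- plantedDataset(seed = 4)
  mk <- sprintf("g%03d", 1:4)
  e1 <- trainBalancedEnsemble(ds, mk, nModels = 4, seed = 11)
  e2 <- trainBalancedEnsemble(ds, mk, nModels = 4, seed = 11)
  expect_identical(subsampleLog(e1), subsampleLog(e2))
  X <- SummarizedExperiment::assay(ds, "exprs")
  expect_identical(predictSeverity(e1, X), predictSeverity(e2, X))
})

test_that("prediction is the member mean and stays inside the member range", {
  ds <- plantedDataset(seed = 5)
  mk <- sprintf("g%03d", 1:4)
  ens <- trainBalancedEnsemble(ds, mk, nModels = 9, seed = 2)
  X <- SummarizedExperiment::assay(ds, "exprs")[, 1:15]
  member_preds <- vapply(ensembleMembers(ens), function(f)
    as.numeric(toxsev:::cpp_predict_forest(f, t(X[mk, ]))),
    numeric(15))
  expect_equal(predictSeverity(ens, X), rowMeans(member_preds),
               tolerance = 1e-12)
  expect_true(all(predictSeverity(ens, X) >= apply(member_preds, 1, min) - 1e-12))
  expect_true(all(predictSeverity(ens, X) <= apply(member_preds, 1, max) + 1e-12))
  # single-member ensemble output equals that member's output
  e1 <- trainBalancedEnsemble(ds, mk, nModels = 1, seed = 2)
  expect_equal(predictSeverity(e1, X),
               as.numeric(toxsev:::cpp_predict_forest(
                 ensembleMembers(e1)[[1]], t(X[mk, ]))),
               tolerance = 1e-12)
})

test_that("a deep single tree reproduces its training targets (overfit sanity)", {
  set.seed(9)
  X <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("g1", "g2"), paste0("s", 1:20)))
  sev <- rep(c(0L, 2L), 10)
  X[1, sev == 2] <- X[1, sev == 2] + 50  # separable
  ds <- makeDataset(X, rep(c("dA", "dB"), each = 10), sev)
  # nModels = 1 with a bootstrap that is forced deterministic by separability
  ens <- trainBalancedEnsemble(ds, c("g1", "g2"), nModels = 1,
                               rfParams = list(nTrees = 25, maxDepth = 0),
                               seed = 7)
  ids <- unlist(subsampleLog(ens)[[1]])
  pred <- predictSeverity(ens, X[, ids])
  expect_equal(pred, as.numeric(sev[match(ids, colnames(X))]),
               tolerance = 1e-9)
})

test_that("degenerate inputs are rejected and scarce controls fall back with a warning", {
  X <- randomExpr(3, 8, seed = 1)
  ds <- makeDataset(X, rep(c("dA", "dB"), 4), c(0L, 1L, 1L, 1L, 1L, 1L, 0L, 1L))
  expect_warning(
    ens <- trainBalancedEnsemble(ds, rownames(X), nModels = 2, seed = 1),
    "with replacement")
  for (s in subsampleLog(ens)) expect_equal(length(s$control), 6L)
  expect_error(trainBalancedEnsemble(ds, c("g001", "nope"), seed = 1),
               "nope")
})
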