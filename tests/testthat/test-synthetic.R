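test_that("the generator is deterministic for a fixed seed", {
  cfg <- cohortConfig(nDrugs = 8, samplesPerDrug = 6, nGenes = 50,
                      nMarkers = 5, seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth@markerGenes, b$truth@markerGenes)
  expect_identical(a$truth@drugGrade, b$truth@drugGrade)
})

test_that("the reference cohort has control-heavy but non-trivial imbalance", {
  cfg <- cohortConfig(nDrugs = 40, samplesPerDrug = 20, nGenes = 2000,
                      nMarkers = 24, effectSize = 0.8,
                      fracToxicDrugs = 0.3, seed = 1)
  sim <- simulateCohort(cfg)
  frac <- mean(sim$samples$severity.necrosis >= 1)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.40)
  # toxic drugs span every grade up to their max
  for (d in names(which(sim$truth@drugGrade > 0))) {
    sev_d <- sim$samples$severity.necrosis[sim$samples$drug_id == d]
    expect_setequal(unique(sev_d), 0:sim$truth@drugGrade[[d]])
  }
})

test_that("with zero effect size, marker and background F statistics are exchangeable", {
  cfg <- cohortConfig(nDrugs = 30, samplesPerDrug = 10, nGenes = 2000,
                      nMarkers = 24, effectSize = 0, fracToxicDrugs = 0.5,
                      seed = 3)
  sim <- simulateCohort(cfg)
  sev <- sim$samples$severity.necrosis
  res <- rowAnova(sim$expression, sev)
  is_marker <- res$gene %in% sim$truth@markerGenes
  ks <- suppressWarnings(stats::ks.test(res$F[is_marker], res$F[!is_marker]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects are severity-monotone with the configured slope", {
  cfg <- cohortConfig(nDrugs = 100, samplesPerDrug = 20, nGenes = 200,
                      nMarkers = 20, effectSize = 0.8, blockSize = 10,
                      fracToxicDrugs = 0.5, seed = 5)
  sim <- simulateCohort(cfg)
  sev <- sim$samples$severity.necrosis
  truth <- sim$truth
  full <- setdiff(truth@markerGenes, truth@weakPair)
  for (g in full) {
    fit <- summary(stats::lm(sim$expression[g, ] ~ sev))$coefficients
    slope <- fit["sev", "Estimate"] * truth@directions[[g]]
    se <- fit["sev", "Std. Error"]
    expect_lt(abs(slope - 0.8), 3 * se)
  }
  # weak pair: effect split across the two members (effectSize * pairSplit)
  for (g in truth@weakPair) {
    fit <- summary(stats::lm(sim$expression[g, ] ~ sev))$coefficients
    slope <- fit["sev", "Estimate"] * truth@directions[[g]]
    expect_lt(abs(slope - 0.8 * 0.5), 3 * fit["sev", "Std. Error"])
  }
  # severity-0 samples: marker means match the (zero) background mean
  ctrl <- sev == 0
  marker_means <- rowMeans(sim$expression[truth@markerGenes, ctrl])
  bg_means <- rowMeans(sim$expression[setdiff(truth@geneIds,
                                              truth@markerGenes), ctrl])
  expect_lt(abs(mean(marker_means) - mean(bg_means)), 0.05)
})

test_that("within-block correlation and the weak-pair correlation match their targets", {
  cfg <- cohortConfig(nDrugs = 100, samplesPerDrug = 20, nGenes = 100,
                      nMarkers = 2, effectSize = 0, blockSize = 10,
                      blockRho = 0.3, pairRho = 0.9, fracToxicDrugs = 0.3,
                      seed = 9)
  sim <- simulateCohort(cfg)
  X <- sim$expression
  pair <- sim$truth@weakPair
  # average off-diagonal correlation inside marker-free blocks
  blocks <- split(rownames(X), rep(seq_len(10), each = 10))
  rhos <- vapply(blocks, function(g) {
    g <- setdiff(g, pair)
    C <- stats::cor(t(X[g, ]))
    mean(C[upper.tri(C)])
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.3), 0.05)
  expect_lt(abs(stats::cor(X[pair[1], ], X[pair[2], ]) - 0.9), 0.05)
})

test_that("simulated annotation plants an enriched term and is otherwise null", {
  cfg <- cohortConfig(nDrugs = 6, samplesPerDrug = 5, nGenes = 80,
                      nMarkers = 10, seed = 2)
  truth <- simulateCohort(cfg)$truth
  ann <- simulateAnnotation(truth, nTerms = 5, termSize = 15, seed = 4)
  expect_identical(ann$truth@plantedTermId, termIds(ann$annotation)[1])
  planted <- termGenes(ann$annotation)[[ann$truth@plantedTermId]]
  expect_gte(length(intersect(planted, truth@markerGenes)),
             ceiling(0.6 * length(truth@markerGenes)))
  # determinism
  ann2 <- simulateAnnotation(truth, nTerms = 5, termSize = 15, seed = 4)
  expect_identical(termGenes(ann2$annotation), termGenes(ann$annotation))
  expect_error(simulateAnnotation(truth, nTerms = 2, termSize = 1000,
                                  seed = 1), "universe")

  # Monte-Carlo check: a random (non-planted) term's marker overlap follows
  # the hypergeometric null
  k0 <- 3L
  hits <- vapply(seq_len(2000), function(s) {
    a <- simulateAnnotation(truth, nTerms = 2, termSize = 15, seed = s)
    ov <- length(intersect(termGenes(a$annotation)[[2]], truth@markerGenes))
    ov >= k0
  }, logical(1))
  theo <- stats::phyper(k0 - 1, 10, 70, 15, lower.tail = FALSE)
  expect_lt(abs(mean(hits) - theo), 0.04)
})
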