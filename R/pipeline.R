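#' Read a pipeline run configuration
#'
#' Plain `key: value` text format, one pair per line; `#` starts a comment.
#' Unknown keys are rejected, numeric keys are coerced, and a `seed` is
#' mandatory: a config without one is refused before any computation.
#'
#' @param path path to the config file
#' @return named list of class `RunConfig`
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  cfg <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  runConfig(cfg)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param ... configuration values (see Details) or a single named list
#' @details Recognized keys (with defaults): cohort -- `n_drugs` (40),
#'   `samples_per_drug` (20), `n_genes` (2000), `n_markers` (24),
#'   `effect_size` (0.8), `block_size` (20), `block_rho` (0.3),
#'   `frac_toxic_drugs` (0.3), `max_grade` (4), `symptom` ("necrosis");
#'   annotation -- `n_terms` (50), `term_size` (20); analysis -- `method`
#'   ("slda"), `m` (32), `k` (10), `n_models` (100), `n_trees` (10),
#'   `lambda2` (1e-3), `normalize` ("global"), `alpha` (0.01), `enrich_mode`
#'   ("plain"); run -- `stages` ("all"), `out_dir`, `seed` (mandatory).
#' @return named list of class `RunConfig`
#' @export
runConfig <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args)))
    args <- args[[1L]]
  num_keys <- c("n_drugs", "samples_per_drug", "n_genes", "n_markers",
                "effect_size", "block_size", "block_rho", "frac_toxic_drugs",
                "max_grade", "n_terms", "term_size", "m", "k", "n_models",
                "n_trees", "lambda2", "alpha", "seed")
  chr_keys <- c("symptom", "method", "normalize", "enrich_mode", "stages",
                "out_dir")
  unknown <- setdiff(names(args), c(num_keys, chr_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    n_drugs = 40, samples_per_drug = 20, n_genes = 2000, n_markers = 24,
    effect_size = 0.8, block_size = 20, block_rho = 0.3,
    frac_toxic_drugs = 0.3, max_grade = 4, symptom = "necrosis",
    n_terms = 50, term_size = 20,
    method = "slda", m = 32, k = 10, n_models = 100, n_trees = 10,
    lambda2 = 1e-3, normalize = "global", alpha = 0.01,
    enrich_mode = "plain", stages = "all", out_dir = ".")
  cfg <- utils::modifyList(defaults, args)
  for (key in intersect(names(cfg), num_keys)) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v)) stop(sprintf("config key '%s' is not numeric", key))
    cfg[[key]] <- v
  }
  if (is.null(cfg$seed))
    stop("config refused: a seed is mandatory for any stochastic step")
  class(cfg) <- "RunConfig"
  cfg
}

# fixed per-stage seed offsets (counter scheme): reordering stages never
# silently changes a stage's random stream
.stageSeed <- function(seed, stage) {
  as.integer(seed) + c(simulate = 101L, select = 202L,
                       evaluate = 303L, enrich = 404L)[[stage]]
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages (`simulate`, `select`, `evaluate`, `enrich`,
#' or `all`) against the configured synthetic cohort, writing each stage's
#' artifacts plus a `manifest.json` (parameters, per-stage seeds, output
#' files, package version) into `out_dir`. Reruns with an identical config
#' are bit-identical for all deterministic outputs. A stage failure aborts
#' with the stage name and the underlying error.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()]
#' @param outDir output directory (created if needed); defaults to
#'   `config$out_dir`
#' @return (invisibly) list with the in-memory stage results and the manifest
#' @export
runPipeline <- function(config, outDir = config$out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (identical(config$stages, "all"))
    c("simulate", "select", "evaluate", "enrich")
  else strsplit(config$stages, ",", fixed = TRUE)[[1L]]
  files <- character(0)
  out <- list()
  runStage <- function(stage, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs (seed %d)", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    .stageSeed(config$seed, stage)))
    res
  }

  # simulate is always needed as input to later stages
  sim <- runStage("simulate", function() {
    cc <- cohortConfig(
      nDrugs = config$n_drugs, samplesPerDrug = config$samples_per_drug,
      nGenes = config$n_genes, nMarkers = config$n_markers,
      effectSize = config$effect_size, blockSize = config$block_size,
      blockRho = config$block_rho, fracToxicDrugs = config$frac_toxic_drugs,
      maxGrade = config$max_grade, symptom = config$symptom,
      seed = .stageSeed(config$seed, "simulate"))
    sim <- simulateCohort(cc)
    ann <- simulateAnnotation(sim$truth, nTerms = config$n_terms,
                              termSize = config$term_size,
                              seed = .stageSeed(config$seed, "simulate"))
    sim$truth <- ann$truth
    sim$annotation <- ann$annotation
    if ("simulate" %in% stages) {
      writeExpression(sim$expression, file.path(outDir, "expression.tsv"))
      writeSamples(sim$samples, file.path(outDir, "samples.tsv"))
      writeGMT(sim$annotation, file.path(outDir, "annotation.gmt"))
      utils::write.table(
        data.frame(gene = sim$truth@markerGenes,
                   direction = unname(sim$truth@directions)),
        file.path(outDir, "truth_markers.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, "expression.tsv", "samples.tsv", "annotation.gmt",
                  "truth_markers.tsv")
    }
    sim
  })
  out$truth <- sim$truth

  ds <- buildDataset(sim$expression, sim$samples, config$symptom)

  if (any(c("select", "enrich") %in% stages)) {
    out$markers <- runStage("select", function() {
      mk <- selectMarkers(ds, method = config$method, m = config$m,
                          lambda2 = config$lambda2)
      tab <- data.frame(rank = seq_along(markerGenes(mk)),
                        gene = markerGenes(mk),
                        score = unname(markerScores(mk)))
      pv <- markerPvalues(mk)
      if (length(pv)) tab$p_value <- unname(pv)
      utils::write.table(tab, file.path(outDir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, "markers.tsv")
      mk
    })
  }

  if ("evaluate" %in% stages) {
    out$evaluation <- runStage("evaluate", function() {
      ev <- crossValidate(ds, method = config$method, m = config$m,
                          k = config$k, nModels = config$n_models,
                          rfParams = list(nTrees = config$n_trees,
                                          maxDepth = 0L),
                          lambda2 = config$lambda2,
                          normalize = config$normalize,
                          seed = .stageSeed(config$seed, "evaluate"))
      metrics <- list(symptom = ev@symptom, method = ev@method, m = ev@m,
                      pooled_scc = ev@pooledSCC,
                      mean_fold_scc = ev@meanFoldSCC,
                      per_fold_scc = ev@perFoldSCC, auc = ev@auc)
      jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.table(oofPredictions(ev),
                         file.path(outDir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rocPoints(ev), file.path(outDir, "roc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, "metrics.json", "predictions.tsv", "roc.tsv")
      ev
    })
  }

  if ("enrich" %in% stages) {
    out$enrichment <- runStage("enrich", function() {
      er <- enrichMarkers(out$markers, sim$annotation,
                          universe = rownames(sim$expression),
                          alpha = config$alpha, mode = config$enrich_mode)
      utils::write.table(er, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, "enrichment.tsv")
      er
    })
  }

  manifest <- list(
    package = "toxsev",
    version = as.character(utils::packageVersion("toxsev")),
    stages = stages,
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = stages), .stageSeed,
                         seed = config$seed),
    parameters = unclass(config),
    outputs = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
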