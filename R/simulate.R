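#' Configuration for a synthetic toxicogenomics cohort
#'
#' Describes the stated world of the generator: a multi-drug in-vivo cohort
#' with control-heavy imbalance, ordinal severity grades, planted
#' severity-monotone marker genes and correlated gene blocks. Defaults follow
#' the reference validation cohort (40 drugs x 20 samples, 2,000 genes, 24
#' markers, per-grade shift 0.8 SD, 30% toxic drugs).
#'
#' @param nDrugs number of drugs.
#' @param samplesPerDrug samples per drug (a dose-like series).
#' @param nGenes number of genes.
#' @param nMarkers number of planted severity-monotone markers (>= 2; the
#'   first two form the correlated weak pair).
#' @param effectSize per-grade mean shift in SD units for a full marker; the
#'   weak pair splits this effect across its two members.
#' @param blockSize genes per correlated latent block.
#' @param blockRho within-block gene-gene correlation, in \[0, 1).
#' @param fracToxicDrugs probability that a drug is toxic, in (0, 1].
#' @param maxGrade highest severity grade a toxic drug can induce (<= 4).
#' @param pairRho noise correlation of the weak pair (strongly mutually
#'   correlated but individually weak).
#' @param pairSplit fraction of `effectSize` carried by each weak-pair
#'   member (opposite signs). At the defaults the members carry half a full
#'   marker's effect each -- weak relative to full markers -- while their
#'   contrast has signal-to-noise `2 * pairSplit * effectSize / sqrt(2 * (1 -
#'   pairRho))` per grade, 2.2x a full marker.
#' @param spontaneousFrac fraction of case findings flagged spontaneous.
#' @param symptom symptom name used in the sample table.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return validated list of class `CohortConfig`
#' @export
cohortConfig <- function(nDrugs = 40L, samplesPerDrug = 20L, nGenes = 2000L,
                         nMarkers = 24L, effectSize = 0.8, blockSize = 20L,
                         blockRho = 0.3, fracToxicDrugs = 0.3,
                         maxGrade = 4L, pairRho = 0.9, pairSplit = 0.5,
                         spontaneousFrac = 0.05, symptom = "necrosis",
                         seed = 1L) {
  cfg <- list(nDrugs = as.integer(nDrugs),
              samplesPerDrug = as.integer(samplesPerDrug),
              nGenes = as.integer(nGenes), nMarkers = as.integer(nMarkers),
              effectSize = effectSize, blockSize = as.integer(blockSize),
              blockRho = blockRho, fracToxicDrugs = fracToxicDrugs,
              maxGrade = as.integer(maxGrade), pairRho = pairRho,
              pairSplit = pairSplit,
              spontaneousFrac = spontaneousFrac, symptom = symptom,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nDrugs >= 1L, samplesPerDrug >= 1L, nGenes >= 1L,
              nMarkers >= 2L, effectSize >= 0, blockSize >= 1L,
              blockRho >= 0, blockRho < 1,
              fracToxicDrugs > 0, fracToxicDrugs <= 1,
              maxGrade >= 1L, maxGrade <= 4L,
              pairRho >= 0, pairRho < 1, pairSplit > 0, pairSplit <= 0.5,
              spontaneousFrac >= 0, spontaneousFrac < 1)
    if (nMarkers > nGenes) stop("nMarkers must not exceed nGenes")
  })
  class(cfg) <- "CohortConfig"
  cfg
}

# run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a multi-drug toxicogenomics cohort
#'
#' Generative model:
#' \enumerate{
#' \item Each drug is toxic with probability `fracToxicDrugs` (at least one
#'   drug is always toxic); a toxic drug draws a maximum induced grade in
#'   1..`maxGrade` and its samples receive severities deterministically
#'   monotone in a latent dose index, spanning 0..max grade. Non-toxic drugs'
#'   samples are all grade 0.
#' \item Gene expression is a within-block latent factor (correlation
#'   `blockRho`) plus unit-variance noise, so marginal scale is 1 SD and
#'   `effectSize` reads directly in SD units. Marker genes additionally shift
#'   their mean by `direction * effectSize * grade`.
#' \item The first two markers form the correlated weak pair: their noise is
#'   mutually correlated at `pairRho` and the effect is split across the pair
#'   with opposite signs (+/- `effectSize * pairSplit` per grade), so each is
#'   individually weak -- at the edge of univariate detectability -- while
#'   their contrast cancels the shared noise and is the strongest
#'   discriminative feature in the data: the test bed for multivariate
#'   (sparse-discriminant) selection beating univariate screening.
#' \item A small random subset of case findings is flagged spontaneous.
#' }
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [cohortConfig()]
#' @return list with `expression` (genes x samples matrix), `samples`
#'   (data.frame in the [readSamples()] layout) and `truth`
#'   ([GroundTruth-class])
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  c2 <- config
  withLocalSeed(c2$seed, {
    nD <- c2$nDrugs; S <- c2$samplesPerDrug
    n <- nD * S; p <- c2$nGenes
    drug_ids <- sprintf("D%03d", seq_len(nD))
    sample_ids <- sprintf("S%05d", seq_len(n))
    gene_ids <- sprintf("g%05d", seq_len(p))

    toxic <- stats::runif(nD) < c2$fracToxicDrugs
    if (!any(toxic)) toxic[1L] <- TRUE
    max_grade <- integer(nD)
    max_grade[toxic] <- sample(seq_len(c2$maxGrade), sum(toxic),
                               replace = TRUE)

    sev <- integer(n)
    drug_of <- rep(drug_ids, each = S)
    for (d in seq_len(nD)) {
      if (!toxic[d]) next
      g <- max_grade[d]
      dose <- if (S == 1L) 0 else (seq_len(S) - 1) / (S - 1)
      sev[(d - 1L) * S + seq_len(S)] <- pmin(g, floor(dose * (g + 1L)))
    }

    nb <- ceiling(p / c2$blockSize)
    block <- rep(seq_len(nb), each = c2$blockSize)[seq_len(p)]
    Z <- matrix(stats::rnorm(nb * n), nb, n)
    E <- sqrt(c2$blockRho) * Z[block, , drop = FALSE] +
      sqrt(1 - c2$blockRho) * matrix(stats::rnorm(p * n), p, n)

    marker_idx <- sample.int(p, c2$nMarkers)
    dirs <- sample(c(1, -1), c2$nMarkers, replace = TRUE)
    dirs[1:2] <- c(1, -1)  # weak pair: effect split with opposite signs
    w <- stats::rnorm(n)
    for (j in 1:2) {
      E[marker_idx[j], ] <- sqrt(c2$pairRho) * w +
        sqrt(1 - c2$pairRho) * stats::rnorm(n)
    }
    eff <- rep(c2$effectSize, c2$nMarkers)
    eff[1:2] <- c2$effectSize * c2$pairSplit
    for (j in seq_len(c2$nMarkers)) {
      E[marker_idx[j], ] <- E[marker_idx[j], ] + dirs[j] * eff[j] * sev
    }
    dimnames(E) <- list(gene_ids, sample_ids)

    spont <- rep(FALSE, n)
    case_idx <- which(sev >= 1L)
    n_sp <- round(c2$spontaneousFrac * length(case_idx))
    if (n_sp > 0L) spont[sample(case_idx, n_sp)] <- TRUE

    samples <- data.frame(sample_id = sample_ids, drug_id = drug_of,
                          sev, spont, stringsAsFactors = FALSE)
    colnames(samples)[3:4] <- paste0(c("severity.", "spontaneous."),
                                     c2$symptom)

    truth <- new("GroundTruth",
                 markerGenes = gene_ids[marker_idx],
                 directions = stats::setNames(dirs, gene_ids[marker_idx]),
                 weakPair = gene_ids[marker_idx[1:2]],
                 drugGrade = stats::setNames(max_grade, drug_ids),
                 geneIds = gene_ids,
                 plantedTermId = "")
    list(expression = E, samples = samples, truth = truth)
  })
}

#' Simulate a gene-set annotation with one planted enriched term
#'
#' The first term (`SET0001`) is planted: it contains `plantedFrac` of the
#' true marker genes (at least 60%), padded with random non-marker genes to
#' `termSize`. The remaining terms are drawn uniformly from the gene
#' universe, so their marker overlap follows the hypergeometric null.
#' Deterministic for a fixed seed.
#'
#' @param truth a [GroundTruth-class] from [simulateCohort()]
#' @param nTerms number of gene sets (>= 1)
#' @param termSize genes per set
#' @param plantedFrac fraction of markers placed in the planted term
#' @param seed integer seed
#' @return list with `annotation` ([AnnotationTable-class]) and `truth` (the
#'   input with `plantedTermId` filled in)
#' @export
simulateAnnotation <- function(truth, nTerms = 50L, termSize = 20L,
                               plantedFrac = 0.7, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"), nTerms >= 1L,
            plantedFrac >= 0.6, plantedFrac <= 1)
  universe <- truth@geneIds
  if (termSize > length(universe))
    stop("termSize exceeds the gene universe")
  withLocalSeed(seed, {
    markers <- truth@markerGenes
    n_plant <- ceiling(plantedFrac * length(markers))
    if (termSize < n_plant)
      stop("termSize too small to hold the planted marker fraction")
    planted <- sample(markers, n_plant)
    pad <- sample(setdiff(universe, markers), termSize - n_plant)
    genes <- vector("list", nTerms)
    genes[[1L]] <- sample(c(planted, pad))  # shuffle member order
    if (nTerms > 1L) {
      for (i in 2:nTerms) genes[[i]] <- sample(universe, termSize)
    }
    ids <- sprintf("SET%04d", seq_len(nTerms))
    nms <- c("planted severity-response module",
             rep("random gene set", max(0L, nTerms - 1L)))
    ann <- new("AnnotationTable", termId = ids, termName = nms, genes = genes)
    truth@plantedTermId <- ids[1L]
    list(annotation = ann, truth = truth)
  })
}
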