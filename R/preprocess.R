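#' Assemble the modeling dataset for one symptom
#'
#' Removes samples whose finding for this symptom is flagged spontaneous AND
#' has severity >= 1 (only drug-induced findings are kept; spontaneous flags
#' on severity-0 records are controls and are retained), derives the binary
#' occurrence label (severity >= 1), and packages expression plus aligned
#' metadata into a [SymptomDataset-class]. Expression values are never
#' altered, only columns subset.
#'
#' @param expression genes x samples numeric matrix with dimnames
#' @param samples sample table as returned by [readSamples()]
#' @param symptom symptom name (must match a `severity.<symptom>` column)
#' @return a [SymptomDataset-class]
#' @export
buildDataset <- function(expression, samples, symptom) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  if (!symptom %in% sampleSymptoms(samples))
    stop(sprintf("unknown symptom '%s'; available: %s", symptom,
                 paste(sampleSymptoms(samples), collapse = ", ")))
  miss <- setdiff(samples$sample_id, colnames(expression))
  if (length(miss))
    stop("sample(s) missing from the expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  sev <- samples[[paste0("severity.", symptom)]]
  sp <- samples[[paste0("spontaneous.", symptom)]]
  keep <- !(sp & sev >= 1L)
  sev <- sev[keep]
  ids <- samples$sample_id[keep]
  if (!any(sev >= 1L))
    stop(sprintf("degenerate dataset: no case samples for symptom '%s'",
                 symptom))
  se <- SummarizedExperiment(
    assays = list(exprs = expression[, ids, drop = FALSE]),
    colData = DataFrame(drug = samples$drug_id[keep],
                        severity = as.integer(sev),
                        occurrence = sev >= 1L,
                        row.names = ids))
  new("SymptomDataset", se, symptom = symptom)
}

#' Z-score genes to mean 0, SD 1
#'
#' Standardizes each gene (row) to mean 0 and *population* standard deviation
#' 1 (denominator n), across all samples. Zero-variance genes are listed in a
#' warning and left centered at 0 (all values 0).
#'
#' @param X genes x samples numeric matrix, or a [SymptomDataset-class]
#'   (whose `exprs` assay is standardized in place)
#' @return object of the same type as the input
#' @export
zscoreGenes <- function(X) {
  if (is(X, "SymptomDataset")) {
    SummarizedExperiment::assay(X, "exprs") <-
      zscoreGenes(SummarizedExperiment::assay(X, "exprs"))
    return(X)
  }
  stopifnot(is.matrix(X), is.numeric(X))
  ctr <- X - rowMeans(X)
  sdp <- sqrt(rowMeans(ctr^2))
  zero <- sdp == 0
  if (any(zero)) {
    warning("zero-variance gene(s) left at 0: ",
            paste(utils::head(rownames(X)[zero], 10L), collapse = ", "))
    sdp[zero] <- 1
  }
  ctr / sdp
}
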