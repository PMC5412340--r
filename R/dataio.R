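#' Read an expression matrix from TSV
#'
#' Expects a tab-separated table with gene ids in the first column and a
#' header row of sample ids: the microarray convention of genes in rows,
#' samples in columns. Values must parse as finite reals; missing values are
#' rejected rather than imputed.
#'
#' @param path path to a TSV file
#' @return numeric matrix, genes x samples, with unique dimnames
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or non-finite expression value at gene '%s', sample '%s'",
      gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpression()]; round trips are lossless (values written
#' with full double precision).
#'
#' @param x numeric genes x samples matrix with dimnames
#' @param path output path
#' @export
writeExpression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Columns: `sample_id`, `drug_id`, then one `severity.<symptom>` (integer
#' grade 0--4) and one `spontaneous.<symptom>` (logical) column per symptom.
#' A grade of 0 means the symptom did not occur in that sample; grades 1--4
#' grade its severity (minimal, slight, moderate, severe).
#'
#' @param path path to a TSV file
#' @return data.frame with character ids, integer severity columns and
#'   logical spontaneous columns
#' @export
readSamples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (!all(c("sample_id", "drug_id") %in% colnames(df)))
    stop("sample table must contain 'sample_id' and 'drug_id' columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$drug_id <- as.character(df$drug_id)
  sev_cols <- grep("^severity\\.", colnames(df), value = TRUE)
  sp_cols <- grep("^spontaneous\\.", colnames(df), value = TRUE)
  if (!length(sev_cols))
    stop("sample table declares no 'severity.<symptom>' column")
  for (cl in sev_cols) {
    v <- suppressWarnings(as.integer(df[[cl]]))
    if (anyNA(v) || !all(v %in% 0:4))
      stop(sprintf("column '%s' contains a severity grade outside {0,...,4}",
                   cl))
    df[[cl]] <- v
  }
  for (cl in sp_cols) df[[cl]] <- as.logical(df[[cl]])
  # symptoms must carry both columns
  sym_sev <- sub("^severity\\.", "", sev_cols)
  sym_sp <- sub("^spontaneous\\.", "", sp_cols)
  miss <- setdiff(sym_sev, sym_sp)
  if (length(miss))
    stop("missing spontaneous column(s) for symptom(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write a sample annotation table to TSV
#' @param samples data.frame as returned by [readSamples()]
#' @param path output path
#' @export
writeSamples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' List the symptoms declared in a sample table
#' @param samples data.frame as returned by [readSamples()]
#' @return character vector of symptom names
#' @export
sampleSymptoms <- function(samples) {
  sub("^severity\\.", "",
      grep("^severity\\.", colnames(samples), value = TRUE))
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, `term_id <tab> description <tab> gene1
#' <tab> gene2 ...`. Member genes are deduplicated within each term.
#'
#' @param path path to a GMT file
#' @return an [AnnotationTable-class]
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- nms <- character(length(lines))
  genes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    ids[i] <- f[1L]
    nms[i] <- f[2L]
    g <- unique(f[-(1:2)])
    if (!length(g))
      stop(sprintf("GMT line %d has an empty gene list after deduplication", i))
    genes[[i]] <- g
  }
  new("AnnotationTable", termId = ids, termName = nms, genes = genes)
}

#' Write gene sets in GMT format
#' @param annotation an [AnnotationTable-class]
#' @param path output path
#' @export
writeGMT <- function(annotation, path) {
  stopifnot(is(annotation, "AnnotationTable"))
  lines <- vapply(seq_along(annotation@termId), function(i) {
    paste(c(annotation@termId[i], annotation@termName[i],
            annotation@genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
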