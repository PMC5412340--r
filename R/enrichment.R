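#' Gene-set over-representation screen for a marker set
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of each annotation term
#' against the marker set, within a background universe (by default all genes
#' of the expression matrix the markers were selected from). For a term with
#' `K` members in the universe of size `N` and a marker set of size `n` with
#' overlap `k`, `p = P(X >= k)` under the hypergeometric null. `mode =
#' "ease"` substitutes `k - 1` successes (floored at 0) for `k`, the
#' conservative EASE-score convention of the DAVID tool. Genes absent from
#' the universe never count towards `k` or `n`.
#'
#' No multiple-testing correction is applied by default (screening at raw
#' `p < alpha`); Benjamini-Hochberg is available via `adjust = "BH"`, in
#' which case significance is flagged on the adjusted values.
#'
#' @param markers a [MarkerSet-class] or character vector of gene ids
#' @param annotation an [AnnotationTable-class]
#' @param universe character vector of background gene ids
#' @param alpha significance level (default 0.01)
#' @param mode `"plain"` (default) or `"ease"`
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame sorted by ascending p with columns term_id, term_name,
#'   k, K, n, N, p_value (and p_adjust when `adjust = "BH"`), significant;
#'   the test mode is recorded in the `"mode"` attribute
#' @export
enrichMarkers <- function(markers, annotation, universe, alpha = 0.01,
                          mode = c("plain", "ease"),
                          adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  stopifnot(is(annotation, "AnnotationTable"),
            alpha > 0, alpha < 1)
  genes <- if (is(markers, "MarkerSet")) markerGenes(markers)
           else as.character(markers)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty background universe")
  genes <- intersect(genes, universe)
  if (!length(genes))
    stop("empty marker set after intersection with the universe")
  N <- length(universe)
  n <- length(genes)

  res <- lapply(seq_along(annotation@termId), function(i) {
    tg <- intersect(annotation@genes[[i]], universe)
    K <- length(tg)
    k <- length(intersect(tg, genes))
    p <- if (k == 0L) 1 else {
      keff <- if (mode == "ease") k - 1L else k
      if (keff == 0L) 1
      else stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(term_id = annotation@termId[i],
               term_name = annotation@termName[i],
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjust < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  attr(out, "mode") <- mode
  out
}
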