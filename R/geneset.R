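#' Hypergeometric over-representation of gene sets
#'
#' Generic over-representation test of a query gene list (e.g. the genes
#' alternatively spliced in one knockdown) against a user-supplied
#' annotation table of terms. For each term with gene set `T` (intersected
#' with the universe), the p-value is the hypergeometric upper tail
#' `P(overlap >= k)` given the universe size, `|T|` and the query size —
#' the one-sided Fisher test on the induced 2x2 table. p-values are
#' BH-adjusted across terms and, by default, only terms with raw
#' `p < p_max` are returned. The universe should normally be the genes
#' observable by the assay (here: all genes appearing in any event table
#' for the cell line), not the whole genome.
#'
#' @param query Character vector of query gene symbols (subset of
#'   `universe`).
#' @param annotation Annotation table from [read_gmt()] (columns
#'   `term_id`, `term_name`, list column `genes`).
#' @param universe Character vector of background genes.
#' @param p_max Raw p-value filter (default 0.05); ignored when
#'   `report_all = TRUE`.
#' @param report_all Also report terms with zero overlap / p >= p_max.
#' @return Data frame with `term_id`, `term_name`, `n_term`, `n_query`,
#'   `overlap`, `pvalue`, `p_adjusted`, ordered by p-value.
#' @export
overrepresentation <- function(query, annotation, universe,
                               p_max = 0.05, report_all = FALSE) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains gene(s) outside the universe")
  if (length(query) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      n_term = integer(), n_query = integer(),
                      overlap = integer(), pvalue = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(universe); n <- length(query)
  term_genes <- lapply(annotation$genes, intersect, y = universe)
  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) length(intersect(g, query)),
              integer(1))
  pval <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = annotation$term_id,
                    term_name = annotation$term_name,
                    n_term = K, n_query = n, overlap = k,
                    pvalue = pval, stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  if (!report_all) out <- out[out$pvalue < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
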