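# Per-(cell line, lncRNA, RBP) binding enrichment. The 2x2 contingency
# table contrasts the proximal regions of one lncRNA knockdown against the
# regions of all other knockdowns in the same cell line, split by whether
# the RBP binds them:
#
#                bound   unbound
#   this lncRNA    x        y
#   background     a        b

#' Contingency table for one (lncRNA, RBP) pair
#'
#' `x`/`y` count the focal lncRNA's proximal regions bound/unbound by the
#' RBP; `a`/`b` count the background (all other lncRNA knockdowns in the
#' same cell line). Counting is region-level; `per_gene = TRUE` collapses
#' regions to genes first (a gene counts as bound if any of its regions
#' is), for the coarser gene-level reading of binding.
#'
#' @param bf A `binding_flags` object for one cell line ([bound_flags()]).
#' @param lncrna Focal lncRNA (must label at least one region).
#' @param rbp RBP column present in the flag matrix.
#' @param per_gene Count genes instead of regions.
#' @return Named numeric vector `c(x, y, a, b)`.
#' @export
build_contingency <- function(bf, lncrna, rbp, per_gene = FALSE) {
  stopifnot(inherits(bf, "binding_flags"))
  if (!rbp %in% colnames(bf$flags))
    stop("RBP ", rbp, " has no peaks in cell line ", bf$cell_line)
  focal <- bf$regions$lncrna == lncrna
  if (!any(focal))
    stop("lncRNA ", lncrna, " has no proximal regions in cell line ",
         bf$cell_line, " (degenerate table)")
  flag <- bf$flags[, rbp]
  if (per_gene) {
    unit <- paste(bf$regions$gene_symbol, bf$regions$lncrna)
    bound_unit <- tapply(flag, unit, any)
    focal_unit <- tapply(focal, unit, any)
    flag <- as.logical(bound_unit)
    focal <- as.logical(focal_unit)
  }
  x <- sum(flag & focal); y <- sum(!flag & focal)
  a <- sum(flag & !focal); b <- sum(!flag & !focal)
  c(x = x, y = y, a = a, b = b)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test of binding over-representation on the 2x2 table
#' `rbind(c(x, y), c(a, b))`, conditional on both margins (the
#' hypergeometric/noncentral reading of Fisher's test). The hypergeometric
#' tail is evaluated in log-factorial arithmetic (`lchoose`) so large
#' margins stay numerically stable; the two-sided p sums all tables whose
#' conditional probability does not exceed the observed one (with the
#' customary `1 + 1e-7` relative tolerance for ties). The odds ratio is
#' the sample odds ratio `(x*b)/(y*a)`, `Inf` when `y*a = 0` with
#' `x*b > 0`, and `NaN` for the doubly degenerate `0/0`.
#'
#' @param x,y,a,b Non-negative counts (see [build_contingency()]).
#' @param alternative `"greater"` (default; enrichment of binding),
#'   `"less"`, or `"two.sided"`.
#' @return List with `odds_ratio` and `pvalue` (`NA` for the all-zero
#'   table, which carries no information).
#' @export
fisher_exact <- function(x, y, a, b,
                         alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(x >= 0, y >= 0, a >= 0, b >= 0)
  m1 <- x + y; m2 <- a + b; K <- x + a; N <- m1 + m2
  odds <- if (y * a == 0) {
    if (x * b == 0) NaN else Inf
  } else (x * b) / (y * a)
  if (N == 0) return(list(odds_ratio = NaN, pvalue = NA_real_))
  lo <- max(0, K - m2); hi <- min(K, m1)
  j <- lo:hi
  logpmf <- lchoose(m1, j) + lchoose(m2, K - j) - lchoose(N, K)
  pmf <- exp(logpmf)
  obs <- which(j == x)
  p <- switch(alternative,
              greater = sum(pmf[j >= x]),
              less = sum(pmf[j <= x]),
              two.sided = sum(pmf[pmf <= pmf[obs] * (1 + 1e-7)]))
  list(odds_ratio = odds, pvalue = min(1, p))
}

#' Adjust enrichment p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (default) over one cell line's pooled tests.
#' `NA` entries (tests not performed — degenerate tables) are excluded
#' from the number of tests `m` and stay `NA`.
#'
#' @param p Numeric vector of raw p-values, `NA` for null results.
#' @param method `"BH"` (default), `"bonferroni"` or `"BY"`.
#' @return Adjusted p-values, same length and `NA` pattern as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "BY")) {
  method <- match.arg(method)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = method, n = sum(ok))
  out
}

#' Binding-enrichment tests for every (lncRNA, RBP) pair of a cell line
#'
#' Runs [build_contingency()] + [fisher_exact()] for every lncRNA and
#' every RBP with peaks in the cell line, then adjusts p-values across all
#' of the cell line's tests. An RBP bound in every region of the cell line
#' has no unbound observations (`y + b = 0`): the test is undefined and
#' the whole column is a null result (`NA` p-values), the behaviour
#' ubiquitously-binding RBPs show in these heatmaps. The all-zero table is
#' null for the same reason.
#'
#' @param bf A `binding_flags` object for one cell line.
#' @param alternative Test sidedness, see [fisher_exact()].
#' @param method Adjustment method, see [adjust_pvalues()].
#' @param alpha Unused here; kept in results metadata for downstream
#'   sponge scoring.
#' @param per_gene Count genes instead of regions.
#' @return Data frame of class `enrichment_results`: one row per
#'   (lncRNA, RBP) with `cell_line`, `lncrna`, `rbp`, `x`, `y`, `a`, `b`,
#'   `odds_ratio`, `pvalue`, `p_adjusted`, `neg_log_p_adj`.
#' @export
run_enrichment <- function(bf, alternative = "greater", method = "BH",
                           alpha = 0.05, per_gene = FALSE) {
  stopifnot(inherits(bf, "binding_flags"))
  lncrnas <- unique(bf$regions$lncrna)
  rbps <- colnames(bf$flags)
  grid <- expand.grid(lncrna = lncrnas, rbp = rbps,
                      stringsAsFactors = FALSE)
  tabs <- t(vapply(seq_len(nrow(grid)), function(i) {
    build_contingency(bf, grid$lncrna[i], grid$rbp[i], per_gene = per_gene)
  }, numeric(4)))
  res <- data.frame(cell_line = bf$cell_line, grid, tabs,
                    stringsAsFactors = FALSE)
  null_row <- (res$y + res$b) == 0 | (res$x + res$y + res$a + res$b) == 0
  stat <- lapply(seq_len(nrow(res)), function(i) {
    if (null_row[i]) return(list(odds_ratio = NaN, pvalue = NA_real_))
    fisher_exact(res$x[i], res$y[i], res$a[i], res$b[i],
                 alternative = alternative)
  })
  res$odds_ratio <- vapply(stat, `[[`, numeric(1), "odds_ratio")
  res$pvalue <- vapply(stat, `[[`, numeric(1), "pvalue")
  res$p_adjusted <- adjust_pvalues(res$pvalue, method = method)
  res$neg_log_p_adj <- ifelse(is.na(res$p_adjusted), NA_real_,
                              -log10(res$p_adjusted))
  attr(res, "alternative") <- alternative
  attr(res, "method") <- method
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' lncRNA x RBP significance matrix for heatmap display
#'
#' Cells hold `-log10(adjusted p)`; `NA` marks null results (tests not
#' performed, e.g. RBPs with no unbound regions anywhere in the cell
#' line — rendered grey in heatmaps, deliberately distinct from 0). Rows
#' and columns are ordered by hierarchical clustering with the
#' 1 - Spearman distance when both axes have at least two levels;
#' pairs without complete observations get the maximal distance 2.
#'
#' @param results `enrichment_results` for one cell line.
#' @param cluster Reorder rows/columns by clustering (default `TRUE`).
#' @param linkage Agglomeration method (default `"average"`).
#' @return Numeric matrix, lncRNAs x RBPs, possibly with `NA` cells.
#' @export
enrichment_heatmap_matrix <- function(results, cluster = TRUE,
                                      linkage = "average") {
  stopifnot(inherits(results, "enrichment_results"))
  if (length(unique(results$cell_line)) > 1L)
    stop("one cell line at a time (panels are per cell line)")
  lnc <- sort(unique(results$lncrna)); rbp <- sort(unique(results$rbp))
  m <- matrix(NA_real_, length(lnc), length(rbp),
              dimnames = list(lnc, rbp))
  m[cbind(match(results$lncrna, lnc), match(results$rbp, rbp))] <-
    results$neg_log_p_adj
  if (cluster && nrow(m) >= 2L && ncol(m) >= 2L) {
    ord <- cluster_matrix(m, axis = "both", linkage = linkage,
                          na_action = "max_distance")
    m <- m[ord$row_order, ord$col_order, drop = FALSE]
  }
  m
}

#' Write enrichment results as TSV (nulls serialized as NA)
#' @param results `enrichment_results` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Render the enrichment heatmap
#'
#' Thin wrapper over `pheatmap` drawing the `-log10(adjusted p)` matrix
#' with null cells in grey. Requires the `pheatmap` package.
#'
#' @param m Matrix from [enrichment_heatmap_matrix()].
#' @param ... Passed to `pheatmap::pheatmap`.
#' @return The pheatmap object, invisibly.
#' @export
plot_enrichment_heatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_enrichment_heatmap() needs the 'pheatmap' package")
  ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           na_col = "grey", ...)
  invisible(ph)
}
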