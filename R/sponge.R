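# RBP-sponge quantification. The sponge hypothesis: an abundant lncRNA
# titrates many RBPs away from pre-mRNA targets, so knocking it down
# releases RBPs and perturbs splicing broadly. Operationalized as binding
# breadth: the fraction of tested RBPs whose binding is significantly
# enriched near the knockdown's splice events.

#' Sponge (binding-breadth) profiles per lncRNA
#'
#' For each lncRNA in each cell line: `n_rbps_tested` counts RBPs with a
#' non-null enrichment test, `n_rbps_significant` those with adjusted
#' p < `alpha`, and `breadth` their ratio. Null cells are excluded from
#' both numerator and denominator. Profiles are sorted by breadth
#' (descending), ties broken by `n_rbps_significant` then lncRNA name, and
#' ranked within each cell line. A lncRNA whose tests are all null gets an
#' undefined breadth and is flagged.
#'
#' @param results `enrichment_results` (one or more cell lines row-bound).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return Data frame with `cell_line`, `lncrna`, `n_rbps_tested`,
#'   `n_rbps_significant`, `breadth`, `rank`, `defined`.
#' @export
sponge_scores <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("cell_line", "lncrna", "rbp", "p_adjusted") %in%
                  names(results)))
  out <- do.call(rbind, lapply(split(results, results$cell_line),
                               function(res) {
    profs <- do.call(rbind, lapply(split(res, res$lncrna), function(r) {
      tested <- sum(!is.na(r$p_adjusted))
      sig <- sum(r$p_adjusted < alpha, na.rm = TRUE)
      data.frame(cell_line = r$cell_line[1L], lncrna = r$lncrna[1L],
                 n_rbps_tested = tested, n_rbps_significant = sig,
                 breadth = if (tested > 0L) sig / tested else NA_real_,
                 defined = tested > 0L, stringsAsFactors = FALSE)
    }))
    ord <- order(-ifelse(is.na(profs$breadth), -Inf, profs$breadth),
                 -profs$n_rbps_significant, profs$lncrna)
    profs <- profs[ord, , drop = FALSE]
    profs$rank <- seq_len(nrow(profs))
    profs
  }))
  rownames(out) <- NULL
  out[, c("cell_line", "lncrna", "n_rbps_tested", "n_rbps_significant",
          "breadth", "rank", "defined")]
}

#' 1 - Spearman rank correlation distance matrix
#'
#' Pairwise distance `d(u, v) = 1 - rho(u, v)` between the rows of a
#' matrix, with Spearman's rank correlation `rho` (range `[0, 2]`:
#' identically ranked rows are at distance 0, perfectly anti-ranked rows
#' at 2). A row with zero variance has no defined rank correlation; its
#' distances are set to the maximum (2) with a warning, so it joins the
#' dendrogram last rather than aborting the clustering. The same rule
#' covers row pairs with no complete observations when `na_action =
#' "max_distance"`.
#'
#' @param m Numeric matrix (rows are clustered).
#' @param na_action `"fail"` (default) or `"max_distance"` for matrices
#'   with `NA` cells.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(m, na_action = c("fail", "max_distance")) {
  na_action <- match.arg(na_action)
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  if (anyNA(m) && na_action == "fail")
    stop("matrix has NA cells; use na_action = 'max_distance'")
  rho <- suppressWarnings(
    stats::cor(t(m), method = "spearman",
               use = if (anyNA(m)) "pairwise.complete.obs" else "everything"))
  if (anyNA(rho))
    warning("undefined Spearman correlation (zero-variance or no complete ",
            "observations) for some row pairs; distance set to 2")
  d <- 1 - rho
  d[is.na(d)] <- 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Hierarchically cluster a matrix with the 1 - Spearman distance
#'
#' Agglomerative clustering (average linkage by default) of rows and/or
#' columns under the 1 - Spearman rank correlation distance. Rows are
#' pre-sorted by label before clustering so that equal-distance merges
#' resolve identically across runs, making the leaf order deterministic.
#'
#' @param m Numeric matrix.
#' @param axis `"both"`, `"rows"` or `"columns"`.
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @param na_action Passed to [spearman_distance()].
#' @return List with `row_order`, `col_order` (label vectors in leaf
#'   order; untouched axes keep their input order) and the `hclust`
#'   objects `row_hclust`, `col_hclust` (or `NULL`).
#' @export
cluster_matrix <- function(m, axis = c("both", "rows", "columns"),
                           linkage = "average", na_action = "fail") {
  axis <- match.arg(axis)
  if (inherits(m, "event_frequency_matrix")) m <- m$counts
  stopifnot(is.matrix(m))
  one_axis <- function(mm) {
    mm <- mm[order(rownames(mm)), , drop = FALSE]
    d <- spearman_distance(mm, na_action = na_action)
    h <- stats::hclust(stats::as.dist(d), method = linkage)
    list(order = rownames(mm)[h$order], hclust = h)
  }
  rows <- cols <- NULL
  if (axis %in% c("both", "rows") && nrow(m) >= 2L) rows <- one_axis(m)
  if (axis %in% c("both", "columns") && ncol(m) >= 2L) cols <- one_axis(t(m))
  list(row_order = if (is.null(rows)) rownames(m) else rows$order,
       col_order = if (is.null(cols)) colnames(m) else cols$order,
       row_hclust = if (is.null(rows)) NULL else rows$hclust,
       col_hclust = if (is.null(cols)) NULL else cols$hclust)
}

#' Export a dendrogram as Newick text
#'
#' Serializes an `hclust` tree (e.g. from [cluster_matrix()]) to Newick,
#' using `ape`.
#'
#' @param h An `hclust` object.
#' @return Newick string.
#' @export
dendrogram_newick <- function(h) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("dendrogram_newick() needs the 'ape' package")
  ape::write.tree(ape::as.phylo(h))
}

#' Correlate RBP binding breadth with splicing burden
#'
#' Per cell line, correlates the number of significant skipped-exon events
#' of each lncRNA knockdown with the number of RBPs significantly enriched
#' for binding near them (Spearman and Pearson, with p-values). With fewer
#' than three lncRNAs carrying both quantities the report carries an
#' `"insufficient data"` status instead of a correlation; when p >= 0.05
#' the status states that no significant correlation was observed.
#'
#' @param freq_mat `event_frequency_matrix` (typically SE) supplying
#'   per-knockdown significant event counts (column sums).
#' @param profiles Sponge profiles from [sponge_scores()].
#' @return Data frame with one row per (cell line, method):
#'   `cell_line`, `method`, `estimate`, `pvalue`, `n`, `status`.
#' @export
binding_splicing_correlation <- function(freq_mat, profiles) {
  stopifnot(inherits(freq_mat, "event_frequency_matrix"))
  ev_counts <- colSums(freq_mat$counts)
  rows <- list()
  for (cl in unique(profiles$cell_line)) {
    prof <- profiles[profiles$cell_line == cl & profiles$defined, ,
                     drop = FALSE]
    comp <- freq_mat$samples[freq_mat$samples$cell_line == cl, , drop = FALSE]
    idx <- match(prof$lncrna, comp$lncrna)
    ok <- !is.na(idx)
    n_events <- ev_counts[comp$comparison_id[idx[ok]]]
    n_rbps <- prof$n_rbps_significant[ok]
    n <- sum(ok)
    for (method in c("spearman", "pearson")) {
      if (n < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = cl, method = method, estimate = NA_real_,
          pvalue = NA_real_, n = n, status = "insufficient data",
          stringsAsFactors = FALSE)
        next
      }
      ct <- tryCatch(
        suppressWarnings(stats::cor.test(n_events, n_rbps, method = method,
                                         exact = FALSE)),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cl, method = method,
        estimate = if (is.null(ct)) NA_real_ else unname(ct$estimate),
        pvalue = if (is.null(ct)) NA_real_ else ct$p.value, n = n,
        status = if (is.null(ct) || is.na(ct$p.value)) "undefined"
        else if (ct$p.value < 0.05) "significant"
        else "no significant correlation",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
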