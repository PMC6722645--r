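#' Significance filter configuration
#'
#' Thresholds used to call a splicing event significant: the event must have
#' `fdr < fdr_max` AND `pvalue < pvalue_max`, both inequalities strict.
#' Defaults (`fdr < 0.1`, `p < 0.05`) are the setting that defines the
#' high-confidence event sets in knockdown-vs-control comparisons.
#'
#' @param fdr_max FDR threshold, in (0, 1].
#' @param pvalue_max p-value threshold, in (0, 1].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(fdr_max = 0.1, pvalue_max = 0.05) {
  stopifnot(is.numeric(fdr_max), length(fdr_max) == 1L,
            fdr_max > 0, fdr_max <= 1,
            is.numeric(pvalue_max), length(pvalue_max) == 1L,
            pvalue_max > 0, pvalue_max <= 1)
  structure(list(fdr_max = fdr_max, pvalue_max = pvalue_max),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Significance filter: fdr <", x$fdr_max, "and p <", x$pvalue_max, "\n")
  invisible(x)
}

#' Extract significant splicing events
#'
#' Keeps exactly the events with `fdr < fdr_max` and `pvalue < pvalue_max`
#' (strict inequalities; an event sitting on either boundary is excluded).
#' Row order is preserved and the operation is idempotent.
#'
#' @param events Event data frame from [read_rmats_table()].
#' @param config A [filter_config()].
#' @return The surviving rows of `events`.
#' @export
filter_events <- function(events, config = filter_config()) {
  .check_events(events)
  stopifnot(inherits(config, "filter_config"))
  if (nrow(events) == 0L) return(events)
  keep <- !is.na(events$fdr) & !is.na(events$pvalue) &
    events$fdr < config$fdr_max & events$pvalue < config$pvalue_max
  events[keep, , drop = FALSE]
}

#' Collapse repeated events to unique ones
#'
#' Two records are the same event when they agree on event type,
#' chromosome, strand and all six exon-boundary coordinates (the same key
#' that defines `event_id`); the first occurrence is kept. Used to
#' summarize events reported by several knockdown comparisons into a
#' unique-event catalogue.
#'
#' @param events Event data frame (possibly concatenated across
#'   comparisons).
#' @return `events` with duplicates removed, original order preserved.
#' @export
deduplicate_events <- function(events) {
  .check_events(events)
  events[!duplicated(events$event_id), , drop = FALSE]
}

#' Build a gene-by-knockdown event frequency matrix
#'
#' Counts, for one event type, how many unique significant splicing events
#' each gene carries in each knockdown comparison: entry `[g, s]` is the
#' number of unique events of that type in gene `g` for comparison `s`.
#' Genes with no events in any comparison are dropped (all-zero rows carry
#' no information for specificity or clustering). Gene identity is the gene
#' symbol, falling back to the gene id where the symbol is missing.
#'
#' @param events_by_comparison Named list (names = `comparison_id`) of
#'   significance-filtered event data frames.
#' @param sheet Sample sheet (rows matching the list names) supplying the
#'   `(lncrna, cell_line)` labels of each comparison.
#' @param event_type The event type to count (`"SE"`, `"RI"`, ...).
#' @return An object of class `event_frequency_matrix`: a list with
#'   `event_type`, integer matrix `counts` (genes x comparisons) and the
#'   data frame `samples` (`comparison_id`, `lncrna`, `cell_line`).
#' @export
build_frequency_matrix <- function(events_by_comparison, sheet, event_type) {
  event_type <- match.arg(event_type, .event_types)
  stopifnot(is.list(events_by_comparison),
            !is.null(names(events_by_comparison)))
  if (!all(names(events_by_comparison) %in% sheet$comparison_id))
    stop("events_by_comparison has comparisons absent from the sample sheet")
  ids <- sheet$comparison_id[sheet$comparison_id %in%
                               names(events_by_comparison)]
  missing <- setdiff(sheet$comparison_id, ids)
  if (length(missing) > 0L)
    warning("no event table for comparison(s): ",
            paste(missing, collapse = ", "), "; zero columns emitted")
  per_comp <- lapply(ids, function(id) {
    ev <- events_by_comparison[[id]]
    ev <- ev[ev$event_type == event_type, , drop = FALSE]
    ev <- deduplicate_events(ev)
    gene <- ifelse(is.na(ev$gene_symbol) | ev$gene_symbol == "",
                   ev$gene_id, ev$gene_symbol)
    table(gene)
  })
  names(per_comp) <- ids
  genes <- sort(unique(unlist(lapply(per_comp, names))))
  all_ids <- sheet$comparison_id
  counts <- matrix(0L, nrow = length(genes), ncol = length(all_ids),
                   dimnames = list(genes, all_ids))
  for (id in ids) {
    tab <- per_comp[[id]]
    counts[names(tab), id] <- as.integer(tab)
  }
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  structure(list(event_type = event_type, counts = counts,
                 samples = sheet[match(all_ids, sheet$comparison_id),
                                 c("comparison_id", "lncrna", "cell_line")]),
            class = "event_frequency_matrix")
}

#' @export
print.event_frequency_matrix <- function(x, ...) {
  cat("Event frequency matrix (", x$event_type, "): ",
      nrow(x$counts), " genes x ", ncol(x$counts), " knockdowns, ",
      sum(x$counts), " events total\n", sep = "")
  invisible(x)
}

#' Cell-type specificity of alternatively spliced genes
#'
#' For each cell line, takes the set of genes with at least one counted
#' event in any of that cell line's knockdowns, then reports Venn-style
#' overlap counts (every non-empty combination of cell lines, both as
#' exclusive region sizes and as plain intersection sizes) and the fraction
#' of genes alternatively spliced in at least two cell lines. The fraction
#' is reported against two denominators: all genes in the matrix and, when
#' available, the per-event-type gene total.
#'
#' @param mat An `event_frequency_matrix`.
#' @return A list of class `specificity_summary` with elements `gene_sets`
#'   (per cell line), `exclusive_counts`, `intersection_counts`,
#'   `shared_genes`, `shared_fraction`, `n_genes` and `note`.
#' @export
specificity_summary <- function(mat) {
  stopifnot(inherits(mat, "event_frequency_matrix"))
  cls <- unique(mat$samples$cell_line)
  sets <- lapply(cls, function(cl) {
    cols <- mat$samples$comparison_id[mat$samples$cell_line == cl]
    cols <- intersect(cols, colnames(mat$counts))
    sub <- mat$counts[, cols, drop = FALSE]
    rownames(sub)[rowSums(sub) > 0L]
  })
  names(sets) <- cls
  all_genes <- sort(unique(unlist(sets)))
  note <- NULL
  if (length(cls) < 2L)
    note <- "single cell line: overlap summary is degenerate"
  # membership matrix genes x cell lines
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                              dimnames = list(all_genes, cls))
  n_cl <- length(cls)
  combos <- list()
  if (n_cl >= 1L && length(all_genes) > 0L) {
    for (k in seq_len(n_cl)) {
      for (idx in utils::combn(n_cl, k, simplify = FALSE)) {
        key <- paste(cls[idx], collapse = "&")
        inside <- rowSums(memb[, idx, drop = FALSE]) == k
        outside <- rowSums(memb[, -idx, drop = FALSE]) == 0L
        combos[[key]] <- c(exclusive = sum(inside & outside),
                           intersection = sum(inside))
      }
    }
  }
  shared <- if (length(all_genes) > 0L)
    all_genes[rowSums(memb) >= 2L] else character()
  structure(list(
    gene_sets = sets,
    exclusive_counts = vapply(combos, `[[`, numeric(1), "exclusive"),
    intersection_counts = vapply(combos, `[[`, numeric(1), "intersection"),
    shared_genes = shared,
    shared_fraction = if (length(all_genes) > 0L)
      length(shared) / length(all_genes) else NA_real_,
    n_genes = length(all_genes),
    note = note
  ), class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat("Cell-type specificity over", x$n_genes, "alternatively spliced genes\n")
  for (cl in names(x$gene_sets))
    cat("  ", cl, ": ", length(x$gene_sets[[cl]]), " genes\n", sep = "")
  cat("  shared by >=2 cell lines: ", length(x$shared_genes), " (",
      sprintf("%.1f%%", 100 * x$shared_fraction), ")\n", sep = "")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
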