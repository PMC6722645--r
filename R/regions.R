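.region_types <- c("upstream_exon_start", "upstream_exon_end",
                   "target_start", "target_end",
                   "downstream_exon_start", "downstream_exon_end")

#' Proximal windows around the six exon-boundary coordinates of an event
#'
#' Every splice event contributes six anchor coordinates: start and end of
#' the upstream flanking exon, of the event-specific exon/intron (target),
#' and of the downstream flanking exon. Each anchor `c` is expanded to the
#' symmetric window `[max(0, c - window), c + window)`, the genomic
#' neighbourhood in which RBP binding is interrogated. Windows from nearby
#' anchors may overlap; they are deliberately kept as six distinct records
#' per event because binding is counted per region, and merging would
#' change the contingency denominators. Windows are strand-agnostic
#' (symmetric on both sides) and are clipped at coordinate 0 only.
#'
#' @param events Event data frame (SE and RI by default; set
#'   `allow_extended_types = TRUE` to accept A5SS/A3SS/MXE under the
#'   documented long/short/flanking and first-exon column mappings).
#' @param window Half-width in bp on either side of each anchor
#'   (default 500).
#' @param lncrna,cell_line Labels attached to every region (the knockdown
#'   the events came from).
#' @param allow_extended_types Permit event types other than SE/RI.
#' @return Data frame with one row per (event, anchor): `event_id`,
#'   `region_type`, `chrom`, `start`, `end`, `strand`, `lncrna`,
#'   `cell_line`, `gene_symbol`. Exactly `6 * nrow(events)` rows.
#' @export
extract_proximal_regions <- function(events, window = 500,
                                     lncrna = NA_character_,
                                     cell_line = NA_character_,
                                     allow_extended_types = FALSE) {
  .check_events(events)
  if (!is.numeric(window) || length(window) != 1L || window <= 0)
    stop("window must be a single positive number of base pairs")
  if (!allow_extended_types &&
      any(!events$event_type %in% c("SE", "RI")))
    stop("proximal regions are defined for SE and RI events; ",
         "set allow_extended_types = TRUE to map other types")
  n <- nrow(events)
  anchor_cols <- c("upstream_start", "upstream_end",
                   "target_start", "target_end",
                   "downstream_start", "downstream_end")
  anchors <- unlist(events[, anchor_cols], use.names = FALSE)
  out <- data.frame(
    event_id = rep(events$event_id, times = 6L),
    region_type = rep(.region_types, each = n),
    chrom = rep(events$chrom, times = 6L),
    start = pmax(0, anchors - window),
    end = anchors + window,
    strand = rep(events$strand, times = 6L),
    lncrna = rep(lncrna, 6L * n),
    cell_line = rep(cell_line, 6L * n),
    gene_symbol = rep(ifelse(is.na(events$gene_symbol) |
                               events$gene_symbol == "",
                             events$gene_id, events$gene_symbol), times = 6L),
    stringsAsFactors = FALSE
  )
  # deterministic order: by event, then anchor type in schema order
  out <- out[order(rep(seq_len(n), times = 6L),
                   rep(seq_along(.region_types), each = n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proximal regions for one knockdown comparison
#'
#' Convenience wrapper: extracts the six windows for every
#' significance-filtered event of a comparison and labels them with the
#' knockdown's lncRNA and cell line.
#'
#' @inheritParams extract_proximal_regions
#' @param lncrna The lncRNA knocked down in this comparison.
#' @param cell_line The cell line of this comparison.
#' @return Region data frame with `6 * nrow(events)` rows.
#' @export
regions_for_comparison <- function(events, lncrna, cell_line, window = 500,
                                   allow_extended_types = FALSE) {
  extract_proximal_regions(events, window = window, lncrna = lncrna,
                           cell_line = cell_line,
                           allow_extended_types = allow_extended_types)
}

.region_uid <- function(regions) {
  paste(regions$event_id, regions$region_type, regions$lncrna, sep = "|")
}
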