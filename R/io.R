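#' @keywords internal
"_PACKAGE"

# Column dialect: rMATS v3.2.5 MATS output tables. Each event type maps its
# own coordinate columns onto the internal six-coordinate schema
# (target, upstream, downstream; all 0-based half-open).
.rmats_coord_map <- list(
  SE = c(target_start = "exonStart_0base", target_end = "exonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  RI = c(target_start = "riExonStart_0base", target_end = "riExonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  MXE = c(target_start = "1stExonStart_0base", target_end = "1stExonEnd",
          upstream_start = "upstreamES", upstream_end = "upstreamEE",
          downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  A5SS = c(target_start = "longExonStart_0base", target_end = "longExonEnd",
           upstream_start = "shortES", upstream_end = "shortEE",
           downstream_start = "flankingES", downstream_end = "flankingEE"),
  A3SS = c(target_start = "longExonStart_0base", target_end = "longExonEnd",
           upstream_start = "shortES", upstream_end = "shortEE",
           downstream_start = "flankingES", downstream_end = "flankingEE")
)

.event_types <- names(.rmats_coord_map)

.coord_fields <- c("target_start", "target_end", "upstream_start",
                   "upstream_end", "downstream_start", "downstream_end")

.event_columns <- c("event_id", "event_type", "gene_id", "gene_symbol",
                    "chrom", "strand", .coord_fields,
                    "pvalue", "fdr", "inc_level_diff")

#' Deterministic event identifier
#'
#' The identity of a splice event is its type, chromosome, strand and all
#' six exon-boundary coordinates; the id is the colon-joined key of those
#' fields, so identical events found in different knockdown comparisons
#' share an id.
#' @noRd
.event_key <- function(event_type, chrom, strand,
                       target_start, target_end,
                       upstream_start, upstream_end,
                       downstream_start, downstream_end) {
  paste(event_type, chrom, strand,
        format(target_start, scientific = FALSE, trim = TRUE),
        format(target_end, scientific = FALSE, trim = TRUE),
        format(upstream_start, scientific = FALSE, trim = TRUE),
        format(upstream_end, scientific = FALSE, trim = TRUE),
        format(downstream_start, scientific = FALSE, trim = TRUE),
        format(downstream_end, scientific = FALSE, trim = TRUE),
        sep = ":")
}

.empty_events <- function() {
  df <- data.frame(event_id = character(), event_type = character(),
                   gene_id = character(), gene_symbol = character(),
                   chrom = character(), strand = character(),
                   target_start = integer(), target_end = integer(),
                   upstream_start = integer(), upstream_end = integer(),
                   downstream_start = integer(), downstream_end = integer(),
                   pvalue = numeric(), fdr = numeric(),
                   inc_level_diff = numeric(),
                   stringsAsFactors = FALSE)
  df
}

.check_events <- function(events) {
  stopifnot(is.data.frame(events))
  missing <- setdiff(.event_columns, names(events))
  if (length(missing) > 0L)
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(events) == 0L) return(invisible(events))
  bad <- events$target_start >= events$target_end |
    events$upstream_start >= events$upstream_end |
    events$downstream_start >= events$downstream_end
  if (any(bad))
    stop("invalid event coordinates (start >= end) in ", sum(bad), " row(s)")
  if (any(events$pvalue < 0 | events$pvalue > 1, na.rm = TRUE) ||
      any(events$fdr < 0 | events$fdr > 1, na.rm = TRUE))
    stop("pvalue/fdr outside [0, 1]")
  invisible(events)
}

#' Read an rMATS event table
#'
#' Parses one tab-separated MATS output table (rMATS v3.2.5 column dialect)
#' into the internal splice-event data frame. Coordinates in `*_0base`
#' columns are taken verbatim as 0-based starts and the corresponding end
#' columns are treated as exclusive, so every interval in the package is
#' 0-based half-open (BED convention) and downstream interval arithmetic
#' needs no conversion.
#'
#' @param path Path to the MATS `.txt` table.
#' @param event_type One of `"SE"`, `"RI"`, `"MXE"`, `"A5SS"`, `"A3SS"`.
#' @param col_map Optional named character vector overriding the coordinate
#'   column mapping for non-default rMATS dialects; names must be the six
#'   internal coordinate fields.
#' @return A data frame with one row per event and columns `event_id`,
#'   `event_type`, `gene_id`, `gene_symbol`, `chrom`, `strand`, the six
#'   coordinates (`target_*`, `upstream_*`, `downstream_*`), `pvalue`,
#'   `fdr`, `inc_level_diff`. The attribute `"source"` records the file the
#'   table was loaded from (rMATS emits both JunctionCountOnly and
#'   ReadsOnTargetAndJunctionCounts flavours; either is accepted and the
#'   filename is kept so the provenance is visible).
#' @seealso [write_rmats_table()], [filter_events()]
#' @export
read_rmats_table <- function(path, event_type, col_map = NULL) {
  event_type <- match.arg(event_type, .event_types)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  cmap <- .rmats_coord_map[[event_type]]
  if (!is.null(col_map)) {
    stopifnot(all(names(col_map) %in% .coord_fields))
    cmap[names(col_map)] <- col_map
  }
  needed <- c(GeneID = "GeneID", geneSymbol = "geneSymbol", chr = "chr",
              strand = "strand", cmap,
              PValue = "PValue", FDR = "FDR",
              IncLevelDifference = "IncLevelDifference")
  absent <- setdiff(unname(needed), names(raw))
  if (length(absent) > 0L)
    stop("rMATS ", event_type, " table ", path,
         " is missing mandatory column(s): ", paste(absent, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- .empty_events()
    attr(out, "source") <- basename(path)
    return(out)
  }
  num <- function(column, what) {
    v <- suppressWarnings(as.numeric(raw[[column]]))
    if (anyNA(v))
      stop("non-numeric ", what, " ('", column, "') at data line ",
           which(is.na(v))[1L], " of ", path)
    v
  }
  out <- data.frame(
    event_type = event_type,
    gene_id = raw$GeneID,
    gene_symbol = raw$geneSymbol,
    chrom = raw$chr,
    strand = raw$strand,
    target_start = num(cmap["target_start"], "coordinate"),
    target_end = num(cmap["target_end"], "coordinate"),
    upstream_start = num(cmap["upstream_start"], "coordinate"),
    upstream_end = num(cmap["upstream_end"], "coordinate"),
    downstream_start = num(cmap["downstream_start"], "coordinate"),
    downstream_end = num(cmap["downstream_end"], "coordinate"),
    pvalue = num("PValue", "pvalue"),
    fdr = num("FDR", "fdr"),
    inc_level_diff = suppressWarnings(as.numeric(raw$IncLevelDifference)),
    stringsAsFactors = FALSE
  )
  out$event_id <- .event_key(out$event_type, out$chrom, out$strand,
                             out$target_start, out$target_end,
                             out$upstream_start, out$upstream_end,
                             out$downstream_start, out$downstream_end)
  out <- out[, .event_columns]
  .check_events(out)
  attr(out, "source") <- basename(path)
  out
}

#' Write an event table in the rMATS column dialect
#'
#' Inverse of [read_rmats_table()]: emits a tab-separated MATS-style table
#' for one event type. All fields retained by the reader round-trip
#' losslessly. For MXE the second-exon columns (which the internal schema
#' does not model) are emitted as copies of the target exon so the file
#' stays schema-valid.
#'
#' @param events Event data frame (single `event_type`).
#' @param path Output path.
#' @param event_type Event type to use for the column dialect when
#'   `events` is empty (otherwise inferred from the table).
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(events, path, event_type = NULL) {
  .check_events(events)
  type <- unique(events$event_type)
  if (length(type) > 1L)
    stop("write_rmats_table() writes one event type per file; got: ",
         paste(type, collapse = ", "))
  if (length(type) == 0L)
    type <- if (is.null(event_type)) "SE" else
      match.arg(event_type, .event_types)
  cmap <- .rmats_coord_map[[type]]
  out <- data.frame(ID = seq_len(nrow(events)), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$GeneID <- events$gene_id
  out$geneSymbol <- events$gene_symbol
  out$chr <- events$chrom
  out$strand <- events$strand
  for (field in .coord_fields) out[[cmap[[field]]]] <- events[[field]]
  if (type == "MXE") {
    out[["2ndExonStart_0base"]] <- events$target_start
    out[["2ndExonEnd"]] <- events$target_end
  }
  out$PValue <- events$pvalue
  out$FDR <- events$fdr
  out$IncLevelDifference <- events$inc_level_diff
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             rbp = character(), cell_line = character(),
             score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

.check_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  needed <- c("chrom", "start", "end", "rbp", "cell_line", "strand")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0L)
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(peaks) > 0L && any(peaks$start >= peaks$end))
    stop("invalid peak coordinates (start >= end)")
  invisible(peaks)
}

#' Read RBP binding peaks from BED6 / narrowPeak
#'
#' Loads a BED6 or narrowPeak file of eCLIP-style binding intervals as
#' 0-based half-open records. Columns beyond the sixth (the narrowPeak
#' signal/p-value/summit columns) are ignored. Every record is labeled with
#' the RBP and cell line it belongs to; when `rbp` is `NULL` the BED name
#' column is used.
#'
#' @param path BED file path.
#' @param rbp RBP label for every record, or `NULL` to take the name column.
#' @param cell_line Cell-line label for every record (e.g. `"HeLa"`,
#'   `"K562"`); `NA` if unknown.
#' @return Data frame with columns `chrom`, `start`, `end`, `rbp`,
#'   `cell_line`, `score`, `strand`.
#' @export
read_peaks_bed <- function(path, rbp = NULL, cell_line = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) return(.empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L)
    stop("BED file ", path, " has a record with fewer than 3 columns")
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  start <- as.integer(get(2L))
  end <- as.integer(get(3L))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates in BED file ", path)
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("start >= end at line ", bad[1L], " of ", path)
  name <- get(4L)
  score <- suppressWarnings(as.numeric(get(5L, "0")))
  strand <- get(6L, ".")
  strand[is.na(strand) | !(strand %in% c("+", "-", "."))] <- "."
  out <- data.frame(chrom = get(1L), start = start, end = end,
                    rbp = if (is.null(rbp)) name else rbp,
                    cell_line = cell_line,
                    score = ifelse(is.na(score), 0, score),
                    strand = strand, stringsAsFactors = FALSE)
  if (any(is.na(out$rbp) | out$rbp == ""))
    stop("peaks without an RBP label (no rbp argument and empty name column)")
  out
}

#' Write intervals as BED6
#'
#' Accepts either the peak data frame of [read_peaks_bed()] (name column =
#' `rbp`) or the proximal-region data frame of [extract_proximal_regions()]
#' (name column = `event_id|region_type|lncrna`).
#'
#' @param x Peak or region data frame with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  name <- if ("rbp" %in% names(x)) {
    x$rbp
  } else if (all(c("event_id", "region_type", "lncrna") %in% names(x))) {
    paste(x$event_id, x$region_type, x$lncrna, sep = "|")
  } else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  bed <- data.frame(x$chrom, x$start, x$end, name, score, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a knockdown sample sheet
#'
#' The sample sheet maps each knockdown-vs-control comparison to the lncRNA
#' knocked down, the cell line, and the per-event-type rMATS tables.
#' Mandatory columns: `comparison_id`, `lncrna`, `cell_line`; event-table
#' paths live in `<type>_path` columns (`se_path`, `ri_path`, ...), resolved
#' relative to the sheet's directory.
#'
#' @param path Sample sheet TSV.
#' @param check_paths Verify that every referenced table exists (default).
#' @return Data frame of comparisons; path columns are absolute.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sheet <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
  needed <- c("comparison_id", "lncrna", "cell_line")
  missing <- setdiff(needed, names(sheet))
  if (length(missing) > 0L)
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(sheet$lncrna, sheet$cell_line, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (lncrna, cell_line) pair(s) in sample sheet: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (anyDuplicated(sheet$comparison_id))
    stop("duplicate comparison_id in sample sheet")
  base <- dirname(normalizePath(path))
  path_cols <- grep("_path$", names(sheet), value = TRUE)
  for (pc in path_cols) {
    rel <- !is.na(sheet[[pc]]) & nzchar(sheet[[pc]])
    sheet[[pc]][rel] <- file.path(base, sheet[[pc]][rel])
    if (check_paths && any(rel) && !all(file.exists(sheet[[pc]][rel])))
      stop("sample sheet references missing file(s) in column ", pc, ": ",
           paste(sheet[[pc]][rel][!file.exists(sheet[[pc]][rel])],
                 collapse = ", "))
  }
  sheet
}

#' Write an event frequency matrix as TSV
#'
#' Genes as rows, knockdown comparisons as columns, with a header row and a
#' leading `gene` column. Lossless against [read_matrix_tsv()].
#'
#' @param mat An `event_frequency_matrix` (or plain numeric matrix with
#'   dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  m <- if (inherits(mat, "event_frequency_matrix")) mat$counts else mat
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency-matrix TSV written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, `term_id <tab> description <tab>
#' gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @return Data frame with columns `term_id`, `term_name` and a list column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0L && any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields in ", path)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term_id in GMT file ", path)
  data.frame(
    term_id = ids,
    term_name = vapply(fields, `[[`, character(1), 2L),
    genes = I(lapply(fields, function(f) unique(f[-(1:2)]))),
    stringsAsFactors = FALSE
  )
}

#' Write gene sets to a GMT file
#' @param sets Data frame as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$term_name[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
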