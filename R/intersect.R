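# Interval-overlap engine with bedtools-intersect semantics on 0-based
# half-open intervals. A single sorted endpoint sweep per chromosome keeps
# the work at O((n + m) log(n + m) + k) for k reported pairs; an all-pairs
# scan is never performed.

.check_chrom_naming <- function(chroms) {
  chroms <- unique(chroms)
  has_prefix <- grepl("^chr", chroms)
  if (any(has_prefix) && !all(has_prefix))
    stop("mixed chromosome naming conventions ('chr1' vs '1'); ",
         "harmonize inputs or set strict = FALSE")
  invisible(TRUE)
}

# Sweep one chromosome. rs/re, ps/pe: starts and ends of regions and peaks.
# Returns list(ri, pi) of overlapping index pairs. Endpoints are processed
# in position order with interval ends strictly before starts at the same
# coordinate, so half-open abutment ([a,b) then [b,c)) never pairs.
.sweep_pairs <- function(rs, re, ps, pe) {
  n <- length(rs); m <- length(ps)
  pos <- c(rs, re, ps, pe)
  # kind: 1 = region start, 2 = peak start, 0 = any end
  kind <- c(rep(1L, n), rep(0L, n), rep(2L, m), rep(0L, m))
  id <- c(seq_len(n), seq_len(n), seq_len(m), seq_len(m))
  is_region <- c(rep(TRUE, 2L * n), rep(FALSE, 2L * m))
  ord <- order(pos, kind != 0L)  # ends (kind 0) first at equal positions
  active_r <- integer(0); active_p <- integer(0)
  out_r <- vector("list", n + m); out_p <- vector("list", n + m)
  nout <- 0L
  for (e in ord) {
    if (kind[e] == 1L) {                      # region opens
      if (length(active_p) > 0L) {
        nout <- nout + 1L
        out_r[[nout]] <- rep.int(id[e], length(active_p))
        out_p[[nout]] <- active_p
      }
      active_r <- c(active_r, id[e])
    } else if (kind[e] == 2L) {               # peak opens
      if (length(active_r) > 0L) {
        nout <- nout + 1L
        out_r[[nout]] <- active_r
        out_p[[nout]] <- rep.int(id[e], length(active_r))
      }
      active_p <- c(active_p, id[e])
    } else if (is_region[e]) {                # region closes
      active_r <- active_r[active_r != id[e]]
    } else {                                  # peak closes
      active_p <- active_p[active_p != id[e]]
    }
  }
  list(ri = unlist(out_r[seq_len(nout)], use.names = FALSE),
       pi = unlist(out_p[seq_len(nout)], use.names = FALSE))
}

#' Intersect proximal regions with RBP binding peaks
#'
#' Reports every (region, peak) pair on the same chromosome whose intervals
#' overlap by at least `min_overlap` bp, with bedtools-intersect semantics:
#' coordinates are 0-based half-open, so intervals that merely abut
#' (`[a,b)` and `[b,c)`) do not overlap. Each qualifying pair appears
#' exactly once, in deterministic order (chromosome, region start, peak
#' start). Matching is unstranded by default, mirroring how eCLIP peaks
#' are intersected with splice-site windows; `stranded = TRUE` restricts
#' pairs to identical strands.
#'
#' @param regions Region data frame ([extract_proximal_regions()]).
#' @param peaks Peak data frame ([read_peaks_bed()]).
#' @param min_overlap Minimum overlap in bp (default 1, the bedtools
#'   default).
#' @param stranded Require identical strand (default `FALSE`).
#' @param strict Reject mixed `chr1`/`1` chromosome naming between the two
#'   inputs instead of silently treating them as different chromosomes.
#' @return Data frame with one row per overlapping pair: `region_idx`,
#'   `peak_idx` (row numbers into the inputs), `chrom`, `region_start`,
#'   `region_end`, `peak_start`, `peak_end`, `rbp`, `overlap_bp`.
#' @export
intersect_intervals <- function(regions, peaks, min_overlap = 1,
                                stranded = FALSE, strict = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end") %in% names(peaks)),
            min_overlap >= 1)
  if (nrow(regions) > 0L && any(regions$start >= regions$end))
    stop("regions contain start >= end")
  if (nrow(peaks) > 0L && any(peaks$start >= peaks$end))
    stop("peaks contain start >= end")
  if (strict) .check_chrom_naming(c(regions$chrom, peaks$chrom))
  empty <- data.frame(region_idx = integer(), peak_idx = integer(),
                      chrom = character(), region_start = integer(),
                      region_end = integer(), peak_start = integer(),
                      peak_end = integer(),
                      rbp = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(peaks) == 0L) return(empty)
  groups_r <- if (stranded) paste(regions$chrom, regions$strand) else
    regions$chrom
  groups_p <- if (stranded) paste(peaks$chrom, peaks$strand) else peaks$chrom
  res_r <- list(); res_p <- list(); gi <- 0L
  for (g in intersect(unique(groups_r), unique(groups_p))) {
    ir <- which(groups_r == g); ip <- which(groups_p == g)
    pr <- .sweep_pairs(regions$start[ir], regions$end[ir],
                       peaks$start[ip], peaks$end[ip])
    if (length(pr$ri) > 0L) {
      gi <- gi + 1L
      res_r[[gi]] <- ir[pr$ri]
      res_p[[gi]] <- ip[pr$pi]
    }
  }
  if (gi == 0L) return(empty)
  ri <- unlist(res_r, use.names = FALSE)
  pi <- unlist(res_p, use.names = FALSE)
  ov <- pmin(regions$end[ri], peaks$end[pi]) -
    pmax(regions$start[ri], peaks$start[pi])
  keep <- ov >= min_overlap
  ri <- ri[keep]; pi <- pi[keep]; ov <- ov[keep]
  out <- data.frame(region_idx = ri, peak_idx = pi,
                    chrom = regions$chrom[ri],
                    region_start = regions$start[ri],
                    region_end = regions$end[ri],
                    peak_start = peaks$start[pi],
                    peak_end = peaks$end[pi],
                    rbp = if ("rbp" %in% names(peaks)) peaks$rbp[pi] else
                      NA_character_,
                    overlap_bp = ov, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$region_start, out$peak_start,
                   out$region_idx, out$peak_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-(region, RBP) binding flags
#'
#' For every cell line present in `regions`, builds a logical matrix whose
#' entry `[region, rbp]` says whether at least one peak of that RBP (from
#' the same cell line) overlaps the region. Cell-line pairing is enforced
#' structurally: a region is only ever tested against peaks recorded in
#' its own cell line, and an RBP with no peaks in a cell line contributes
#' no column there (absent, which is distinguishable from all-`FALSE`).
#'
#' @inheritParams intersect_intervals
#' @param peaks Peak data frame with `rbp` and `cell_line` columns.
#' @return Named list (one element per cell line) of `binding_flags`
#'   objects: `cell_line`, the `regions` slice, and the logical matrix
#'   `flags` with rownames `event_id|region_type|lncrna`.
#' @export
bound_flags <- function(regions, peaks, min_overlap = 1, stranded = FALSE,
                        strict = TRUE) {
  stopifnot(all(c("rbp", "cell_line") %in% names(peaks)),
            "cell_line" %in% names(regions))
  out <- list()
  for (cl in unique(regions$cell_line)) {
    reg <- regions[regions$cell_line == cl, , drop = FALSE]
    pk <- peaks[peaks$cell_line == cl, , drop = FALSE]
    rbps <- sort(unique(pk$rbp))
    flags <- matrix(FALSE, nrow = nrow(reg), ncol = length(rbps),
                    dimnames = list(.region_uid(reg), rbps))
    for (r in rbps) {
      hits <- intersect_intervals(reg, pk[pk$rbp == r, , drop = FALSE],
                                  min_overlap = min_overlap,
                                  stranded = stranded, strict = strict)
      flags[unique(hits$region_idx), r] <- TRUE
    }
    out[[cl]] <- structure(list(cell_line = cl, regions = reg, flags = flags),
                           class = "binding_flags")
  }
  out
}

#' @export
print.binding_flags <- function(x, ...) {
  cat("Binding flags for ", x$cell_line, ": ", nrow(x$flags),
      " regions x ", ncol(x$flags), " RBPs (",
      sum(x$flags), " bound)\n", sep = "")
  invisible(x)
}
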