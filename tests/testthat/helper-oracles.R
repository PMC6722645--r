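# Independent oracles and fixture builders used across the suite. These
# deliberately use the dumbest correct algorithm (all-pairs scans, direct
# combinatorial sums) so they share no code path with the implementation
# they check.

# All-pairs interval overlap oracle (0-based half-open).
brute_force_intersect <- function(regions, peaks, min_overlap = 1,
                                  stranded = FALSE) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(peaks))) {
      if (regions$chrom[i] != peaks$chrom[j]) next
      if (stranded && regions$strand[i] != peaks$strand[j]) next
      ov <- min(regions$end[i], peaks$end[j]) -
        max(regions$start[i], peaks$start[j])
      if (ov >= min_overlap)
        out[[length(out) + 1L]] <- c(i, j, ov)
    }
  }
  if (length(out) == 0L)
    return(data.frame(region_idx = integer(), peak_idx = integer(),
                      overlap_bp = integer()))
  m <- do.call(rbind, out)
  data.frame(region_idx = m[, 1], peak_idx = m[, 2], overlap_bp = m[, 3])
}

# Same all-pairs semantics, vectorized per chromosome so large fixtures
# stay fast; still examines every (region, peak) pair on a chromosome.
brute_force_intersect_vec <- function(regions, peaks, min_overlap = 1) {
  out <- list()
  for (ch in intersect(unique(regions$chrom), unique(peaks$chrom))) {
    ri <- which(regions$chrom == ch)
    pj <- which(peaks$chrom == ch)
    i <- rep(ri, times = length(pj))
    j <- rep(pj, each = length(ri))
    ov <- pmin(regions$end[i], peaks$end[j]) -
      pmax(regions$start[i], peaks$start[j])
    keep <- ov >= min_overlap
    out[[ch]] <- data.frame(region_idx = i[keep], peak_idx = j[keep],
                            overlap_bp = ov[keep])
  }
  if (length(out) == 0L)
    return(data.frame(region_idx = integer(), peak_idx = integer(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# Canonical sortable key for a pair set, for exact set comparison.
pair_key <- function(df) sort(paste(df$region_idx, df$peak_idx, df$overlap_bp))

# Direct combinatorial hypergeometric tail oracle for a 2x2 table
# (x, y, a, b): sums choose() products over the support, no logs, no
# shared code with fisher_exact().
hyper_oracle <- function(x, y, a, b, alternative = "greater") {
  m1 <- x + y; m2 <- a + b; K <- x + a; N <- m1 + m2
  j <- max(0, K - m2):min(K, m1)
  pmf <- choose(m1, j) * choose(m2, K - j) / choose(N, K)
  obs <- pmf[j == x]
  p <- switch(alternative,
              greater = sum(pmf[j >= x]),
              less = sum(pmf[j <= x]),
              two.sided = sum(pmf[pmf <= obs * (1 + 1e-7)]))
  min(1, p)
}

# Random synthetic event table (not via the study generator) for io and
# filtering tests.
random_events <- function(n, event_type = "SE", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sort(sample.int(1e6, n)) * 10L
  ev <- data.frame(
    event_type = event_type,
    gene_id = sprintf("ENSG%08d", sample.int(500, n, replace = TRUE)),
    gene_symbol = sprintf("G%03d", sample.int(500, n, replace = TRUE)),
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    target_start = start + 3000L, target_end = start + 3800L,
    upstream_start = start, upstream_end = start + 900L,
    downstream_start = start + 6000L, downstream_end = start + 7100L,
    pvalue = round(runif(n), 8), fdr = round(runif(n), 8),
    inc_level_diff = round(runif(n, -1, 1), 4),
    stringsAsFactors = FALSE)
  ev$event_id <- paste(ev$event_type, ev$chrom, ev$strand, ev$target_start,
                       ev$target_end, ev$upstream_start, ev$upstream_end,
                       ev$downstream_start, ev$downstream_end, sep = ":")
  ev[, c("event_id", "event_type", "gene_id", "gene_symbol", "chrom",
         "strand", "target_start", "target_end", "upstream_start",
         "upstream_end", "downstream_start", "downstream_end",
         "pvalue", "fdr", "inc_level_diff")]
}

# Random labeled intervals for intersection tests.
random_intervals <- function(n, chroms = paste0("chr", 1:3),
                             max_pos = 1e5, max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n,
                                                     replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Small binding_flags object built by hand.
make_flags <- function(flags, lncrna, cell_line = "HeLa",
                       gene = NULL) {
  n <- nrow(flags)
  regions <- data.frame(
    event_id = sprintf("ev%03d", seq_len(n)),
    region_type = "target_start",
    chrom = "chr1", start = seq_len(n) * 1000,
    end = seq_len(n) * 1000 + 100, strand = "+",
    lncrna = lncrna, cell_line = cell_line,
    gene_symbol = if (is.null(gene)) sprintf("g%03d", seq_len(n)) else gene,
    stringsAsFactors = FALSE)
  rownames(flags) <- paste(regions$event_id, regions$region_type,
                           regions$lncrna, sep = "|")
  structure(list(cell_line = cell_line, regions = regions, flags = flags),
            class = "binding_flags")
}
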