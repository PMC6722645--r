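region_df <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("overlap arithmetic and half-open abutment follow bedtools", {
  r <- region_df("chr1", 500, 1500)
  p <- data.frame(chrom = "chr1", start = 1400, end = 1600, rbp = "X",
                  cell_line = "HeLa", strand = "+")
  hit <- intersect_intervals(r, p)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$overlap_bp, 100)
  # [500,1500) and [1500,1600) abut but do not overlap
  p$start <- 1500
  expect_equal(nrow(intersect_intervals(r, p)), 0L)
})

test_that("sweep matches the all-pairs oracle on random fixtures", {
  set.seed(202)
  regions <- random_intervals(300)
  peaks <- random_intervals(300)
  peaks$rbp <- "X"
  got <- intersect_intervals(regions, peaks, strict = FALSE)
  want <- brute_force_intersect(regions, peaks)
  expect_identical(pair_key(got), pair_key(want))
  # stranded mode
  got_s <- intersect_intervals(regions, peaks, stranded = TRUE,
                               strict = FALSE)
  want_s <- brute_force_intersect(regions, peaks, stranded = TRUE)
  expect_identical(pair_key(got_s), pair_key(want_s))
})

test_that("intersection is symmetric and monotone in min_overlap", {
  set.seed(77)
  a <- random_intervals(150)
  b <- random_intervals(150)
  ab <- intersect_intervals(a, b, strict = FALSE)
  ba <- intersect_intervals(b, a, strict = FALSE)
  expect_identical(sort(paste(ab$region_idx, ab$peak_idx)),
                   sort(paste(ba$peak_idx, ba$region_idx)))
  for (mo in c(1, 10, 50, 200)) {
    sub <- intersect_intervals(a, b, min_overlap = mo, strict = FALSE)
    expect_true(all(sub$overlap_bp >= mo))
    expect_true(all(paste(sub$region_idx, sub$peak_idx) %in%
                      paste(ab$region_idx, ab$peak_idx)))
  }
})

test_that("deterministic output order and duplicate-free pairs", {
  set.seed(31)
  regions <- random_intervals(100)
  peaks <- random_intervals(100)
  h1 <- intersect_intervals(regions, peaks, strict = FALSE)
  h2 <- intersect_intervals(regions, peaks, strict = FALSE)
  expect_identical(h1, h2)
  expect_false(anyDuplicated(paste(h1$region_idx, h1$peak_idx)) > 0)
  ord <- order(h1$chrom, h1$region_start, h1$peak_start)
  expect_equal(ord, seq_len(nrow(h1)))
})

test_that("mixed chromosome naming is rejected under strict mode", {
  r <- region_df("chr1", 10, 50)
  p <- data.frame(chrom = "1", start = 20, end = 40, rbp = "X",
                  cell_line = "HeLa", strand = "+")
  expect_error(intersect_intervals(r, p), "mixed chromosome naming")
  expect_equal(nrow(intersect_intervals(r, p, strict = FALSE)), 0L)
})

test_that("bound_flags respects cell-line pairing and absent RBPs", {
  regions <- data.frame(
    event_id = c("e1", "e2"), region_type = "target_start",
    chrom = c("chr1", "chr2"), start = c(100, 100), end = c(200, 200),
    strand = "+", lncrna = c("L1", "L1"),
    cell_line = c("HeLa", "HeLa"), gene_symbol = c("g1", "g2"),
    stringsAsFactors = FALSE)
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(150, 150, 150), end = c(180, 180, 180),
    rbp = c("X", "Y", "X"), cell_line = c("HeLa", "K562", "K562"),
    strand = "+", stringsAsFactors = FALSE)
  bf <- bound_flags(regions, peaks)
  expect_named(bf, "HeLa")
  # only HeLa peaks are consulted: X has a HeLa peak, Y does not
  expect_equal(colnames(bf$HeLa$flags), "X")
  expect_equal(unname(bf$HeLa$flags[, "X"]), c(TRUE, FALSE))
})

test_that("flag table equals the planted truth on simulated data", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 12, n_lncrnas_per_cell_line = 3,
                    n_events_per_comparison = 20,
                    n_as_genes_per_cell_line = 6, n_genes = 30, n_rbps = 4)
  tr <- simulate_splicing_study(cfg, dir)
  peaks <- do.call(rbind, lapply(names(tr$flags), function(cl) {
    manifest <- read.delim(file.path(dir, "peaks", "manifest.tsv"),
                           stringsAsFactors = FALSE)
    manifest <- manifest[manifest$cell_line == cl, ]
    do.call(rbind, lapply(seq_len(nrow(manifest)), function(i)
      read_peaks_bed(file.path(dir, manifest$path[i]),
                     rbp = manifest$rbp[i], cell_line = cl)))
  }))
  regs <- do.call(rbind, tr$regions)
  bf <- bound_flags(regs, peaks)
  for (cl in names(tr$flags)) {
    want <- tr$flags[[cl]]
    got <- bf[[cl]]$flags[rownames(want), colnames(want)]
    expect_identical(unname(got), unname(want), info = cl)
  }
})
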