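test_that("significance filter applies strict fdr and p thresholds", {
  ev <- random_events(3, seed = 1)
  ev$pvalue <- c(0.01, 0.04, 0.2)
  ev$fdr <- c(0.05, 0.2, 0.01)
  keep <- filter_events(ev, filter_config())
  expect_equal(keep$event_id, ev$event_id[1])
  # boundary values are excluded (strict inequalities)
  ev$pvalue <- c(0.05, 0.049, 0.01)
  ev$fdr <- c(0.01, 0.1, 0.0999)
  keep <- filter_events(ev)
  expect_equal(keep$event_id, ev$event_id[3])
})

test_that("filter matches an independent predicate scan on random events", {
  ev <- random_events(200, seed = 42)
  keep <- filter_events(ev, filter_config(0.1, 0.05))
  oracle_n <- sum(ev$fdr < 0.1 & ev$pvalue < 0.05)
  expect_equal(nrow(keep), oracle_n)
  # idempotent, order preserved
  expect_equal(filter_events(keep), keep)
  expect_true(!is.unsorted(match(keep$event_id, ev$event_id)))
})

test_that("relaxing thresholds never removes survivors (monotonicity)", {
  ev <- random_events(150, seed = 9)
  strict <- filter_events(ev, filter_config(0.05, 0.01))
  loose <- filter_events(ev, filter_config(0.2, 0.1))
  expect_true(all(strict$event_id %in% loose$event_id))
})

test_that("deduplication keys on type, position and strand", {
  ev <- random_events(5, seed = 2)
  dup <- rbind(ev, ev[2, ])             # identical event twice
  expect_equal(nrow(deduplicate_events(dup)), 5L)
  other <- ev[2, ]
  other$event_type <- "RI"              # same coordinates, other type
  other$event_id <- sub("^SE", "RI", other$event_id)
  expect_equal(nrow(deduplicate_events(rbind(dup, other))), 6L)
  # random planted duplicates match a set-of-keys oracle
  set.seed(7)
  big <- random_events(80, seed = 3)
  mixed <- big[sample.int(80, 200, replace = TRUE), ]
  expect_equal(nrow(deduplicate_events(mixed)),
               length(unique(mixed$event_id)))
})

test_that("frequency matrix counts unique significant events per gene", {
  ev <- random_events(4, seed = 4)
  ev$gene_symbol <- c("A", "A", "B", "C")
  sheet <- data.frame(comparison_id = c("c1", "c2"),
                      lncrna = c("L1", "L2"),
                      cell_line = c("HeLa", "HeLa"),
                      stringsAsFactors = FALSE)
  by_comp <- list(c1 = ev[1:3, ], c2 = ev[c(3, 3), ])  # duplicate in c2
  m <- build_frequency_matrix(by_comp, sheet, "SE")
  expect_equal(m$counts["A", "c1"], 2L)
  expect_equal(m$counts["B", "c1"], 1L)
  expect_equal(m$counts["B", "c2"], 1L)   # dedup within comparison
  expect_false("C" %in% rownames(m$counts))  # all-zero row removed
  # column sums equal per-comparison unique significant event counts
  expect_equal(unname(colSums(m$counts)), c(3L, 1L))
})

test_that("comparison without a table yields a warning and zero column", {
  ev <- random_events(2, seed = 6)
  sheet <- data.frame(comparison_id = c("c1", "c2"),
                      lncrna = c("L1", "L2"), cell_line = c("K562", "K562"),
                      stringsAsFactors = FALSE)
  expect_warning(m <- build_frequency_matrix(list(c1 = ev), sheet, "SE"),
                 "c2")
  expect_equal(unname(colSums(m$counts)[["c2"]]), 0L)
})

test_that("specificity summary reproduces hand-counted overlaps", {
  # gene sets {A,B,C}, {B,C,D}, {E}: pairwise overlaps 2, 0, 0; 2/5 shared
  counts <- matrix(0L, 5, 3,
                   dimnames = list(c("A", "B", "C", "D", "E"),
                                   c("x1", "x2", "x3")))
  counts[c("A", "B", "C"), "x1"] <- 1L
  counts[c("B", "C", "D"), "x2"] <- 1L
  counts["E", "x3"] <- 1L
  m <- structure(list(event_type = "SE", counts = counts,
                      samples = data.frame(comparison_id = paste0("x", 1:3),
                                           lncrna = paste0("L", 1:3),
                                           cell_line = c("HeLa", "K562",
                                                         "U87"))),
                 class = "event_frequency_matrix")
  sp <- specificity_summary(m)
  expect_equal(unname(sp$intersection_counts["HeLa&K562"]), 2)
  expect_equal(unname(sp$intersection_counts["HeLa&U87"]), 0)
  expect_equal(unname(sp$intersection_counts["K562&U87"]), 0)
  expect_equal(sp$shared_fraction, 2 / 5)
  expect_equal(sort(sp$shared_genes), c("B", "C"))
})

test_that("identical per-cell-line gene sets give shared fraction 1", {
  counts <- matrix(1L, 3, 2, dimnames = list(c("A", "B", "C"),
                                             c("x1", "x2")))
  m <- structure(list(event_type = "SE", counts = counts,
                      samples = data.frame(comparison_id = c("x1", "x2"),
                                           lncrna = c("L1", "L2"),
                                           cell_line = c("HeLa", "K562"))),
                 class = "event_frequency_matrix")
  expect_equal(specificity_summary(m)$shared_fraction, 1)
})

test_that("single cell line is flagged as degenerate", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("A", "B"), c("x1", "x2")))
  m <- structure(list(event_type = "SE", counts = counts,
                      samples = data.frame(comparison_id = c("x1", "x2"),
                                           lncrna = c("L1", "L2"),
                                           cell_line = c("HeLa", "HeLa"))),
                 class = "event_frequency_matrix")
  expect_match(specificity_summary(m)$note, "single cell line")
})
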