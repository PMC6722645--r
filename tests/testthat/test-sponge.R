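fake_results <- function(cell_line, lncrna, rbp, p_adj) {
  data.frame(cell_line = cell_line, lncrna = lncrna, rbp = rbp,
             pvalue = p_adj, p_adjusted = p_adj,
             stringsAsFactors = FALSE)
}

test_that("breadth is the significant fraction of tested RBPs", {
  res <- fake_results("HeLa", rep("L1", 10), paste0("R", 1:10),
                      c(rep(0.01, 7), rep(0.5, 3)))
  prof <- sponge_scores(res, alpha = 0.05)
  expect_equal(prof$n_rbps_tested, 10L)
  expect_equal(prof$n_rbps_significant, 7L)
  expect_equal(prof$breadth, 0.7)
})

test_that("null cells are excluded and all-null profiles flagged", {
  res <- rbind(
    fake_results("HeLa", rep("L1", 4), paste0("R", 1:4),
                 c(0.01, NA, 0.2, NA)),
    fake_results("HeLa", rep("L2", 4), paste0("R", 1:4),
                 rep(NA_real_, 4)))
  prof <- sponge_scores(res)
  l1 <- prof[prof$lncrna == "L1", ]
  expect_equal(l1$n_rbps_tested, 2L)
  expect_equal(l1$breadth, 0.5)
  l2 <- prof[prof$lncrna == "L2", ]
  expect_false(l2$defined)
  expect_true(is.na(l2$breadth))
  expect_equal(l2$rank, 2L)  # undefined ranks last
})

test_that("ranking breaks ties by significant count then name", {
  res <- rbind(
    fake_results("K562", rep("LB", 4), paste0("R", 1:4),
                 c(0.01, 0.01, 0.5, 0.5)),
    fake_results("K562", rep("LA", 4), paste0("R", 1:4),
                 c(0.01, 0.01, 0.5, 0.5)),
    fake_results("K562", rep("LC", 2), paste0("R", 1:2),
                 c(0.01, 0.5)))
  prof <- sponge_scores(res)
  # LA and LB tie on breadth 0.5 and count 2 -> name order; LC has breadth
  # 0.5 with fewer significant RBPs -> after them
  expect_equal(prof$lncrna, c("LA", "LB", "LC"))
  expect_equal(prof$rank, 1:3)
})

test_that("sponge ranking is invariant under RBP column relabeling", {
  set.seed(21)
  res <- fake_results("HeLa",
                      rep(paste0("L", 1:5), each = 8),
                      rep(paste0("R", 1:8), times = 5),
                      runif(40))
  prof1 <- sponge_scores(res)
  res2 <- res
  res2$rbp <- paste0("Z", match(res2$rbp, unique(res2$rbp)))
  prof2 <- sponge_scores(res2)
  expect_equal(prof1$lncrna, prof2$lncrna)
  expect_equal(prof1$rank, prof2$rank)
})

test_that("spearman distance matches naive rank-then-Pearson", {
  set.seed(4)
  m <- matrix(rnorm(36), 6, 6,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:6)))
  d <- spearman_distance(m)
  for (i in 1:6) {
    for (j in 1:6) {
      naive <- 1 - stats::cor(rank(m[i, ]), rank(m[j, ]))
      expect_equal(d[i, j], naive, tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d, t(d))
})

test_that("identical rows are at distance 0, anti-ranked rows at 2", {
  m <- rbind(a = 1:6, b = 1:6, c = 6:1)
  d <- spearman_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  cl <- cluster_matrix(m, axis = "rows")
  # identical rows merge first
  expect_equal(cl$row_hclust$height[1], 0)
})

test_that("zero-variance rows warn and take maximal distance", {
  m <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_warning(d <- spearman_distance(m), "zero-variance")
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "a"], 0)
})

test_that("leaf order is deterministic across runs", {
  set.seed(10)
  m <- matrix(sample(0:5, 48, replace = TRUE), 8, 6,
              dimnames = list(paste0("g", 8:1), paste0("s", 1:6)))
  c1 <- cluster_matrix(m, axis = "both")
  c2 <- cluster_matrix(m[sample(8), sample(6)], axis = "both")
  expect_equal(c1$row_order, c2$row_order)
  expect_equal(c1$col_order, c2$col_order)
})

test_that("proportional counts give rho 1; n < 3 is insufficient", {
  sheet <- data.frame(comparison_id = paste0("c", 1:4),
                      lncrna = paste0("L", 1:4),
                      cell_line = "HeLa", stringsAsFactors = FALSE)
  counts <- matrix(c(2L, 4L, 6L, 8L), 1, 4,
                   dimnames = list("G1", sheet$comparison_id))
  fm <- structure(list(event_type = "SE", counts = counts, samples = sheet),
                  class = "event_frequency_matrix")
  prof <- data.frame(cell_line = "HeLa", lncrna = paste0("L", 1:4),
                     n_rbps_significant = c(1L, 2L, 3L, 4L),
                     defined = TRUE, stringsAsFactors = FALSE)
  corr <- binding_splicing_correlation(fm, prof)
  sp <- corr[corr$method == "spearman", ]
  expect_equal(sp$estimate, 1)
  expect_equal(sp$status, "significant")
  corr2 <- binding_splicing_correlation(fm, prof[1:2, ])
  expect_true(all(corr2$status == "insufficient data"))
  expect_true(all(is.na(corr2$estimate)))
})

test_that("independent counts rarely reach significance", {
  sheet <- data.frame(comparison_id = paste0("c", 1:10),
                      lncrna = paste0("L", 1:10),
                      cell_line = "K562", stringsAsFactors = FALSE)
  set.seed(99)
  sig <- replicate(100, {
    counts <- matrix(rpois(10, 8), 1, 10,
                     dimnames = list("G1", sheet$comparison_id))
    fm <- structure(list(event_type = "SE", counts = counts,
                         samples = sheet),
                    class = "event_frequency_matrix")
    prof <- data.frame(cell_line = "K562", lncrna = paste0("L", 1:10),
                       n_rbps_significant = rpois(10, 5),
                       defined = TRUE, stringsAsFactors = FALSE)
    corr <- binding_splicing_correlation(fm, prof)
    corr$pvalue[corr$method == "spearman"] < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})
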