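test_that("contingency counts split focal vs background regions", {
  # lncRNA L1: 4 regions (3 bound); background L2: 10 regions (2 bound)
  flags <- matrix(c(rep(TRUE, 3), FALSE, rep(TRUE, 2), rep(FALSE, 8)),
                  ncol = 1, dimnames = list(NULL, "X"))
  bf <- make_flags(flags, lncrna = c(rep("L1", 4), rep("L2", 10)))
  tab <- build_contingency(bf, "L1", "X")
  expect_equal(tab, c(x = 3, y = 1, a = 2, b = 8))
  # RBP binding nothing: (0, n, 0, m)
  bf0 <- make_flags(matrix(FALSE, 14, 1, dimnames = list(NULL, "X")),
                    lncrna = c(rep("L1", 4), rep("L2", 10)))
  expect_equal(build_contingency(bf0, "L1", "X"), c(x = 0, y = 4, a = 0,
                                                    b = 10))
  expect_error(build_contingency(bf, "NOPE", "X"), "degenerate")
})

test_that("contingency equals a naive per-region loop on simulated flags", {
  set.seed(5)
  lnc <- sample(paste0("L", 1:4), 60, replace = TRUE)
  flags <- matrix(runif(120) < 0.3, 60, 2, dimnames = list(NULL, c("X", "Y")))
  bf <- make_flags(flags, lncrna = lnc)
  for (l in unique(lnc)) {
    for (r in c("X", "Y")) {
      tab <- build_contingency(bf, l, r)
      x <- 0; y <- 0; a <- 0; b <- 0
      for (i in seq_len(60)) {
        if (lnc[i] == l) {
          if (flags[i, r]) x <- x + 1 else y <- y + 1
        } else {
          if (flags[i, r]) a <- a + 1 else b <- b + 1
        }
      }
      expect_equal(tab, c(x = x, y = y, a = a, b = b))
      expect_equal(sum(tab), 60)  # conservation over all regions
    }
  }
})

test_that("fisher_exact reproduces hand-enumerated tails", {
  # (3,1,1,3): support {0..4}, PMF (1,16,36,16,1)/70
  ft <- fisher_exact(3, 1, 1, 3, alternative = "two.sided")
  expect_equal(ft$pvalue, 34 / 70, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, 9)
  expect_equal(fisher_exact(3, 1, 1, 3, "greater")$pvalue, 17 / 70,
               tolerance = 1e-12)
  # degenerate margins carry no signal
  expect_equal(fisher_exact(0, 5, 0, 5)$pvalue, 1)
  expect_true(is.nan(fisher_exact(0, 5, 0, 5)$odds_ratio))
  expect_true(is.na(fisher_exact(0, 0, 0, 0)$pvalue))
  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
})

test_that("fisher_exact agrees with PMF enumeration and fisher.test", {
  set.seed(9)
  for (i in 1:200) {
    tab <- as.integer(rmultinom(1, sample(5:60, 1), rep(0.25, 4)))
    for (alt in c("greater", "less", "two.sided")) {
      mine <- fisher_exact(tab[1], tab[2], tab[3], tab[4], alt)$pvalue
      expect_equal(mine, hyper_oracle(tab[1], tab[2], tab[3], tab[4], alt),
                   tolerance = 1e-12)
      expect_equal(mine,
                   stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                                      alternative = alt)$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment follows the step-up formula and skips nulls", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03), 0.03)
  p <- c(0.01, NA, 0.02, NA, 0.03, 0.04)
  adj <- adjust_pvalues(p)
  expect_equal(is.na(adj), is.na(p))
  expect_equal(adj[!is.na(adj)], rep(0.04, 4))  # m = 4, not 6
  # hand step-up on a random vector: adj_i = min_{k >= i} m * p_(k) / k
  set.seed(3)
  pv <- runif(25)
  adj <- adjust_pvalues(pv)
  o <- order(pv)
  hand <- rev(cummin(rev(length(pv) * pv[o] / seq_along(pv))))
  expect_equal(adj[o], pmin(1, hand))
})

test_that("enrichment results honour the null-row contract", {
  # X binds everything (no unbound anywhere): whole column null
  # Y binds only L1 regions: testable
  flags <- cbind(X = rep(TRUE, 12),
                 Y = c(rep(TRUE, 4), rep(FALSE, 8)))
  bf <- make_flags(flags, lncrna = c(rep("L1", 4), rep("L2", 4),
                                     rep("L3", 4)))
  res <- run_enrichment(bf)
  expect_true(all(is.na(res$pvalue[res$rbp == "X"])))
  expect_true(all(is.na(res$neg_log_p_adj[res$rbp == "X"])))
  expect_true(all(!is.na(res$pvalue[res$rbp == "Y"])))
  # conservation: every table sums to the total region count
  expect_true(all(res$x + res$y + res$a + res$b == 12))
  hm <- enrichment_heatmap_matrix(res, cluster = FALSE)
  expect_true(all(is.na(hm[, "X"])))
  expect_equal(hm["L1", "Y"], -log10(res$p_adjusted[res$rbp == "Y" &
                                                      res$lncrna == "L1"]))
})

test_that("-log10 heatmap cells match adjusted p-values", {
  flags <- cbind(Y = c(rep(TRUE, 6), rep(FALSE, 18)))
  bf <- make_flags(flags, lncrna = rep(c("L1", "L2", "L3"), each = 8))
  res <- run_enrichment(bf)
  expect_equal(res$neg_log_p_adj, -log10(res$p_adjusted))
  r1 <- res[res$lncrna == "L1", ]
  expect_equal(unname(c(r1$x, r1$y, r1$a, r1$b)), c(6, 2, 0, 16))
})

test_that("label permutation destroys planted enrichment (type-I)", {
  set.seed(811)
  # planted: L1 dense (0.8), others sparse (0.1)
  lnc <- rep(paste0("L", 1:6), each = 40)
  pvals <- replicate(30, {
    dens <- ifelse(lnc == "L1", 0.8, 0.1)
    flags <- matrix(runif(length(lnc)) < dens, ncol = 1,
                    dimnames = list(NULL, "X"))
    perm <- sample(lnc)  # break the label-binding association
    bf <- make_flags(flags, lncrna = perm)
    res <- run_enrichment(bf)
    res$pvalue
  })
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(frac, 0.05 + 3 * se)
})

test_that("permuted sidedness: two-sided and greater relate sensibly", {
  ft2 <- fisher_exact(8, 2, 3, 7, "two.sided")
  ftg <- fisher_exact(8, 2, 3, 7, "greater")
  expect_gte(ft2$pvalue, ftg$pvalue)
})
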