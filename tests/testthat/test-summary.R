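# Minimal regulatory/inheritance call sets built by hand.
fake_reg <- function(cis, trans, sig_allelic = abs(cis) > 0.3,
                     sig_trans = abs(trans) > 0.3,
                     sig_parental = abs(cis + trans) > 0.3) {
  n <- length(cis)
  data.frame(
    gene_id = paste0("g", seq_len(n)),
    cis = cis, trans = trans, parental_div = cis + trans,
    pct_cis = pct_cis(cis, trans),
    sig_parental = sig_parental, sig_allelic = sig_allelic,
    sig_trans = sig_trans,
    category = classify_regulatory(sig_parental, sig_allelic, sig_trans,
                                   cis, trans),
    stringsAsFactors = FALSE
  )
}

test_that("magnitude comparison reproduces the exact rank-sum case", {
  reg <- fake_reg(cis = c(1, 2, 3, 0, 0, 0) / 2,
                  trans = c(0, 0, 0, 10, 11, 12) / 2,
                  sig_allelic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                  sig_trans = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  got <- compare_magnitudes(reg)
  expect_equal(got$p_value, 0.1, tolerance = 1e-12)  # 2 / choose(6, 3)
  expect_equal(got$median_abs_cis, 1)
  expect_equal(got$median_abs_trans, 5.5)
  expect_equal(got$median_fold_trans, 2^5.5)
})

test_that("identical magnitude samples are not distinguishable", {
  reg <- fake_reg(cis = c(1, 2, 3), trans = c(1, 2, 3),
                  sig_allelic = TRUE, sig_trans = TRUE)
  expect_equal(compare_magnitudes(reg)$p_value, 1)
})

test_that("Kendall correlation behaves at its extremes", {
  set.seed(111)
  pd <- rnorm(200)
  reg <- fake_reg(cis = rep(0, 200), trans = pd)  # trans == parental_div
  ct <- correlate_divergence(reg)
  expect_equal(ct$tau[ct$component == "trans"], 1)
  # antisymmetry: negating one variable negates tau
  reg2 <- reg
  reg2$trans <- -reg2$trans
  ct2 <- correlate_divergence(reg2)
  expect_equal(ct2$tau[ct2$component == "trans"],
               -ct$tau[ct$component == "trans"])
  # independent cis: tau near zero
  reg3 <- fake_reg(cis = rnorm(500), trans = rnorm(500))
  reg3$parental_div <- rnorm(500)   # decouple entirely
  ct3 <- correlate_divergence(reg3)
  expect_lt(max(abs(ct3$tau)), 0.1)
})

test_that("percent-cis binning respects bin edges and medians", {
  reg <- fake_reg(cis = c(0.1, 0.5, 1.5, 3), trans = rep(0, 4))
  bins <- pct_cis_by_bin(reg, edges = c(1.25, 2, 4))
  expect_equal(nrow(bins), 4)
  expect_equal(bins$n, c(1L, 1L, 1L, 1L))  # folds 1.07, 1.41, 2.83, 8
  reg2 <- fake_reg(cis = rep(1, 5), trans = rep(1, 5))
  bins2 <- pct_cis_by_bin(reg2)
  expect_equal(bins2$median_pct_cis[bins2$n > 0], 50)
  expect_equal(sum(bins2$n), 5)
  expect_error(pct_cis_by_bin(reg, edges = c(2, 1.25)), "increasing")
})

test_that("constructed trans-growth makes percent-cis fall with divergence", {
  # cis magnitude constant, trans grows with total divergence
  cis <- rep(0.4, 300)
  trans <- seq(0.05, 4, length.out = 300)
  reg <- fake_reg(cis = cis, trans = trans)
  bins <- pct_cis_by_bin(reg)
  med <- bins$median_pct_cis[bins$n > 0]
  expect_true(all(diff(med) < 0))
})

test_that("percent-cis by inheritance contrasts the built-in strata", {
  reg <- fake_reg(cis = c(rep(2, 20), rep(0, 20)),
                  trans = c(rep(0, 20), rep(2, 20)))
  inh <- data.frame(
    gene_id = paste0("g", 1:40),
    cluster = c(rep("overdominance", 20), rep("additivity_f_gt_m", 20)),
    stringsAsFactors = FALSE
  )
  got <- pct_cis_by_inheritance(reg, inh)
  expect_equal(got$median_additive, 0)
  expect_equal(got$median_non_additive, 100)
  expect_lt(got$p_value, 0.01)
  # absent additive stratum
  inh$cluster <- "overdominance"
  got2 <- pct_cis_by_inheritance(reg, inh)
  expect_true(is.na(got2$median_additive))
  expect_true(is.na(got2$p_value))
})

test_that("category-by-pattern table column-normalizes to 100", {
  reg <- fake_reg(cis = c(1, 0, 2), trans = c(0, 1, 2))
  inh <- data.frame(gene_id = c("g1", "g2", "g3"),
                    cluster = c("additivity_f_gt_m", "male_dominance_up",
                                "underdominance"),
                    stringsAsFactors = FALSE)
  tab <- category_by_cluster_table(reg, inh)
  expect_equal(dim(tab$counts), c(7L, 4L))
  expect_equal(tab$col_pct["cis_only", "additivity"], 100)
  nonempty <- colSums(tab$counts) > 0
  expect_equal(unname(colSums(tab$col_pct)[nonempty]),
               rep(100, sum(nonempty)), tolerance = 0.1)
})

test_that("cross comparison is symmetric and exact on constructed counts", {
  mk <- function(cis_only, n) {
    reg <- fake_reg(cis = c(rep(2, cis_only), rep(0, n - cis_only)),
                    trans = rep(0, n))
    inh <- data.frame(gene_id = paste0("g", seq_len(n)),
                      cluster = rep(c("overdominance", "no_change"),
                                    length.out = n),
                      stringsAsFactors = FALSE)
    cross_summary(reg, inh, label = "x")
  }
  a <- mk(5, 10)
  b <- mk(0, 10)
  cmp <- compare_crosses(a, b)
  row <- cmp[cmp$comparison == "cis_only_among_genes", ]
  expect_equal(row$p_value, fisher_test_p(5, 5, 0, 10), tolerance = 1e-12)
  cmp_swapped <- compare_crosses(b, a)
  expect_equal(cmp_swapped$p_value[cmp_swapped$comparison ==
                                     "cis_only_among_genes"],
               row$p_value, tolerance = 1e-12)
  same <- compare_crosses(a, a)
  expect_true(all(same$p_value[1:4] == 1))
})
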