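test_that("the decomposition reproduces hand-computed log ratios", {
  d <- cis_trans_decompose(400, 100, 300, 100, pseudocount = 0)
  expect_equal(d$parental_div, 2)
  expect_equal(d$cis, log2(3), tolerance = 1e-12)
  expect_equal(d$trans, 2 - log2(3), tolerance = 1e-12)
  # equal alleles: no cis signal
  expect_equal(cis_trans_decompose(50, 80, 100, 100)$cis, 0)
  # compensatory geometry: equal parents, imbalanced alleles
  d2 <- cis_trans_decompose(200, 200, 200, 100, pseudocount = 0)
  expect_equal(d2$trans, -d2$cis)
  expect_error(cis_trans_decompose(-1, 1, 1, 1), "nonnegative")
})

test_that("the decomposition identity holds to machine precision", {
  set.seed(103)
  n <- 2000
  d <- cis_trans_decompose(rpois(n, 200), rpois(n, 100),
                           rpois(n, 150), rpois(n, 50))
  expect_lt(max(abs(d$cis + d$trans - d$parental_div)), 1e-12)
})

test_that("percent cis covers its boundary cases", {
  expect_equal(pct_cis(1, 1), 50)
  expect_equal(pct_cis(-2, 0), 100)
  expect_equal(pct_cis(0, 3), 0)
  expect_true(is.na(pct_cis(0, 0)))
  expect_equal(pct_cis(log2(3), 2 - log2(3)), log2(3) / 2 * 100,
               tolerance = 1e-12)  # ~79.25
})

test_that("the flag table maps onto the seven categories totally", {
  flags <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE),
                       C = c(TRUE, FALSE))
  got <- classify_regulatory(flags$A, flags$B, flags$C,
                             cis = rep(1, 8), trans = rep(0.5, 8))
  want <- with(flags, ifelse(!A & !B & !C, "conserved",
               ifelse(A & B & !C, "cis_only",
               ifelse(A & !B & C, "trans_only",
               ifelse(!A & B & C, "compensatory",
               ifelse(A & B & C, "cis_plus_trans", "ambiguous"))))))
  expect_identical(got, want)
  # sign splits inside the all-significant cell
  expect_identical(classify_regulatory(TRUE, TRUE, TRUE, 1.2, -0.4),
                   "cis_by_trans")
  expect_identical(classify_regulatory(TRUE, TRUE, TRUE, 1.2, 0.4),
                   "cis_plus_trans")
  expect_identical(classify_regulatory(TRUE, TRUE, TRUE, 0, 0.4),
                   "ambiguous")
  expect_identical(classify_regulatory(TRUE, FALSE, FALSE, 1, 1),
                   "ambiguous")
})

test_that("pooled pseudo-counts average replicates on a common scale", {
  gt <- data.frame(gene_id = "g1", n_sites = 1L,
                   parent1_rep1_a1 = 10, parent1_rep2_a1 = 20,
                   parent1_rep3_a1 = 30,
                   parent2_rep1_a2 = 7, parent2_rep2_a2 = 7,
                   parent2_rep3_a2 = 8,
                   F1_rep1_a1 = 5, F1_rep2_a1 = 5, F1_rep3_a1 = 5,
                   F1_rep1_a2 = 1, F1_rep2_a2 = 1, F1_rep3_a2 = 1,
                   stringsAsFactors = FALSE)
  fac <- flat_factors(c(paste0("parent1_rep", 1:3),
                        paste0("parent2_rep", 1:3),
                        paste0("F1_rep", 1:3)))
  inp <- allelic_inputs(gt, fac)
  expect_equal(inp$P1, 20)
  expect_equal(inp$P2, 7)   # mean 22/3 rounds half-to-even to 7
  expect_equal(inp$F1A1, 5)
  expect_equal(inp$F1A2, 1)
})

test_that("pooled values track simulator expectations under size factors", {
  cross <- simulate_cross(sim_config(600,
    category_mix = c(conserved = 0.7, cis_only = 0.3),
    effect_size_range = c(1, 1), base_mean = 1000, dispersion = 0.01,
    library_size_factors = c(1, 2, 0.5), seed = 19))
  prep <- prep_cross(cross$sites)
  inp <- allelic_inputs(prep$gene_tab, prep$factors)
  truth <- cross$truth[match(inp$gene_id, cross$truth$gene_id), ]
  # normalization undoes the depth factors: pooled ratios sit on the truth
  expect_lt(median(abs(log2(inp$P1 / inp$P2) -
                         truth$expected_parental_log2)), 0.15)
  share <- 2^truth$cis_effect / (1 + 2^truth$cis_effect)
  expect_lt(abs(mean(inp$F1A1 / (inp$F1A1 + inp$F1A2)) - mean(share)),
            0.02)
})

test_that("regulatory calls recover the simulated architecture", {
  cross <- simulate_cross(sim_config(800, category_mix = c(
    conserved = 0.4, cis_only = 0.2, trans_only = 0.2, compensatory = 0.2),
    effect_size_range = c(1.2, 2), base_mean = 1000, dispersion = 0.005,
    seed = 23))
  prep <- prep_cross(cross$sites)
  reg <- regulatory_calls(prep$gene_tab, prep$factors)
  truth <- cross$truth[match(reg$gene_id, cross$truth$gene_id), ]
  for (cat in c("cis_only", "trans_only", "compensatory")) {
    idx <- truth$category == cat
    expect_gt(mean(reg$category[idx] == cat), 0.7)
  }
  # cis estimates track the truth closely
  expect_lt(median(abs(reg$cis - truth$cis_effect)), 0.15)
})

test_that("relabelling the parents negates estimates, keeps inference", {
  cross <- simulate_cross(sim_config(300, seed = 29))
  prep <- prep_cross(cross$sites)
  reg <- regulatory_calls(prep$gene_tab, prep$factors)
  prep2 <- prep_cross(swap_parents(cross$sites))
  reg2 <- regulatory_calls(prep2$gene_tab, prep2$factors)
  reg2 <- reg2[match(reg$gene_id, reg2$gene_id), ]
  expect_equal(reg2$cis, -reg$cis, tolerance = 1e-12)
  expect_equal(reg2$trans, -reg$trans, tolerance = 1e-12)
  expect_equal(reg2$parental_div, -reg$parental_div, tolerance = 1e-12)
  expect_equal(reg2$p_parental, reg$p_parental, tolerance = 1e-12)
  expect_equal(reg2$p_allelic, reg$p_allelic, tolerance = 1e-12)
  expect_equal(reg2$p_trans, reg$p_trans, tolerance = 1e-12)
  expect_equal(reg2$pct_cis, reg$pct_cis, tolerance = 1e-12)
  expect_identical(reg2$category, reg$category)
})

test_that("all-zero genes are excluded and logged", {
  gt <- data.frame(gene_id = c("g1", "g2"), n_sites = 1L,
                   parent1_rep1_a1 = c(100, 0), parent1_rep2_a1 = c(90, 0),
                   parent2_rep1_a2 = c(80, 0), parent2_rep2_a2 = c(85, 0),
                   F1_rep1_a1 = c(40, 0), F1_rep2_a1 = c(42, 0),
                   F1_rep1_a2 = c(41, 0), F1_rep2_a2 = c(39, 0),
                   stringsAsFactors = FALSE)
  fac <- flat_factors(c("parent1_rep1", "parent1_rep2", "parent2_rep1",
                        "parent2_rep2", "F1_rep1", "F1_rep2"))
  reg <- regulatory_calls(gt, fac)
  expect_identical(reg$gene_id, "g1")
  expect_identical(attr(reg, "excluded"), "g2")
})
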