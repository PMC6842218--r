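test_that("configuration invariants are enforced", {
  expect_error(sim_config(10, category_mix = c(conserved = 0.5)),
               "sum to 1")
  expect_error(sim_config(10, base_mean = 0), "positive")
  expect_error(sim_config(10, n_replicates = 1), ">= 2")
  expect_error(sim_config(10, mapping_bias = 1.5), "mapping_bias")
  expect_error(sim_config(10, library_size_factors = c(1, 2)), "length")
  expect_error(sim_config(0), ">= 1")
})

test_that("truth table encodes the generative identities exactly", {
  cross <- simulate_cross(sim_config(400, category_mix = c(
    conserved = 0.2, cis_only = 0.2, trans_only = 0.2,
    cis_plus_trans = 0.15, cis_by_trans = 0.15, compensatory = 0.1),
    seed = 11))
  tr <- cross$truth
  expect_identical(tr$expected_parental_log2,
                   tr$cis_effect + tr$trans_effect)
  expect_identical(tr$expected_f1_allelic_log2, tr$cis_effect)
  # category constraints
  with(tr[tr$category == "conserved", ],
       expect_true(all(cis_effect == 0 & trans_effect == 0)))
  with(tr[tr$category == "cis_only", ],
       expect_true(all(trans_effect == 0 & abs(cis_effect) > 0)))
  with(tr[tr$category == "trans_only", ],
       expect_true(all(cis_effect == 0 & abs(trans_effect) > 0)))
  with(tr[tr$category == "compensatory", ],
       expect_true(all(trans_effect == -cis_effect & cis_effect != 0)))
  with(tr[tr$category == "cis_plus_trans", ],
       expect_true(all(cis_effect * trans_effect > 0)))
  with(tr[tr$category == "cis_by_trans", ],
       expect_true(all(cis_effect * trans_effect < 0 &
                         cis_effect + trans_effect != 0)))
})

test_that("identical seeds give byte-identical output, new seeds differ", {
  cfg <- sim_config(50, seed = 42, mapping_bias = 0.1)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  c <- simulate_cross(sim_config(50, seed = 43, mapping_bias = 0.1))
  expect_false(identical(a$sites, c$sites))
})

test_that("conserved genes are symmetric: means match and F1 share is half", {
  cross <- simulate_cross(sim_config(2000, category_mix = c(conserved = 1),
                                     base_mean = 500, dispersion = 0.05,
                                     seed = 7))
  gc <- cross$gene_counts
  p1 <- rowMeans(gc[, grep("^parent1", names(gc))])
  p2 <- rowMeans(gc[, grep("^parent2", names(gc))])
  expect_lt(abs(mean(log2(p1 / p2))), 0.05)
  a1 <- rowSums(gc[, grep("^F1_rep[0-9]+_a1$", names(gc))])
  a2 <- rowSums(gc[, grep("^F1_rep[0-9]+_a2$", names(gc))])
  expect_lt(abs(sum(a1) / sum(a1 + a2) - 0.5), 0.005)
  # moment check at the library level
  x <- gc$parent1_rep1_a1
  expect_lt(abs(mean(x) / 500 - 1), 0.05)
  expect_lt(abs(var(x) / (500 + 0.05 * 500^2) - 1), 0.15)
})

test_that("cis and trans effects surface as the expected ratios", {
  # pure cis at +1: F1 allele ratio 2:1 and parental ratio 2:1
  cross <- simulate_cross(sim_config(1500,
    category_mix = c(cis_only = 1), effect_size_range = c(1, 1),
    base_mean = 800, dispersion = 0.02, seed = 5))
  gc <- cross$gene_counts
  sgn <- sign(cross$truth$cis_effect)
  a1 <- rowSums(gc[, grep("^F1_rep[0-9]+_a1$", names(gc))])
  a2 <- rowSums(gc[, grep("^F1_rep[0-9]+_a2$", names(gc))])
  expect_lt(abs(mean(sgn * log2(a1 / a2)) - 1), 0.05)
  p1 <- rowMeans(gc[, grep("^parent1", names(gc))])
  p2 <- rowMeans(gc[, grep("^parent2", names(gc))])
  expect_lt(abs(mean(sgn * log2(p1 / p2)) - 1), 0.05)
})

test_that("library size factors scale per-library means", {
  cross <- simulate_cross(sim_config(1200, category_mix = c(conserved = 1),
    base_mean = 400, dispersion = 0.01,
    library_size_factors = c(1, 2, 0.5), seed = 9))
  gc <- cross$gene_counts
  expect_lt(abs(mean(gc$parent1_rep1_a1) / 400 - 1), 0.05)
  expect_lt(abs(mean(gc$parent2_rep1_a2) / 800 - 1), 0.05)
  f1tot <- gc$F1_rep1_a1 + gc$F1_rep1_a2
  expect_lt(abs(mean(f1tot) / 200 - 1), 0.05)
})

test_that("site split conserves gene totals exactly", {
  cross <- simulate_cross(sim_config(80, n_snps = c(1, 3, 7), seed = 13))
  agg <- aggregate_to_genes(cross$sites)
  gc <- cross$gene_counts[match(agg$gene_id, cross$gene_counts$gene_id), ]
  for (col in setdiff(names(gc), "gene_id")) {
    expect_identical(as.numeric(agg[[col]]), as.numeric(gc[[col]]))
  }
})

test_that("dual-mapping copies are identical at zero bias, thinned otherwise", {
  a <- simulate_cross(sim_config(60, mapping_bias = 0, seed = 3))
  expect_identical(a$sites$F1_rep1_a1_m1, a$sites$F1_rep1_a1_m2)
  expect_identical(a$sites$F1_rep2_a2_m1, a$sites$F1_rep2_a2_m2)
  b <- simulate_cross(sim_config(60, mapping_bias = 0.3, seed = 3))
  expect_true(all(b$sites$F1_rep1_a1_m2 <= b$sites$F1_rep1_a1_m1))
  expect_true(all(b$sites$F1_rep1_a2_m1 <= b$sites$F1_rep1_a2_m2))
  expect_lt(sum(b$sites$F1_rep1_a1_m2) / sum(b$sites$F1_rep1_a1_m1), 0.8)
})

test_that("a simulated cross round-trips through the writer", {
  cross <- simulate_cross(sim_config(15, seed = 2))
  dir <- withr::local_tempdir()
  write_sim_cross(cross, dir)
  expect_true(all(file.exists(file.path(dir,
    c("counts.tsv", "truth.tsv", "config.json")))))
  back <- read_snp_counts(file.path(dir, "counts.tsv"))
  expect_equal(back, cross$sites)
})
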