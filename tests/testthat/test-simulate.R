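test_that("all-null configuration yields uniform p-values in both traits", {
  cfg <- sim_config(seed = 11, m_snps = 10000, pi_null = 1, pi_a = 0,
                    pi_b = 0, pi_ab = 0)
  s <- simulate_two_trait_stats(cfg)
  ks_a <- suppressWarnings(ks.test(s$stats_a$pvalue, "punif"))$statistic
  ks_b <- suppressWarnings(ks.test(s$stats_b$pvalue, "punif"))$statistic
  expect_lt(ks_a, 0.02)
  expect_lt(ks_b, 0.02)
  expect_true(all(s$truth$component == "null"))
})

test_that("zero effect size makes a causal trait indistinguishable from null", {
  cfg <- sim_config(seed = 12, m_snps = 10000, mu_a = 0)
  s <- simulate_two_trait_stats(cfg)
  ks_a <- suppressWarnings(ks.test(s$stats_a$pvalue, "punif"))$statistic
  expect_lt(ks_a, 0.02)
})

test_that("generated p-values live in (0, 1] and the RNG contract holds", {
  cfg <- sim_config(seed = 13, m_snps = 2000)
  s1 <- simulate_two_trait_stats(cfg)
  s2 <- simulate_two_trait_stats(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_two_trait_stats(sim_config(seed = 14, m_snps = 2000))
  expect_false(identical(s1$truth$z_a, s3$truth$z_a))
  expect_true(all(s1$stats_a$pvalue > 0 & s1$stats_a$pvalue <= 1))
  expect_true(all(s1$stats_b$pvalue > 0 & s1$stats_b$pvalue <= 1))
})

test_that("mixture component counts follow the configured proportions", {
  pis <- c(null = 0.90, a_only = 0.04, b_only = 0.04, pleiotropic = 0.02)
  pvals <- vapply(21:25, function(sd) {
    s <- simulate_two_trait_stats(sim_config(seed = sd, m_snps = 10000))
    counts <- table(factor(s$truth$component, levels = names(pis)))
    suppressWarnings(chisq.test(counts, p = pis)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("invalid mixture proportions are rejected", {
  expect_error(sim_config(seed = 1, pi_null = 0.5, pi_a = 0.1, pi_b = 0.1,
                          pi_ab = 0.1), "sum to 1")
  expect_error(sim_config(seed = 1, pi_null = 0.95, pi_a = -0.01,
                          pi_b = 0.04, pi_ab = 0.02), "non-negative|sum to 1")
})

test_that("panel LD structure: independent SNPs, hot blocks, block borders", {
  n <- 500
  # rho = 0: essentially no LD anywhere
  cfg0 <- sim_config(seed = 31, m_snps = 110, n_samples = n, rho = 0,
                     block_size = 10, n_chrom = 1)
  pan0 <- simulate_reference_panel(cfg0)
  d0 <- pan0$dosages[pan0$info$chrom == "1", ]
  cm0 <- cor(t(d0))^2
  expect_lte(mean(cm0[upper.tri(cm0)]), 0.05)

  # rho = 0.95: adjacent SNPs inside a block strongly correlated
  cfg1 <- sim_config(seed = 32, m_snps = 110, n_samples = n, rho = 0.95,
                     block_size = 10, n_chrom = 1)
  pan1 <- simulate_reference_panel(cfg1)
  d1 <- pan1$dosages[pan1$info$chrom == "1", ]
  k <- nrow(d1)
  block <- ceiling(seq_len(k) / 10)
  adj <- which(block[-k] == block[-1])
  r2_adj <- vapply(adj, function(i) cor(d1[i, ], d1[i + 1, ])^2, numeric(1))
  expect_gt(median(r2_adj), 0.2)

  # cross-block pairs stay uncorrelated even at high rho
  cross <- outer(seq_len(k), seq_len(k),
                 function(i, j) block[i] != block[j] & i < j)
  cm1 <- cor(t(d1))^2
  expect_lte(mean(cm1[cross]), 0.05)

  # dosages are genotypes; MAF recomputed from dosages respects maf_range
  expect_true(all(pan1$dosages %in% c(0, 1, 2)))
  expect_true(all(pan1$info$maf > 0.05 - 3 * sqrt(0.05 * 0.95 / (2 * n))))
})

test_that("detection evaluation counts errors against simulation truth", {
  truth <- data.table::data.table(
    snp_id = paste0("rs", 1:40),
    component = rep(c("null", "a_only", "b_only", "pleiotropic"), each = 10),
    z_a = 0, z_b = 0)
  expect_equal(
    suppressMessages(evaluate_detection(truth, character(0), "conjunction")),
    c(empirical_fdr = 0, power = 0))
  pleio <- truth$snp_id[truth$component == "pleiotropic"]
  perfect <- evaluate_detection(truth, pleio, "conjunction")
  expect_equal(unname(perfect), c(0, 1))
  mixed <- evaluate_detection(truth, c(truth$snp_id[1:10], pleio),
                              "conjunction")
  expect_equal(unname(mixed["empirical_fdr"]), 0.5)
  # direction-specific relevant sets
  ab <- evaluate_detection(truth, truth$snp_id[11:20], "A|B")
  expect_equal(unname(ab), c(0, 0.5))  # a_only called: half of A-causal set
  expect_error(evaluate_detection(truth, "rs999", "A|B"), "absent from truth")
})
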