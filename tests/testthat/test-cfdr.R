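test_that("conditional empirical cdf counts are self-inclusive and exact", {
  expect_equal(conditional_cdf(0.4, 0.7, 1),
               c(n_cond = 1, n_joint = 1, ccdf = 1))
  # SNP maximal in both coordinates
  expect_equal(conditional_cdf(c(.1, .2, .3), c(.01, .5, .9), 3),
               c(n_cond = 3, n_joint = 3, ccdf = 1))
  # hand-counted interior case
  expect_equal(conditional_cdf(c(.1, .2, .3, .4), c(.4, .3, .2, .1), 2),
               c(n_cond = 3, n_joint = 1, ccdf = 1 / 3))
})

test_that("a SNP alone in its conditioning subset has cfdr equal to its p", {
  # strictly smallest p2 -> n_cond = n_joint = 1 -> cfdr = p1
  m <- make_merged(p1 = c(3.25e-7, 0.5, 0.8), p2 = c(1.3e-36, 0.2, 0.9))
  tab <- cfdr_estimate(m, "A|B")
  expect_equal(tab$cfdr[1], 3.25e-7)
  expect_equal(tab$ccdf[1], 1)
})

test_that("vacuous conditioning reduces cfdr to the BH-style quantity", {
  set.seed(61)
  p1 <- runif(50)
  m <- make_merged(p1 = p1, p2 = rep(1, 50))
  tab <- cfdr_estimate(m, "A|B")
  expect_equal(tab$cfdr, pmin(1, p1 * 50 / rank(p1, ties.method = "max")))
})

test_that("six-SNP worked instance matches the double-loop oracle exactly", {
  p1 <- c(.01, .02, .5, .6, .9, .95)
  p2 <- c(.03, .5, .04, .9, .95, .99)
  tab <- cfdr_estimate(make_merged(p1, p2), "A|B")
  expect_identical(tab$cfdr, oracle_cfdr(p1, p2))
  expect_identical(as.numeric(tab$n_joint), oracle_joint_counts(p1, p2))
})

test_that("vectorized estimator equals the counting oracle, ties included", {
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(5:400, 1)
    # heavy ties on a coarse grid plus continuous values
    p1 <- sample(c(runif(n), round(runif(n), 1) + 0.05), n)
    p2 <- sample(c(runif(n), round(runif(n), 1) + 0.05), n)
    p1 <- pmin(pmax(p1, 1e-6), 1)
    p2 <- pmin(pmax(p2, 1e-6), 1)
    tab <- cfdr_estimate(make_merged(p1, p2), "A|B")
    expect_identical(as.numeric(tab$n_joint), oracle_joint_counts(p1, p2))
    expect_equal(tab$cfdr, oracle_cfdr(p1, p2))
  }
})

test_that("direction B|A swaps the roles of the two traits", {
  set.seed(63)
  p1 <- runif(30); p2 <- runif(30)
  ba <- cfdr_estimate(make_merged(p1, p2), "B|A")
  ab_swapped <- cfdr_estimate(make_merged(p2, p1), "A|B")
  expect_equal(ba$cfdr, ab_swapped$cfdr)
  expect_equal(ba$p1, p2)
})

test_that("cfdr is bounded below by the nominal p-value", {
  set.seed(64)
  m <- make_merged(runif(500), runif(500))
  for (dir in c("A|B", "B|A")) {
    tab <- cfdr_estimate(m, dir)
    expect_true(all(tab$cfdr >= tab$p1))
    expect_true(all(tab$cfdr <= 1))
    expect_true(all(tab$ccdf > 0 & tab$ccdf <= 1))
    expect_true(all(tab$n_joint >= 1 & tab$n_joint <= tab$n_cond))
  }
})

test_that("conjunction FDR is the per-SNP maximum of the two directions", {
  m <- make_merged(c(2.52e-124, 8.66e-15, 0.3), c(1.9e-10, 2.5e-4, 0.4))
  ab <- cfdr_estimate(m, "A|B")
  ba <- cfdr_estimate(m, "B|A")
  conj <- conjunction_fdr(ab, ba)
  expect_equal(conj$conj_fdr, pmax(ab$cfdr, ba$cfdr))
  # max identity on equal inputs
  expect_equal(conjunction_fdr(ab, ab)$conj_fdr, ab$cfdr)
  # id mismatch is an alignment error naming offenders
  ba_bad <- data.table::copy(ba)[1, snp_id := "rs999"]
  expect_error(conjunction_fdr(ab, ba_bad), "rs999")
})

test_that("published worked-example loci reproduce under the conjunction rule", {
  loci <- bmi_t2d_loci()
  conj <- reconjoin_loci(loci)
  expect_equal(conj$conj_fdr, loci$conj_fdr)
  expect_equal(conj$conj_fdr[conj$snp_id == "rs9930506"], 1.90e-10)
  expect_equal(conj$conj_fdr[conj$snp_id == "rs7141420"], 0.001125)
})

test_that("significance calls use a strict threshold and sort ascending", {
  tab <- data.table::data.table(snp_id = c("a", "b", "c"),
                                cfdr = c(0.05, 0.01, 0.2))
  out <- call_significant(tab, 0.05, "cfdr")
  expect_equal(out$snp_id, "b")            # 0.05 itself excluded
  expect_equal(nrow(call_significant(tab, 1, "cfdr")), 3)
  expect_equal(call_significant(tab, 1, "cfdr")$cfdr, c(0.01, 0.05, 0.2))
  expect_error(call_significant(tab, 0.05, "conj_fdr"), "not present")
})

test_that("independent conditioning leaves the median cfdr near the BH level", {
  # negative-control property: with p2 independent of p1, conditioning is
  # uninformative and cfdr behaves like the unconditional empirical FDR
  set.seed(65)
  m <- merged_from_sim(simulate_two_trait_stats(
    negative_control_config(seed = 66, m_snps = 20000)))
  tab <- cfdr_estimate(m, "A|B")
  bh <- pmin(1, tab$p1 * nrow(m) / rank(tab$p1, ties.method = "max"))
  expect_lt(abs(median(tab$cfdr) - median(bh)) / median(bh), 0.2)
})
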