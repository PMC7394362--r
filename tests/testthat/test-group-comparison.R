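test_that("median difference uses the base median convention", {
  expect_equal(median_difference(c(1, 2, 3), c(5, 7)), -4)
  expect_equal(median_difference(c(1, 3), c(0, 0)), 2)
})

test_that("the bootstrap is deterministic under a fixed seed", {
  a <- rnorm(30, 2)
  b <- rnorm(30, 0)
  r1 <- bootstrap_median_ci(a, b, n_replicates = 500, seed = 5)
  r2 <- bootstrap_median_ci(a, b, n_replicates = 500, seed = 5)
  expect_identical(r1, r2)
  r3 <- bootstrap_median_ci(a, b, n_replicates = 500, seed = 6)
  expect_false(identical(r1$ci_low, r3$ci_low))
  expect_equal(r1$estimate, median(a) - median(b))
  expect_lte(r1$ci_low, r1$ci_high)
  expect_equal(r1$n_a, 30)
  expect_error(bootstrap_median_ci(a, b, n_replicates = 1), "at least 2")
  expect_warning(bootstrap_median_ci(a, b, n_replicates = 50, seed = 1),
                 "fewer than 100")
})

test_that("the bootstrap detects a planted shift and not a null", {
  set.seed(81)
  a <- rnorm(100, 3)
  b <- rnorm(100, 0)
  shifted <- bootstrap_median_ci(a, b, n_replicates = 2000, seed = 9)
  expect_true(shifted$significant)
  expect_gt(shifted$ci_low, 0)
  null <- bootstrap_median_ci(rnorm(100), rnorm(100),
                              n_replicates = 2000, seed = 9)
  expect_true(null$ci_low <= 0 && null$ci_high >= 0 || !null$significant)
  # significance is defined exactly as "CI excludes zero"
  expect_equal(null$significant, null$ci_low > 0 || null$ci_high < 0)
})

test_that("bootstrap leaves the global RNG stream untouched", {
  set.seed(123)
  a <- rnorm(10)
  b <- rnorm(10)
  before <- .Random.seed
  invisible(bootstrap_median_ci(a, b, n_replicates = 200, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("wilcoxon statistic is the rank sum of the first group", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)
  expect_lt(res$p_value, 0.15)
  tied <- wilcoxon_rank_sum(c(1, 1, 2), c(1, 2, 2))
  expect_equal(tied$statistic, sum(rank(c(1, 1, 2, 1, 2, 2))[1:3]))
  expect_warning(deg <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)),
                 "all values identical")
  expect_equal(deg$p_value, 1)
})

test_that("asymptotic p-values track the exact permutation p at small n", {
  # tie-free data: the regime where the normal approximation is supported;
  # extreme ties at these sizes are a documented limitation
  set.seed(91)
  for (i in 1:40) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- runif(na)
    b <- runif(nb)
    p_asym <- wilcoxon_rank_sum(a, b)$p_value
    p_exact <- oracle_perm_wilcoxon(a, b)
    expect_lt(abs(p_asym - p_exact), 0.1)
  }
})

test_that("group comparison covers the four pairs and pools IBD", {
  set.seed(101)
  donors <- data.frame(
    donor_id = sprintf("d%03d", 1:80),
    group = rep(c("healthy", "ibd_cd", "ibd_uc", "prediabetes"), each = 20),
    presence_count = c(pmin(18, rpois(20, 13)), pmin(18, rpois(20, 10)),
                       pmin(18, rpois(20, 10)), pmin(18, rpois(20, 13))))
  res <- compare_all_groups(donors, n_replicates = 500, seed = 2)
  expect_equal(nrow(res), 4)
  expect_equal(res$group_a, c("healthy", "healthy", "prediabetes", "ibd_cd"))
  expect_equal(res$n_b[res$group_b == "ibd"], c(40, 40))
  expect_true(all(c("wilcoxon_statistic", "wilcoxon_p", "metric") %in%
                    names(res)))
  # identical inputs and seed reproduce identical intervals
  res2 <- compare_all_groups(donors, n_replicates = 500, seed = 2)
  expect_identical(res, res2)
})

test_that("pairs with too few donors are skipped with a message", {
  donors <- data.frame(
    donor_id = c("d1", "d2", "d3", "d4", "d5"),
    group = c("healthy", "healthy", "ibd_cd", "ibd_uc", "prediabetes"),
    presence_count = c(12L, 14L, 9L, 10L, 13L))
  expect_message(res <- compare_all_groups(donors, n_replicates = 200,
                                           seed = 3),
                 "fewer than 2 donors")
  expect_false("prediabetes" %in% res$group_a)
  expect_true("ibd" %in% res$group_b)
})

test_that("comparisons can use bacteroidetes abundance as the metric", {
  set.seed(111)
  donors <- data.frame(
    donor_id = sprintf("d%03d", 1:40),
    group = rep(c("healthy", "ibd_cd"), each = 20),
    presence_count = rep(10L, 40),
    bacteroidetes = c(rnorm(20, 55, 5), rnorm(20, 35, 5)))
  res <- compare_all_groups(donors, metric = "bacteroidetes_abundance",
                            n_replicates = 1000, seed = 4)
  row <- res[res$group_a == "healthy" & res$group_b == "ibd", ]
  expect_true(row$significant)
  expect_gt(row$estimate, 10)
})
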