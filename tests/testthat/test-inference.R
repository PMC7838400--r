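test_that("pearson_r matches direct evaluation and validates input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  expect_equal(pearson_r(x, y), cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  expect_equal(pearson_r(x, y), 0.7850, tolerance = 1e-4)
  expect_error(pearson_r(1:2, 1:2), class = "pl_degenerate_input")
  expect_error(pearson_r(rep(1, 5), 1:5), class = "pl_degenerate_input")
})

test_that("permutation p uses the add-one rule and respects the identity case", {
  set.seed(10)
  x <- sample(25)  # distinct values: only the identity attains r = 1
  out <- permutation_p(x, x, n_perm = 10000, seed = 3)
  expect_equal(out$p, 1 / 10001)
  expect_equal(out$r, 1)
  # never zero, invariant to common rescaling
  y <- rnorm(25)
  p1 <- permutation_p(x, y, n_perm = 500, seed = 5)
  p2 <- permutation_p(x * 10 + 3, y, n_perm = 500, seed = 5)
  p3 <- permutation_p(x, y * -2, n_perm = 500, seed = 5)
  expect_gt(p1$p, 0)
  expect_equal(p1$p, p2$p)
  expect_equal(p1$p, p3$p)  # one-sided follows the flipped observed sign
  # deterministic under a fixed seed
  expect_identical(permutation_p(x, y, n_perm = 500, seed = 5), p1)
})

test_that("sampled permutation p agrees with the exhaustive n = 6 oracle", {
  set.seed(20)
  for (rep in 1:5) {
    x <- rnorm(6)
    y <- rnorm(6)
    exact <- oracle_exact_perm_p(x, y)
    sampled <- permutation_p(x, y, n_perm = 100000, seed = rep)$p
    expect_lt(abs(sampled - exact), 0.01)
  }
})

test_that("group permutation test permutes masks as the exchangeable units", {
  set.seed(30)
  dmg <- rnorm(25)
  # all control columns identical: mean r equals the single-column r and p
  # equals the single-column permutation p
  q1 <- rnorm(25)
  qm <- matrix(q1, 25, 10)
  grp <- group_permutation_p(dmg, qm, n_perm = 2000, seed = 8)
  # both procedures permute the damage vector, so with identical seeds the
  # degenerate group test reproduces the single-column test exactly
  single <- permutation_p(q1, dmg, n_perm = 2000, seed = 8)
  expect_equal(grp$mean_r, single$r, tolerance = 1e-12)
  expect_equal(grp$r_values, rep(single$r, 10), tolerance = 1e-12)
  expect_equal(grp$p, single$p)
  # strong coupling: power and sign
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    d <- rnorm(25)
    qm2 <- matrix(2 * d, 25, 10) + matrix(rnorm(250, sd = 0.8), 25, 10)
    g <- group_permutation_p(d, qm2, n_perm = 1000, seed = s)
    g$mean_r > 0 && g$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(group_permutation_p(dmg, matrix(1, 25, 3), n_perm = 10),
               class = "pl_degenerate_input")
})

test_that("group permutation rejection is near alpha under the null", {
  set.seed(40)
  rej <- vapply(1:500, function(i) {
    d <- rnorm(25)
    qm <- matrix(rnorm(25 * 10), 25, 10)
    group_permutation_p(d, qm, n_perm = 199, side = "two_sided",
                        seed = i)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("bootstrap comparison has the documented tail behaviour", {
  # degenerate pseudo distribution equal to the real value: p capped at 1
  expect_equal(bootstrap_compare(0.5, rep(0.5, 10), n_boot = 1000,
                                 seed = 1)$p, 1)
  # real value below every pseudo value: smallest attainable p
  out <- bootstrap_compare(-5, rnorm(10), n_boot = 1000, seed = 2)
  expect_lte(out$p, 2 / 1000)
  # shift invariance
  rs <- rnorm(10)
  p1 <- bootstrap_compare(0.2, rs, n_boot = 2000, seed = 3)$p
  p2 <- bootstrap_compare(0.2 + 7, rs + 7, n_boot = 2000, seed = 3)$p
  expect_equal(p1, p2)
  expect_error(bootstrap_compare(0, 1, n_boot = 10), class = "pl_invalid_input")
})

test_that("bootstrap p is central when the real value sits at the group mean", {
  # the procedure compares a single value against the bootstrap distribution
  # of the group MEAN, so it is only calibrated for central values; a value
  # equal to the group mean must yield a large two-sided p
  set.seed(50)
  ps <- vapply(1:200, function(i) {
    pseudo <- rnorm(10, sd = 0.3)
    bootstrap_compare(mean(pseudo), pseudo, n_boot = 400, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.8)
})

test_that("t-test tables carry Bonferroni correction and degeneracy flags", {
  a <- c(0.50, 0.52, 0.48, 0.55, 0.45, 0.51, 0.49, 0.53, 0.47, 0.50)
  # paired difference with mean 0.1 and sample sd 0.05: t = 0.1/(0.05/sqrt(10))
  diffs <- 0.1 + 0.05 * as.vector(scale(1:10))
  tt <- group_ttests(list(shift = list(a = a + diffs, b = a)),
                     design = "paired", n_comparisons = 2)
  expect_equal(tt$t, 0.1 / (0.05 / sqrt(10)), tolerance = 1e-10)
  expect_equal(tt$df, 9)
  expect_false(tt$degenerate)
  # identical paired groups are degenerate, not NaN
  td <- group_ttests(list(same = list(a = a, b = a)), design = "paired")
  expect_true(td$degenerate)
  # Bonferroni caps at 1
  set.seed(60)
  x <- rnorm(20); y <- rnorm(20)
  ti <- group_ttests(list(null = list(a = x, b = y)),
                     design = "independent", n_comparisons = 3)
  expect_equal(ti$p_bonferroni, min(1, ti$p_raw * 3))
  expect_error(group_ttests(list(bad = list(a = 1:3, b = 1:4)),
                            design = "paired"),
               class = "pl_incompatible_input")
})

test_that("hub set comparison computes set algebra and laterality chi-square", {
  nt <- generate_node_space(40, 2, seed = 6)
  cmp <- compare_hub_sets(c(1L, 2L), c(2L, 3L), nt)
  expect_equal(cmp$lost, 1L)
  expect_equal(cmp$new, 3L)
  expect_equal(cmp$shared, 2L)
  same <- compare_hub_sets(c(1L, 2L), c(1L, 2L), nt)
  expect_length(same$lost, 0)
  expect_length(same$new, 0)
  # 13 RH of 20 hubs: chi2 = 2 * 3^2 / 10 = 1.8
  rh <- nt$node_id[nt$hemisphere == "R"][1:13]
  lh <- nt$node_id[nt$hemisphere == "L"][1:7]
  cmp2 <- compare_hub_sets(integer(0), c(rh, lh), nt)
  expect_equal(cmp2$chi2_B, 1.8)
  expect_equal(cmp2$p_B, pchisq(1.8, 1, lower.tail = FALSE))
  expect_equal(cmp2$rh_fraction_B, 13 / 20)
  expect_error(compare_hub_sets(999L, 1L, nt), class = "pl_invalid_node")
})
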