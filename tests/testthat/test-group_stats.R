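test_that("the ABM statistic does median arithmetic correctly", {
  expect_equal(abm_statistic(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(abm_statistic(c(0, 0, 0, 10), c(1, 1, 1, 1)), 1)
  expect_equal(abm_statistic(2, 5), 3)
  expect_equal(abm_statistic(c(1, 2, NA), c(4, NA)), abs(1.5 - 4))
  expect_error(abm_statistic(NA_real_, 1), "non-empty")
})

test_that("exhaustive enumeration gives exact permutation p-values", {
  ex <- exhaustive_permutation_test(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_equal(ex$p, 2 / 6)
  expect_equal(ex$n_assignments, 6)
  expect_equal(exhaustive_permutation_test(rep(2, 6),
                                           rep(c("a", "b"), 3))$p, 1)
  expect_error(exhaustive_permutation_test(rnorm(14), rep(c("a", "b"), 7)),
               "enumeration bound")
})

test_that("Monte-Carlo permutation p agrees with the exhaustive oracle", {
  set.seed(10)
  fixtures <- list(
    list(v = c(0, 0, 1, 1), g = rep(c("a", "b"), each = 2)),
    list(v = rnorm(8), g = rep(c("a", "b"), each = 4)),
    list(v = c(1, 1, 2, 2, 3, 3, 4, 9), g = rep(c("a", "b"), 4)),
    list(v = rnorm(10), g = rep(c("a", "b"), c(6, 4)))
  )
  for (fx in fixtures) {
    ex <- exhaustive_permutation_test(fx$v, fx$g)
    mc <- permutation_test(fx$v, fx$g, n_permutations = 20000, seed = 77)
    se <- sqrt(ex$p * (1 - ex$p) / 20000)
    expect_lt(abs(mc$p - ex$p), max(3 * se, 2 / 20000))
  }
})

test_that("permutation test respects seed, tie rule and label symmetry", {
  set.seed(5)
  v <- rnorm(30); g <- rep(c("a", "b"), 15)
  p1 <- permutation_test(v, g, 2000, seed = 9)
  p2 <- permutation_test(v, g, 2000, seed = 9)
  expect_identical(p1$p, p2$p)

  # relabeling the groups changes nothing
  g2 <- ifelse(g == "a", "ctl", "dis")
  p3 <- permutation_test(v, g2, 2000, seed = 9)
  expect_identical(p1$p, p3$p)

  # degenerate data: every permuted ABM equals 0
  vc <- rep(1, 20); gc <- rep(c("a", "b"), 10)
  expect_equal(permutation_test(vc, gc, 500, seed = 1)$p, 1)
  expect_equal(permutation_test(vc, gc, 500, seed = 1,
                                tie_rule = "gt")$p, 0)

  expect_error(permutation_test(v, rep("a", 30), 100), "two group")
})

test_that("rank_sum_test matches exact enumeration on small samples", {
  expect_equal(rank_sum_test(1:3, 4:6), 0.1)
  expect_equal(rank_sum_test(2, 2), 1)
  # independent oracle: enumerate all C(n, n_a) rank splits of the pooled
  # sample and compute the two-sided rank-sum p directly
  enum_p <- function(a, b) {
    pool <- c(a, b); n <- length(pool); na <- length(a)
    r <- rank(pool)
    w_obs <- sum(r[seq_len(na)])
    ws <- apply(utils::combn(n, na), 2, function(ix) sum(r[ix]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu))
  }
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    expect_lt(abs(rank_sum_test(a, b) - enum_p(a, b)), 0.02)
  }
})

test_that("Fisher's method matches its closed forms", {
  f1 <- fisher_combine(rep(1, 4))
  expect_equal(f1$chi2, 0); expect_equal(f1$p, 1)
  # single p: chi-square with 2 dof identity exp(-X/2) = p
  for (p in c(0.9, 0.3, 0.012)) expect_equal(fisher_combine(p)$p, p)
  f2 <- fisher_combine(c(0.05, 0.05))
  x <- -2 * 2 * log(0.05)
  expect_equal(f2$chi2, x)
  expect_equal(f2$p, exp(-x / 2) * (1 + x / 2))  # chi^2_4 survival closed form
  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("Holm correction matches the step-down definition and its bounds", {
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.04), 0.04)
  expect_equal(holm_correct(rep(1, 5)), rep(1, 5))
  expect_equal(holm_correct(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    h <- holm_correct(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, length(p) * p)))  # never above Bonferroni
    o <- order(p)
    expect_true(!is.unsorted(h[o]))  # order-preserving on sorted p
  }
})

test_that("balanced bootstrap Fisher is deterministic and rank-discriminates", {
  set.seed(2)
  g <- rep(c("a", "b"), each = 40)
  v_null <- rnorm(80)
  v_eff <- c(rnorm(40), rnorm(40, mean = 2))
  b1 <- balanced_bootstrap_fisher(v_eff, g, n_samples = 50,
                                  size_per_group = 40, seed = 3)
  b2 <- balanced_bootstrap_fisher(v_eff, g, n_samples = 50,
                                  size_per_group = 40, seed = 3)
  expect_identical(b1$p_fisher, b2$p_fisher)
  expect_length(b1$p_samples, 50)

  # one resample reduces to Fisher of a single Wilcoxon p (identity)
  b3 <- balanced_bootstrap_fisher(v_null, g, n_samples = 1,
                                  size_per_group = 40, seed = 4)
  expect_equal(b3$p_fisher, b3$p_samples[1])

  # a large location shift must outrank a null feature nearly always
  wins <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    vn <- rnorm(80)
    ve <- c(rnorm(40), rnorm(40, mean = 1.5))
    pn <- balanced_bootstrap_fisher(vn, g, 30, 40, seed = 200 + r)$p_fisher
    pe <- balanced_bootstrap_fisher(ve, g, 30, 40, seed = 300 + r)$p_fisher
    wins <- wins + (pe < pn)
  }
  expect_gte(wins, 19)

  expect_error(
    balanced_bootstrap_fisher(v_null, g, 10, 50, replace = FALSE),
    "exceeds")
})

test_that("run_group_analysis corrects over the full feature family", {
  ft <- synthetic_feature_table(40, seed = 55)
  md <- simple_metadata(40)
  res <- run_group_analysis(ft, md, grouping = "group",
                            n_permutations = 200, seed = 6)
  expect_equal(nrow(res), 279)
  expect_equal(sum(res$quantifier == "A"), 93)
  expect_true(all(table(res$region) == 9))  # 9 features per region
  expect_true(all(res$p_holm >= res$p_raw - 1e-15))
  expect_identical(res$significant, !is.na(res$p_holm) & res$p_holm < 0.05)

  # permuting the subject rows leaves every output unchanged
  ft_shuf <- ft[sample(nrow(ft)), ]
  res2 <- run_group_analysis(ft_shuf, md, grouping = "group",
                             n_permutations = 200, seed = 6)
  expect_equal(res, res2)

  # column order must not matter either (per-feature substreams)
  ft_cols <- ft[, c(1, sample(2:ncol(ft)))]
  res3 <- run_group_analysis(ft_cols, md, grouping = "group",
                             n_permutations = 200, seed = 6)
  res3 <- res3[match(res$feature, res3$feature), ]
  expect_equal(res$p_raw, res3$p_raw)

  expect_error(run_group_analysis(ft, md, grouping = "site", 100), "binary")
})
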