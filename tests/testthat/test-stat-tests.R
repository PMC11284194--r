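test_that("categorical routing keys on the minimum expected cell count", {
  # [[2,12],[2,12]]: min expected = 4 * 14 / 28 = 2 < 5 -> Fisher
  a <- rep(c("yes", "no"), c(2, 12))
  b <- rep(c("yes", "no"), c(2, 12))
  routed <- choose_test(a, b, kind = "binary")
  expect_equal(routed$test, "fisher-exact")
  expect_equal(routed$trace$min_expected_cell, 2)
  # all expected cells >= 5 -> chi-square
  a2 <- rep(c("yes", "no"), c(7, 7))
  b2 <- rep(c("yes", "no"), c(6, 8))
  routed2 <- choose_test(a2, b2, kind = "binary")
  expect_equal(routed2$test, "chi-square")
  expect_gte(routed2$trace$min_expected_cell, 5)
})

test_that("metric routing screens normality per group, then variance homogeneity", {
  set.seed(101)
  heavy_a <- rlnorm(30, 0, 2)^2   # grossly non-normal
  heavy_b <- rlnorm(30, 0, 2)^2
  expect_equal(choose_test(heavy_a, heavy_b, kind = "metric")$test, "mann-whitney")
  norm_a <- rnorm(40, 10, 2); norm_b <- rnorm(40, 10, 2)
  routed <- choose_test(norm_a, norm_b, kind = "metric")
  expect_equal(routed$test, "t-test")
  expect_true(routed$trace$pooled)
  # grossly heteroscedastic normal groups route to Welch
  set.seed(102)
  wide_b <- rnorm(40, 10, 30)
  routed_w <- choose_test(rnorm(40, 10, 1), wide_b, kind = "metric")
  if (routed_w$test == "t-test") expect_false(routed_w$trace$pooled)
  # degenerate groups cannot be screened and count as non-normal
  expect_equal(choose_test(c(1, 1, 1), c(1, 2, 3, 4, 5), kind = "ordinal")$test,
               "mann-whitney")
  expect_error(choose_test(numeric(0), 1:3, kind = "metric"),
               class = "aneumatch_domain_error")
})

test_that("Fisher's exact p equals full margin-fixed enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 12, 12), 2))$p.value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p.value, 2 / 252)
  expect_warning(res0 <- fisher_exact_2x2(matrix(c(0, 0, 14, 14), 2)),
                 "zero margin", ignore.case = TRUE)
  expect_equal(res0$p.value, 1)
  # enumeration oracle across exhaustive small tables and random larger ones
  for (n in 2:7) {
    for (a in 0:n) for (b in 0:n) {
      tab <- matrix(c(a, b, n - a, n - b), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab)$p.value, oracle_fisher_p(tab),
                   tolerance = 1e-10)
    }
  }
  set.seed(111)
  for (i in 1:200) {
    n <- sample(16:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("Pearson chi-square uses no continuity correction and enforces routing", {
  res <- chi_square_2xc(matrix(c(10, 15, 10, 5), 2))
  expect_equal(res$statistic, 8 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # symmetry in the group rows
  res_swap <- chi_square_2xc(matrix(c(15, 10, 5, 10), 2))
  expect_equal(res_swap$statistic, res$statistic)
  # identical distributions: statistic 0, p 1
  res0 <- chi_square_2xc(matrix(c(7, 7, 7, 7), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_error(chi_square_2xc(matrix(c(2, 2, 12, 12), 2)),
               class = "aneumatch_routing_error")
})

test_that("Mann-Whitney U comes from rank sums and matches enumeration exactly", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney_u(c(1, 3, 5), c(2, 4, 6))$statistic, 3)
  res_sym <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_sym$p.value, 1)
  # exact p equals full labeling enumeration for tie-free samples, n <= 12
  set.seed(121)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    v <- sample(1:100, na + nb)      # distinct values, no ties
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    res <- mann_whitney_u(a, b)
    expect_true(res$exact)
    expect_equal(res$p.value, oracle_mwu_p(a, b), tolerance = 1e-10)
  }
  # ties or combined n > 20 switch to the corrected normal approximation
  expect_false(mann_whitney_u(c(1, 1, 2), c(2, 3, 4))$exact)
  expect_false(mann_whitney_u(rnorm(11), rnorm(10))$exact)
})

test_that("t-test handles pooled, Welch and degenerate variance cases", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  res <- t_test_groups(x, y, pooled = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  degen_eq <- t_test_groups(c(2, 2), c(2, 2))
  expect_equal(degen_eq$p.value, 1)
  expect_match(degen_eq$flag, "equal means")
  degen_ne <- t_test_groups(c(0, 0), c(1, 1))
  expect_equal(degen_ne$p.value, 0)
  expect_match(degen_ne$flag, "unequal means")
  # two-sided p agrees with an independent permutation oracle
  set.seed(131)
  a <- rnorm(14, 10, 2); b <- rnorm(14, 10.8, 2)
  p_t <- t_test_groups(a, b, pooled = TRUE)$p.value
  p_perm <- oracle_perm_t_p(a, b, n_perm = 10000)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("routing is a pure function of its inputs", {
  set.seed(141)
  a <- rlnorm(14); b <- rlnorm(14)
  r1 <- choose_test(a, b, kind = "metric")
  r2 <- choose_test(a, b, kind = "metric")
  expect_identical(r1, r2)
})
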