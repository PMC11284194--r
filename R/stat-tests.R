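#' Route a two-group comparison to its statistical test
#'
#' Implements the test-selection rules of the comparison engine:
#'
#' * binary / categorical variables — Pearson chi-square, unless any expected
#'   cell frequency (row total x column total / N) is below 5, in which case
#'   Fisher's exact test substitutes;
#' * ordinal / metric variables — each group is screened for normality with a
#'   Kolmogorov-Smirnov-type test (Lilliefors correction, since the mean and
#'   SD are estimated) at `alpha`; if either group is non-normal the
#'   Mann-Whitney U test is used, otherwise Levene's test (mean-centred)
#'   decides between the pooled t-test (Levene p >= `alpha`) and the
#'   unequal-variance Welch t-test.
#'
#' Groups with fewer than 4 observations or zero variance cannot be screened
#' and are routed as non-normal. The full routing trace (minimum expected
#' cell, per-group normality p, Levene p) is returned.
#'
#' @param a,b The two group samples. For `kind = "binary"`/`"categorical"`
#'   these are factors/character/logical vectors; otherwise numeric.
#' @param kind One of `"binary"`, `"categorical"`, `"ordinal"`, `"metric"`.
#' @param alpha Screening level for the normality and variance pre-tests.
#' @return A list: `test` (one of `"chi-square"`, `"fisher-exact"`,
#'   `"t-test"`, `"mann-whitney"`) and `trace` (named list of the routing
#'   quantities).
#' @export
choose_test <- function(a, b, kind = c("binary", "categorical", "ordinal", "metric"),
                        alpha = 0.05) {
  kind <- match.arg(kind)
  if (length(a) == 0 || length(b) == 0) {
    am_abort("Both groups must be non-empty.", "aneumatch_domain_error")
  }
  if (kind %in% c("binary", "categorical")) {
    tab <- two_group_table(a, b)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    min_exp <- min(expected)
    test <- if (min_exp < 5) "fisher-exact" else "chi-square"
    return(list(test = test, trace = list(min_expected_cell = min_exp)))
  }
  pa <- normality_p(a)
  pb <- normality_p(b)
  if (pa < alpha || pb < alpha) {
    return(list(test = "mann-whitney",
                trace = list(normality_p_a = pa, normality_p_b = pb,
                             levene_p = NA_real_)))
  }
  lev <- levene_p(a, b)
  list(
    test = "t-test",
    trace = list(normality_p_a = pa, normality_p_b = pb, levene_p = lev,
                 pooled = lev >= alpha)
  )
}

# stacked 2 x C contingency table, group rows first
two_group_table <- function(a, b) {
  x <- c(as.character(a), as.character(b))
  g <- rep(c("a", "b"), c(length(a), length(b)))
  table(group = g, value = x)
}

# Lilliefors-corrected KS normality p; degenerate samples count as non-normal
normality_p <- function(x) {
  if (length(x) < 4 || length(unique(x)) < 2) return(0)
  tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
}

levene_p <- function(a, b) {
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (sd(a) == 0 && sd(b) == 0) return(1)
  res <- car::leveneTest(y, g, center = mean)
  res[["Pr(>F)"]][1]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' whose point probability does not exceed that of the observed table. A
#' table with a zero margin is degenerate: the conditional distribution is a
#' point mass, so p = 1 (with a warning).
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return List with `p.value`, `estimate` (the conditional odds ratio, `NA`
#'   for degenerate tables) and `method`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)) # p = 2/252
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_count_table(tab, square2 = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::warn("Degenerate 2x2 table (zero margin); p = 1.")
    return(list(p.value = 1, estimate = NA_real_, method = "fisher-exact"))
  }
  ft <- stats::fisher.test(tab)
  list(p.value = ft$p.value, estimate = unname(ft$estimate), method = "fisher-exact")
}

#' Pearson chi-square test for a 2xC table
#'
#' Pearson's statistic `sum (O - E)^2 / E` against the chi-square
#' distribution on `(r - 1)(c - 1)` degrees of freedom, without continuity
#' correction. The routing contract requires all expected cells to be at
#' least 5; violating tables are an error (route them to
#' [fisher_exact_2x2()] instead).
#'
#' @param tab A 2xC matrix of non-negative integer counts.
#' @return List with `statistic`, `p.value`, `df` and `method`.
#' @export
chi_square_2xc <- function(tab) {
  tab <- check_count_table(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < 5) {
    am_abort(
      sprintf("Expected cell count %.2f < 5: chi-square routing violated; use Fisher's exact test.",
              min(expected)),
      "aneumatch_routing_error"
    )
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       df = unname(ct$parameter), method = "chi-square")
}

check_count_table <- function(tab, square2 = FALSE) {
  tab <- as.matrix(tab)
  if (square2 && !all(dim(tab) == c(2, 2))) {
    am_abort("Expected a 2x2 table.", "aneumatch_domain_error")
  }
  if (nrow(tab) != 2) {
    am_abort("Expected a table with 2 group rows.", "aneumatch_domain_error")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    am_abort("Table entries must be non-negative integers.", "aneumatch_domain_error")
  }
  tab
}

#' Mann-Whitney U test
#'
#' The U statistic for the first group, computed from midrank sums
#' (`U = R_a - n_a (n_a + 1) / 2`). The two-sided p-value is exact when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b Numeric group samples (each non-empty).
#' @return List with `statistic` (U for group `a`), `p.value`, `exact`
#'   (logical) and `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    am_abort("Both groups must be non-empty.", "aneumatch_domain_error")
  }
  na <- length(a)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (na + length(b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = u, p.value = wt$p.value, exact = exact, method = "mann-whitney")
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param a,b Numeric group samples, each with at least 2 observations.
#' @param pooled Use the pooled-variance statistic (TRUE) or the Welch
#'   unequal-variance statistic (FALSE).
#' @return List with `statistic`, `p.value`, `df`, `method` and `flag`
#'   (notes for degenerate inputs). Zero variance in both groups gives
#'   p = 1 when the means are equal (no evidence either way from constant
#'   data) and p = 0 with a flag when they differ.
#' @export
t_test_groups <- function(a, b, pooled = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    am_abort("Each group needs at least 2 observations.", "aneumatch_domain_error")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p.value = 1, df = NA_real_,
                  method = "t-test", flag = "zero variance, equal means"))
    }
    return(list(statistic = Inf, p.value = 0, df = NA_real_,
                method = "t-test", flag = "zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter),
       method = if (pooled) "t-test" else "t-test (Welch)", flag = NA_character_)
}
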