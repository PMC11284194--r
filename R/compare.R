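#' Variable registries for baseline and outcome comparisons
#'
#' `baseline_variables()` lists the matching covariates and descriptors of
#' the baseline-balance table (gender, age, medical history, rupture status,
#' aneurysm multiplicity, size, irregularity, plus Hunt & Hess score and
#' Fisher grade restricted to ruptured cases). `outcome_variables()` lists
#' the primary outcomes — degree of occlusion (complete/incomplete) and
#' modified Rankin Scale at discharge — and the secondary outcomes
#' (temporary clipping, intraoperative rupture, postoperative stroke and
#' hemorrhage, hydrocephalus, ventriculoperitoneal shunt, vasospasm).
#'
#' @return A tibble with columns `name`, `kind`, `role` and `ruptured_only`.
#' @export
baseline_variables <- function() {
  tibble(
    name = c(
      "gender", "age", "hypertension", "diabetes",
      "peripheral_arterial_disease", "heart_disease", "ischemic_stroke",
      "thrombosis", "obesity", "nicotine_abuse", "alcohol_abuse",
      "ruptured", "multiple_aneurysms", "size_mm", "shape",
      "hunt_hess", "fisher_grade"
    ),
    kind = c(
      "binary", "metric", rep("binary", 9), "binary", "binary",
      "metric", "binary", "ordinal", "ordinal"
    ),
    role = c(
      "matching covariate", "matching covariate", rep("descriptor", 9),
      "descriptor", "descriptor", "matching covariate", "matching covariate",
      "matching covariate", "matching covariate"
    ),
    ruptured_only = c(rep(FALSE, 15), TRUE, TRUE)
  )
}

#' @rdname baseline_variables
#' @export
outcome_variables <- function() {
  tibble(
    name = c(
      "occlusion_complete", "mrs_discharge", "temporary_clipping",
      "intraoperative_rupture", "postoperative_stroke",
      "postoperative_hemorrhage", "hydrocephalus", "vp_shunt", "vasospasm"
    ),
    kind = c("binary", "ordinal", rep("binary", 7)),
    role = c("primary outcome", "primary outcome", rep("secondary outcome", 7)),
    ruptured_only = FALSE
  )
}

#' Format and parse "count (percent)" summaries
#'
#' Percentages are `100 * count / n` rounded to one decimal; whole-number
#' percentages are printed without a decimal (so 7/14 renders as
#' `"7 (50%)"`, 5/14 as `"5 (35.7%)"`).
#'
#' @param count Integer count(s) of positives.
#' @param n Arm size(s).
#' @return `format_count_percent()`: a character vector.
#' @examples
#' format_count_percent(c(5, 6, 4, 7), 14)
#' @export
format_count_percent <- function(count, n) {
  pct <- round(100 * count / n, 1)
  ifelse(
    pct == round(pct),
    sprintf("%d (%d%%)", count, round(pct)),
    sprintf("%d (%.1f%%)", count, pct)
  )
}

#' @rdname format_count_percent
#' @param x Character vector of `"count (percent%)"` strings.
#' @return `parse_count_percent()`: a tibble with `count` and `percent`.
#' @export
parse_count_percent <- function(x) {
  m <- stringr::str_match(x, "^(\\d+) \\((\\d+(?:\\.\\d+)?)%\\)$")
  if (anyNA(m[, 1])) {
    am_abort(sprintf("Cannot parse summary string: %s", x[is.na(m[, 1])][1]),
             "aneumatch_domain_error")
  }
  tibble(count = as.integer(m[, 2]), percent = as.numeric(m[, 3]))
}

# positive level of a two-level character variable under the codebook,
# falling back to the alphabetically larger level
positive_level <- function(name, x) {
  cb <- binary_codebook()[[name]]
  if (!is.null(cb)) return(names(cb)[cb == 1])
  u <- sort(unique(as.character(x)))
  u[length(u)]
}

binary_count <- function(name, x) {
  if (is.logical(x)) sum(x) else sum(x == positive_level(name, x))
}

#' Compare one variable between the two arms
#'
#' Routes the variable through [choose_test()] and runs the selected test.
#' A variable whose pooled sample is constant (e.g. zero positives in both
#' arms, or an outcome identical everywhere) carries no contrast; its test is
#' skipped and marked with an em-dash, mirroring how such rows are reported
#' in baseline tables.
#'
#' @param data Case table containing both arms.
#' @param name Variable (column) name.
#' @param kind `"binary"`, `"categorical"`, `"ordinal"` or `"metric"`.
#' @param arm_col Arm column (default `"arm"`); the AOI arm is the level
#'   `aoi_arm`, all other rows form the reference group.
#' @param aoi_arm AOI arm label (default `"AIA"`).
#' @param alpha Routing level for the normality/variance pre-tests.
#' @return A one-row tibble (`variable`, `kind`, `summary_aoi`,
#'   `summary_ref`, `test`, `statistic`, `p_value`, routing-trace columns,
#'   `direction`).
#' @export
compare_variable <- function(data, name, kind, arm_col = "arm",
                             aoi_arm = "AIA", alpha = 0.05) {
  if (!name %in% names(data)) {
    am_abort(sprintf("Variable `%s` absent from data.", name),
             "aneumatch_schema_error")
  }
  x <- data[[name]]
  is_aoi <- data[[arm_col]] == aoi_arm
  a <- x[is_aoi & !is.na(x)]
  b <- x[!is_aoi & !is.na(x)]
  if (length(a) == 0 || length(b) == 0) {
    am_abort(sprintf("Variable `%s` has an empty arm.", name),
             "aneumatch_domain_error")
  }

  row <- tibble(
    variable = name, kind = kind,
    summary_aoi = NA_character_, summary_ref = NA_character_,
    test = "—", statistic = NA_real_, p_value = NA_real_,
    min_expected_cell = NA_real_, normality_p_aoi = NA_real_,
    normality_p_ref = NA_real_, levene_p = NA_real_,
    direction = NA_character_
  )

  if (kind %in% c("binary", "categorical")) {
    ca <- binary_count(name, a); cb <- binary_count(name, b)
    row$summary_aoi <- format_count_percent(ca, length(a))
    row$summary_ref <- format_count_percent(cb, length(b))
    pa <- ca / length(a); pb <- cb / length(b)
    row$direction <- if (pa == pb) "equal" else
      if (pa < pb) "lower in AOI arm" else "higher in AOI arm"
  } else {
    loc <- if (kind == "ordinal") function(v) median(v) else function(v) mean(v)
    lab <- if (kind == "ordinal") "median" else "mean"
    row$summary_aoi <- sprintf("%s %.3g", lab, loc(a))
    row$summary_ref <- sprintf("%s %.3g", lab, loc(b))
    row$direction <- if (loc(a) == loc(b)) "equal" else
      if (loc(a) < loc(b)) "lower in AOI arm" else "higher in AOI arm"
  }

  # a pooled-constant variable offers no contrast: test skipped ("-")
  if (length(unique(c(a, b))) < 2) return(row)

  routed <- choose_test(a, b, kind = kind, alpha = alpha)
  row$test <- routed$test
  tr <- routed$trace
  row$min_expected_cell <- tr$min_expected_cell %||% NA_real_
  row$normality_p_aoi <- tr$normality_p_a %||% NA_real_
  row$normality_p_ref <- tr$normality_p_b %||% NA_real_
  row$levene_p <- tr$levene_p %||% NA_real_

  res <- switch(routed$test,
    "chi-square" = chi_square_2xc(two_group_table(a, b)),
    "fisher-exact" = suppressWarnings(fisher_exact_2x2(two_group_table(a, b))),
    "mann-whitney" = mann_whitney_u(as.numeric(a), as.numeric(b)),
    "t-test" = t_test_groups(as.numeric(a), as.numeric(b),
                             pooled = isTRUE(tr$pooled))
  )
  row$statistic <- res$statistic %||% NA_real_
  row$p_value <- res$p.value
  row
}

#' Baseline-balance table for a matched cohort
#'
#' One row per baseline variable comparing the two arms: count (percent)
#' summaries for binary variables, mean/median for metric/ordinal ones, the
#' routed test and its p-value. Hunt & Hess and Fisher grades are compared
#' within ruptured cases only. In a well-matched cohort no matching covariate
#' should differ significantly.
#'
#' @param data Case table of the matched cohort (both arms); see
#'   [matched_cases()] to extract it from a matching result.
#' @param variables Variable registry (default [baseline_variables()]);
#'   rows whose `name` is absent from `data` error.
#' @param correction Multiple-testing correction across rows: `"none"`
#'   (default, per-variable p-values as commonly presented) or `"holm"`
#'   (adds a `p_adjusted` column).
#' @inheritParams compare_variable
#' @return An `aneumatch_comparison` tibble, one row per variable.
#' @export
baseline_table <- function(data, variables = baseline_variables(),
                           arm_col = "arm", aoi_arm = "AIA", alpha = 0.05,
                           correction = c("none", "holm")) {
  correction <- match.arg(correction)
  comparison_table(data, variables, arm_col, aoi_arm, alpha, correction)
}

#' Primary and secondary outcome analysis
#'
#' Compares the primary outcomes — occlusion (binary) and mRS at discharge
#' (ordinal, routed through normality screening to Mann-Whitney or t) — and
#' each binary secondary outcome between the arms, reporting the test,
#' statistic, p-value and direction of effect.
#'
#' @inheritParams baseline_table
#' @param variables Variable registry (default [outcome_variables()]).
#' @return An `aneumatch_comparison` tibble with a `role` column.
#' @export
outcome_analysis <- function(data, variables = outcome_variables(),
                             arm_col = "arm", aoi_arm = "AIA", alpha = 0.05,
                             correction = c("none", "holm")) {
  correction <- match.arg(correction)
  comparison_table(data, variables, arm_col, aoi_arm, alpha, correction)
}

comparison_table <- function(data, variables, arm_col, aoi_arm, alpha, correction) {
  rows <- map(seq_len(nrow(variables)), function(i) {
    v <- variables[i, ]
    d <- data
    if (isTRUE(v$ruptured_only)) d <- filter(d, .data$ruptured)
    out <- compare_variable(d, v$name, v$kind, arm_col, aoi_arm, alpha)
    out$role <- v$role %||% NA_character_
    out
  })
  tbl <- list_rbind(rows) |> relocate("role", .after = "kind")
  if (correction == "holm") tbl$p_adjusted <- stats::p.adjust(tbl$p_value, "holm")
  structure(tbl, alpha = alpha,
            class = c("aneumatch_comparison", class(tbl)))
}

#' Extract the matched case table from a matching result
#'
#' Subsets the original case table to the matched pairs (each AOI and its
#' assigned reference), so it can flow into [baseline_table()] and
#' [outcome_analysis()].
#'
#' @param match A `matched_cohort` from [sequential_match()].
#' @param cases The case table the match was built from.
#' @return A case table of `2 * n_pairs` rows.
#' @export
matched_cases <- function(match, cases) {
  ids <- c(match$pairs$aoi_id, match$pairs$reference_id)
  filter(cases, .data$id %in% ids)
}
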