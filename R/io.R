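#' Canonical case-table schema
#'
#' Column registry of the interchange CSV: one row per column with its kind,
#' whether it is required, and the validation rule applied on read. The
#' dialect is fixed: UTF-8, comma-delimited, `.` decimal separator, empty
#' fields for missing optional values. Matching features must be non-missing
#' for matchable cases; descriptors and outcomes may be missing.
#'
#' @return A tibble with columns `name`, `kind`, `required`, `rule`.
#' @export
case_table_schema <- function() {
  covs <- names(default_covariate_prevalences())
  outs <- setdiff(outcome_variables()$name, "mrs_discharge")
  tibble(
    name = c(
      "id", "arm", "gender", "age", "ruptured", "hunt_hess", "fisher_grade",
      "size_mm", "shape", "width_mm", "height_mm", "neck_mm", "d1_mm",
      "d2_mm", "hmax_mm", "vessel_angle", "inclination_angle", "fda_angle",
      "bleb", covs, outs, "mrs_discharge", "sr", "ar", "fda_category"
    ),
    kind = c(
      "character", "character", "binary", "continuous", "logical",
      "ordinal", "ordinal", "continuous", "binary", rep("continuous", 6),
      "continuous", "continuous", "continuous", "logical",
      rep("logical", length(covs)), rep("logical", length(outs)),
      "ordinal", "continuous", "continuous", "ordinal"
    ),
    required = c(
      TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
      rep(FALSE, 6), FALSE, FALSE, TRUE, FALSE,
      rep(FALSE, length(covs)), rep(FALSE, length(outs)),
      FALSE, FALSE, FALSE, FALSE
    ),
    rule = c(
      "unique", "one of AIA|PA", "one of male|female", "in [18, 120]",
      "logical", "integer in 1-5", "integer in 1-4", "> 0",
      "one of regular|irregular", rep("> 0", 6), "in [0, 360]",
      "in [0, 360]", "in [0, 360)", "logical",
      rep("logical", length(covs)), rep("logical", length(outs)),
      "integer in 0-6", "> 0", "> 0", "integer in 1-4"
    )
  )
}

#' Read and validate a case-table CSV
#'
#' Reads the canonical comma-delimited case table (UTF-8, `.` decimals,
#' `#`-prefixed provenance headers skipped) and validates it against
#' [case_table_schema()]: required columns present, ids unique, enumerations
#' and ranges respected. Violations error with the offending row, column and
#' value.
#'
#' @param path Path to a CSV file.
#' @return A validated case-table tibble.
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) {
    am_abort(sprintf("File not found: %s", path), "aneumatch_io_error")
  }
  schema <- case_table_schema()
  types <- setNames(
    lapply(schema$kind, function(k) switch(k,
      character = , binary = readr::col_character(),
      logical = readr::col_logical(),
      ordinal = readr::col_integer(),
      continuous = readr::col_double()
    )),
    schema$name
  )
  hdr <- names(readr::read_csv(path, comment = "#", n_max = 0,
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE))
  types <- types[intersect(names(types), hdr)]
  df <- readr::read_csv(
    path, comment = "#", na = "",
    col_types = do.call(readr::cols, c(types, list(.default = readr::col_guess()))),
    progress = FALSE
  )
  validate_case_table(df)
}

#' @rdname read_case_table
#' @param cases A case table (already in memory).
#' @export
validate_case_table <- function(cases) {
  schema <- case_table_schema()
  missing_req <- setdiff(schema$name[schema$required], names(cases))
  if (length(missing_req)) {
    am_abort(paste0("Missing required column(s): ",
                    paste(missing_req, collapse = ", ")),
             "aneumatch_schema_error")
  }
  if (anyDuplicated(cases$id)) {
    am_abort(paste0("Duplicate case id: ", cases$id[duplicated(cases$id)][1]),
             "aneumatch_schema_error")
  }
  fail <- function(col, bad_rows, why) {
    r <- bad_rows[1]
    am_abort(
      sprintf("Column `%s` row %d: value `%s` %s.", col, r,
              as.character(cases[[col]][r]), why),
      "aneumatch_validation_error"
    )
  }
  check_range <- function(col, lo, hi, integer = FALSE, hi_open = FALSE) {
    if (!col %in% names(cases)) return(invisible())
    x <- cases[[col]]
    ok <- is.na(x) | (x >= lo & (if (hi_open) x < hi else x <= hi) &
                        (!integer | x == round(x)))
    if (!all(ok)) {
      fail(col, which(!ok),
           sprintf("outside %s%g, %g%s", if (integer) "integer range [" else "[",
                   lo, hi, if (hi_open) ")" else "]"))
    }
  }
  check_levels <- function(col, levels) {
    if (!col %in% names(cases)) return(invisible())
    x <- cases[[col]]
    ok <- is.na(x) | x %in% levels
    if (!all(ok)) fail(col, which(!ok),
                       paste0("not one of ", paste(levels, collapse = "|")))
  }
  check_levels("arm", c("AIA", "PA"))
  check_levels("gender", c("male", "female"))
  check_levels("shape", c("regular", "irregular"))
  check_range("age", 18, 120)
  check_range("hunt_hess", 1, 5, integer = TRUE)
  check_range("fisher_grade", 1, 4, integer = TRUE)
  check_range("mrs_discharge", 0, 6, integer = TRUE)
  check_range("fda_category", 1, 4, integer = TRUE)
  check_range("fda_angle", 0, 360, hi_open = TRUE)
  for (col in c("size_mm", "width_mm", "height_mm", "neck_mm", "d1_mm",
                "d2_mm", "hmax_mm", "sr", "ar")) {
    if (!col %in% names(cases)) next
    x <- cases[[col]]
    ok <- is.na(x) | x > 0
    if (!all(ok)) fail(col, which(!ok), "must be > 0")
  }
  as_tibble(cases)
}

#' Write a case table or result table as canonical CSV
#'
#' @param x A tibble.
#' @param path Output path.
#' @param seed,config_hash Optional provenance recorded in `#`-prefixed
#'   header lines (skipped on read).
#' @return `path`, invisibly.
#' @export
write_case_table <- function(x, path, seed = NULL, config_hash = NULL) {
  hdr <- provenance_header(seed, config_hash)
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

provenance_header <- function(seed = NULL, config_hash = NULL) {
  c(
    sprintf("# aneumatch %s", as.character(utils::packageVersion("aneumatch"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config_hash)) sprintf("# config: %s", config_hash)
  )
}

# order-stable hash of a config list, for provenance headers; file-system
# paths are excluded so reruns in different directories hash identically
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("input", "output_dir"))]
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # small polynomial rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435456
  sprintf("%07x", h)
}

#' Write the full report bundle of a pipeline run
#'
#' Emits machine-readable CSVs (matched pairs, adjudication log, distance
#' matrix, baseline table, outcome report) plus a plain-text summary, every
#' file carrying provenance headers (tool version, seed, config hash).
#'
#' @param results A list as produced by [run_pipeline()] (fields `match`,
#'   `baseline`, `outcomes`, `config`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- results$config$seed
  h <- config_hash(results$config)
  out <- c(
    pairs = "pairs.csv", log = "adjudication_log.csv",
    distances = "distance_matrix.csv", baseline = "baseline_table.csv",
    outcomes = "outcome_report.csv", summary = "summary.txt"
  )
  paths <- file.path(dir, out)
  names(paths) <- names(out)
  write_case_table(results$match$pairs, paths["pairs"], seed, h)
  write_case_table(results$match$log, paths["log"], seed, h)
  write_case_table(results$match$distances, paths["distances"], seed, h)
  strip <- function(tb) as_tibble(as.data.frame(tb))
  write_case_table(strip(results$baseline), paths["baseline"], seed, h)
  write_case_table(strip(results$outcomes), paths["outcomes"], seed, h)

  g <- glance(results$match)
  txt <- c(
    provenance_header(seed, h),
    "",
    sprintf("Matched pairs: %d (one per AOI)", g$n_pairs),
    sprintf("Conflicts adjudicated: %d", g$n_conflicts),
    sprintf("Stratum merges: %d", g$n_merges),
    sprintf("Mean pair distance: %.4f", g$mean_distance),
    "",
    "Baseline balance (variable: AOI arm | reference arm | test | p):",
    sprintf("  %-28s %-14s %-14s %-12s %s",
            results$baseline$variable, results$baseline$summary_aoi,
            results$baseline$summary_ref, results$baseline$test,
            ifelse(is.na(results$baseline$p_value), "—",
                   sprintf("p = %.3f", results$baseline$p_value))),
    "",
    "Outcomes:",
    sprintf("  %-28s %-14s %-14s %-12s %s",
            results$outcomes$variable, results$outcomes$summary_aoi,
            results$outcomes$summary_ref, results$outcomes$test,
            ifelse(is.na(results$outcomes$p_value), "—",
                   sprintf("p = %.3f", results$outcomes$p_value)))
  )
  writeLines(txt, paths["summary"])
  invisible(paths)
}
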