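#' Build a matching feature specification
#'
#' A feature spec is a tibble with one row per matching feature (`name`,
#' `kind`, `weight`) and a neighbour count `k` carried as an attribute. Kinds
#' are `binary` (0/1-encoded), `ordinal` (integer grade passed through) and
#' `continuous`. Weights are the `fw_l` multipliers of the weighted Euclidean
#' dissimilarity; the default is 1 for every feature.
#'
#' @param features Data frame or tibble with columns `name`, `kind` and
#'   optionally `weight`.
#' @param k Neighbour count for k-NN retrieval (default 3).
#' @return A `feature_spec` tibble.
#' @export
feature_spec <- function(features, k = 3L) {
  features <- as_tibble(features)
  if (!all(c("name", "kind") %in% names(features))) {
    am_abort("`features` needs `name` and `kind` columns.", "aneumatch_config_error")
  }
  if (!"weight" %in% names(features)) features$weight <- 1
  if (anyDuplicated(features$name)) {
    am_abort("Feature names must be unique.", "aneumatch_config_error")
  }
  bad_kind <- setdiff(features$kind, c("binary", "ordinal", "continuous"))
  if (length(bad_kind)) {
    am_abort(paste0("Unknown feature kind: ", bad_kind[1]), "aneumatch_config_error")
  }
  if (any(features$weight < 0)) {
    am_abort("Feature weights must be >= 0.", "aneumatch_config_error")
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    am_abort("`k` must be an integer >= 1.", "aneumatch_config_error")
  }
  structure(features[c("name", "kind", "weight")],
            k = as.integer(k),
            class = c("feature_spec", class(features)))
}

#' @rdname feature_spec
#' @param spec A `feature_spec`.
#' @export
spec_k <- function(spec) attr(spec, "k")

#' Matching feature sets for ruptured and unruptured cases
#'
#' Unruptured aneurysms are matched on gender, age at surgery, aneurysm shape
#' and aneurysm size (4 features). Ruptured aneurysms additionally use the
#' Hunt & Hess score and the Fisher grade (6 features). All weights default
#' to 1 and `k = 3`.
#'
#' @param ruptured Logical flag selecting the ruptured feature set.
#' @param k Neighbour count (default 3).
#' @return A [feature_spec()].
#' @examples
#' select_matching_features(ruptured = TRUE)
#' @export
select_matching_features <- function(ruptured, k = 3L) {
  base <- tibble(
    name = c("gender", "age", "shape", "size_mm"),
    kind = c("binary", "continuous", "binary", "continuous")
  )
  if (isTRUE(ruptured)) {
    base <- bind_rows(
      base[1:2, ],
      tibble(name = c("hunt_hess", "fisher_grade"), kind = "ordinal"),
      base[3:4, ]
    )
  }
  feature_spec(base, k = k)
}

# documented codebook for 0/1 encodings of the canonical schema
binary_codebook <- function() {
  list(
    gender = c(male = 0, female = 1),
    shape = c(regular = 0, irregular = 1)
  )
}

#' Encode matching features as a numeric matrix
#'
#' Binary features are 0/1-encoded under the package codebook (gender:
#' male = 0, female = 1; shape: regular = 0, irregular = 1; logical columns:
#' FALSE = 0, TRUE = 1), ordinal grades enter as their integer level, and
#' continuous features pass through unchanged. Row order is preserved and row
#' names are the case ids. A missing value or unknown category is an error
#' naming the case and feature.
#'
#' @param cases A case table.
#' @param spec A [feature_spec()].
#' @return A numeric matrix, rows = cases (named by id), columns = features
#'   in spec order.
#' @export
encode_features <- function(cases, spec) {
  missing_cols <- setdiff(spec$name, names(cases))
  if (length(missing_cols)) {
    am_abort(paste0("Case table lacks matching feature(s): ",
                    paste(missing_cols, collapse = ", ")),
             "aneumatch_schema_error")
  }
  cb <- binary_codebook()
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    nm <- spec$name[i]
    x <- cases[[nm]]
    if (anyNA(x)) {
      bad <- cases$id[which(is.na(x))[1]]
      am_abort(sprintf("Missing value for feature `%s` in case `%s`.", nm, bad),
               "aneumatch_missing_error")
    }
    if (spec$kind[i] == "binary") {
      if (is.logical(x)) return(as.numeric(x))
      if (!is.null(cb[[nm]])) {
        unknown <- setdiff(unique(x), names(cb[[nm]]))
        if (length(unknown)) {
          am_abort(sprintf("Unknown category `%s` for feature `%s`.",
                           unknown[1], nm), "aneumatch_schema_error")
        }
        return(unname(cb[[nm]][x]))
      }
      u <- sort(unique(x))
      if (length(u) > 2) {
        am_abort(sprintf("Binary feature `%s` has >2 levels.", nm),
                 "aneumatch_schema_error")
      }
      return(as.numeric(x == u[length(u)]))
    }
    as.numeric(x)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(cases$id, spec$name)
  m
}

#' Z-score standardization of a feature matrix
#'
#' Each column is centred on its mean and divided by its standard deviation
#' (denominator `n - 1`). Constant columns cannot be scaled; they are mapped
#' to all-zero, flagged in the `constant` attribute, and a warning is issued —
#' in small matching strata a constant covariate (e.g. all-female) is common
#' and simply carries no matching information. Standardization of a single
#' row is undefined and errors.
#'
#' @param m Numeric matrix (rows = cases, columns = features).
#' @return A `standardized_matrix`: the standardized matrix with attributes
#'   `center`, `scale` (per-column mean/SD used) and `constant` (logical flag
#'   per column).
#' @export
zscore_standardize <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 2) {
    am_abort("Z-score standardization needs at least 2 rows.",
             "aneumatch_domain_error")
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  constant <- scl == 0 | is.na(scl)
  if (any(constant)) {
    rlang::warn(paste0("Constant feature column(s) mapped to zero: ",
                       paste(colnames(m)[constant], collapse = ", ")))
    scl[constant] <- 1
    ctr[constant] <- m[1, constant]
  }
  z <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  structure(z, center = ctr, scale = scl, constant = constant,
            class = c("standardized_matrix", class(z)))
}
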