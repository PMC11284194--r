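#' Size ratio of an aneurysm
#'
#' The size ratio (SR) is the maximum aneurysm height divided by the average
#' parent-vessel diameter: `SR = Hmax / ((D1 + D2) / 2)`. `D1` is the vessel
#' diameter at the proximal neck and `D2` the diameter measured `1.5 * D1`
#' upstream. SR is dimensionless and invariant to a common rescaling of all
#' three lengths.
#'
#' @param hmax Maximum distance of the dome from the middle of the neck (mm).
#' @param d1 Parent-vessel diameter at the proximal neck (mm).
#' @param d2 Parent-vessel diameter 1.5 x `d1` upstream (mm).
#' @return Numeric vector of size ratios.
#' @examples
#' size_ratio(5, 2, 3) # 2
#' @export
size_ratio <- function(hmax, d1, d2) {
  check_positive_lengths(hmax = hmax, d1 = d1, d2 = d2)
  hmax / ((d1 + d2) / 2)
}

#' Aspect ratio of an aneurysm
#'
#' The aspect ratio (AR) is the maximum perpendicular dome height divided by
#' the average neck diameter: `AR = H / D`.
#'
#' @param h Maximum perpendicular distance of the dome from the neck plane (mm).
#' @param d Neck diameter: twice the average centroid-to-edge distance (mm).
#' @return Numeric vector of aspect ratios.
#' @examples
#' aspect_ratio(4, 2) # 2
#' @export
aspect_ratio <- function(h, d) {
  check_positive_lengths(h = h, d = d)
  h / d
}

check_positive_lengths <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x)) {
      am_abort(sprintf("`%s` must be numeric.", nm), "aneumatch_domain_error")
    }
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      am_abort(
        sprintf("`%s` must be > 0 (offending value: %g).", nm, x[bad][1]),
        "aneumatch_domain_error"
      )
    }
  }
  invisible(NULL)
}

#' Classify the frontal base-dome-angle into quadrant categories
#'
#' The frontal base-dome-angle (FDA) is measured on sagittal imaging between a
#' baseline parallel to the frontal skull base and the aneurysm's
#' maximum-height axis, with 0 degrees ventral to the aneurysm and a full
#' 360-degree circular path. Angles are binned into four quadrant categories:
#' category 1 covers `[0, 90]`, category 2 `(90, 180]`, category 3
#' `(180, 270]`, category 4 `(270, 360]`. Boundary angles belong to the lower
#' category (90 is category 1); 360 is accepted as the top of category 4 and
#' is not wrapped to 0.
#'
#' @param angle Numeric vector of angles in degrees, each in `[0, 360]`.
#' @return Integer vector of categories in `1:4`.
#' @examples
#' classify_fda(c(0, 45, 90, 135, 225, 300, 360)) # 1 1 1 2 3 4 4
#' @export
classify_fda <- function(angle) {
  if (!is.numeric(angle)) {
    am_abort("`angle` must be numeric.", "aneumatch_domain_error")
  }
  out_of_range <- !is.na(angle) & (angle < 0 | angle > 360)
  if (any(out_of_range)) {
    am_abort(
      sprintf(
        "FDA angle must lie in [0, 360] degrees (offending value: %g).",
        angle[out_of_range][1]
      ),
      "aneumatch_domain_error"
    )
  }
  as.integer(pmin(pmax(ceiling(angle / 90), 1L), 4L))
}

#' Append derived morphometrics to a case table
#'
#' Adds the size ratio (`sr`), aspect ratio (`ar`) and FDA quadrant category
#' (`fda_category`) columns, computed from the raw measurement columns
#' `hmax_mm`, `d1_mm`, `d2_mm`, `height_mm`, `neck_mm` and `fda_angle`.
#' Existing derived columns are recomputed.
#'
#' @param cases A case table (one row per aneurysm case).
#' @return The case table with `sr`, `ar` and `fda_category` columns appended.
#' @export
derive_morphometrics <- function(cases) {
  needed <- c("hmax_mm", "d1_mm", "d2_mm", "height_mm", "neck_mm", "fda_angle")
  missing_cols <- setdiff(needed, names(cases))
  if (length(missing_cols)) {
    am_abort(
      paste0("Missing measurement columns: ", paste(missing_cols, collapse = ", ")),
      "aneumatch_schema_error"
    )
  }
  cases |>
    mutate(
      sr = size_ratio(.data$hmax_mm, .data$d1_mm, .data$d2_mm),
      ar = aspect_ratio(.data$height_mm, .data$neck_mm),
      fda_category = classify_fda(.data$fda_angle)
    )
}
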