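#' Configuration for a synthetic aneurysm cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults emulate the structure of a two-arm surgical series of anterior
#' communicating artery aneurysms: a small interhemispheric-approach arm
#' ("AIA", the aneurysms of interest) against a larger pterional-approach
#' reference arm ("PA"), with a ~50% rupture rate, mostly female patients,
#' log-normal aneurysm size and uniform dome angulation.
#'
#' @param n_aoi Number of cases in the AOI ("AIA") arm. Default 14.
#' @param n_reference Number of reference ("PA") candidates. Default 36.
#' @param rupture_rate Probability that a case is ruptured. Default 0.5.
#' @param age_mean,age_sd Mean and SD (years) of the age distribution, a
#'   normal truncated to `[18, 95]`.
#' @param size_log_mean,size_log_sd Log-scale mean and SD of the log-normal
#'   aneurysm size (mm). Defaults give a 7 mm median.
#' @param gender_female_prob Probability a case is female. Default 12/14.
#' @param shape_irregular_prob Probability of irregular aneurysm shape.
#' @param covariate_prevalences Named numeric vector of binary-covariate
#'   prevalences (probabilities in `[0, 1]`).
#' @param outcome_effects Named list; each element a length-2 numeric vector
#'   `c(aoi, reference)` of Bernoulli outcome probabilities per arm. Defaults
#'   are equal across arms (no treatment effect).
#' @param hunt_hess_probs Probability masses for Hunt & Hess grades 1-5
#'   (ruptured cases only).
#' @param fisher_grade_probs Probability masses for Fisher grades 1-4
#'   (ruptured cases only).
#' @param mrs_probs Probability masses for modified Rankin Scale scores 0-6
#'   at discharge (shared by both arms).
#' @param seed Integer seed; the whole cohort is drawn from one seeded stream.
#' @return A validated `cohort_config` object (a named list).
#' @seealso [generate_cohort()], [simulate_null()], [plant_twins()]
#' @export
cohort_config <- function(n_aoi = 14,
                          n_reference = 36,
                          rupture_rate = 0.5,
                          age_mean = 55,
                          age_sd = 10,
                          size_log_mean = log(7),
                          size_log_sd = 0.5,
                          gender_female_prob = 12 / 14,
                          shape_irregular_prob = 9 / 28,
                          covariate_prevalences = default_covariate_prevalences(),
                          outcome_effects = default_outcome_effects(),
                          hunt_hess_probs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                          fisher_grade_probs = c(0.15, 0.30, 0.35, 0.20),
                          mrs_probs = c(0.35, 0.20, 0.12, 0.10, 0.08, 0.10, 0.05),
                          seed = 1L) {
  cfg <- list(
    n_aoi = n_aoi, n_reference = n_reference, rupture_rate = rupture_rate,
    age_mean = age_mean, age_sd = age_sd,
    size_log_mean = size_log_mean, size_log_sd = size_log_sd,
    gender_female_prob = gender_female_prob,
    shape_irregular_prob = shape_irregular_prob,
    covariate_prevalences = covariate_prevalences,
    outcome_effects = outcome_effects,
    hunt_hess_probs = hunt_hess_probs,
    fisher_grade_probs = fisher_grade_probs,
    mrs_probs = mrs_probs,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_covariate_prevalences <- function() {
  c(
    hypertension = 11 / 28,
    diabetes = 0,
    peripheral_arterial_disease = 1 / 28,
    heart_disease = 5 / 28,
    ischemic_stroke = 3 / 28,
    thrombosis = 0,
    obesity = 2 / 28,
    nicotine_abuse = 10 / 28,
    alcohol_abuse = 0,
    multiple_aneurysms = 9 / 28
  )
}

#' @rdname cohort_config
#' @export
default_outcome_effects <- function() {
  list(
    occlusion_complete = c(0.85, 0.85),
    temporary_clipping = c(0.40, 0.40),
    intraoperative_rupture = c(0.15, 0.15),
    postoperative_stroke = c(0.15, 0.15),
    postoperative_hemorrhage = c(0.10, 0.10),
    hydrocephalus = c(0.30, 0.30),
    vp_shunt = c(0.20, 0.20),
    vasospasm = c(0.25, 0.25)
  )
}

validate_cohort_config <- function(cfg) {
  check_prob <- function(p, nm) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
      am_abort(sprintf("`%s` must be a probability in [0, 1].", nm),
               "aneumatch_config_error")
    }
  }
  for (nm in c("n_aoi", "n_reference")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      am_abort(sprintf("`%s` must be an integer count >= 1.", nm),
               "aneumatch_config_error")
    }
  }
  for (nm in c("age_sd", "size_log_sd")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      am_abort(sprintf("`%s` must be > 0.", nm), "aneumatch_config_error")
    }
  }
  check_prob(cfg$rupture_rate, "rupture_rate")
  check_prob(cfg$gender_female_prob, "gender_female_prob")
  check_prob(cfg$shape_irregular_prob, "shape_irregular_prob")
  check_prob(cfg$covariate_prevalences, "covariate_prevalences")
  if (is.null(names(cfg$covariate_prevalences)) ||
      anyDuplicated(names(cfg$covariate_prevalences))) {
    am_abort("`covariate_prevalences` must be uniquely named.",
             "aneumatch_config_error")
  }
  for (nm in names(cfg$outcome_effects)) {
    eff <- cfg$outcome_effects[[nm]]
    if (length(eff) != 2) {
      am_abort(sprintf("outcome effect `%s` must be length 2 (aoi, reference).", nm),
               "aneumatch_config_error")
    }
    check_prob(eff, sprintf("outcome_effects$%s", nm))
  }
  for (nm in c("hunt_hess_probs", "fisher_grade_probs", "mrs_probs")) {
    check_prob(cfg[[nm]], nm)
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8) {
      am_abort(sprintf("`%s` must sum to 1.", nm), "aneumatch_config_error")
    }
  }
  n_lv <- c(hunt_hess_probs = 5L, fisher_grade_probs = 4L, mrs_probs = 7L)
  for (nm in names(n_lv)) {
    if (length(cfg[[nm]]) != n_lv[[nm]]) {
      am_abort(sprintf("`%s` must have %d masses.", nm, n_lv[[nm]]),
               "aneumatch_config_error")
    }
  }
  invisible(cfg)
}

# truncated-normal draw through the probability integral transform, so a
# single uniform stream suffices and no rejection loop perturbs determinism
rtruncnorm_pit <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# raw clinical + morphological features for n cases (no ids/arms/outcomes);
# shared by the cohort generator and the decoy generator
r_case_features <- function(n, cfg) {
  ruptured <- runif(n) < cfg$rupture_rate
  size_mm <- rlnorm(n, cfg$size_log_mean, cfg$size_log_sd)
  hmax_mm <- size_mm
  height_mm <- hmax_mm * runif(n, 0.7, 1.0)
  feat <- tibble(
    gender = ifelse(runif(n) < cfg$gender_female_prob, "female", "male"),
    age = rtruncnorm_pit(n, cfg$age_mean, cfg$age_sd, 18, 95),
    ruptured = ruptured,
    hunt_hess = ifelse(
      ruptured, sample.int(5L, n, replace = TRUE, prob = cfg$hunt_hess_probs), NA_integer_
    ),
    fisher_grade = ifelse(
      ruptured, sample.int(4L, n, replace = TRUE, prob = cfg$fisher_grade_probs), NA_integer_
    ),
    size_mm = size_mm,
    shape = ifelse(runif(n) < cfg$shape_irregular_prob, "irregular", "regular"),
    width_mm = size_mm * runif(n, 0.6, 1.1),
    height_mm = height_mm,
    neck_mm = size_mm * runif(n, 0.3, 0.6),
    d1_mm = rtruncnorm_pit(n, 2.5, 0.4, 0.8, 5),
    d2_mm = NA_real_,
    hmax_mm = hmax_mm,
    vessel_angle = runif(n, 0, 180),
    inclination_angle = runif(n, 0, 180),
    fda_angle = runif(n, 0, 360),
    bleb = runif(n) < 0.2
  )
  feat$d2_mm <- feat$d1_mm * runif(n, 0.8, 1.1)
  for (cov in names(cfg$covariate_prevalences)) {
    feat[[cov]] <- runif(n) < cfg$covariate_prevalences[[cov]]
  }
  feat
}

r_outcomes <- function(arm, cfg) {
  n <- length(arm)
  out <- tibble(.rows = n)
  for (nm in names(cfg$outcome_effects)) {
    p <- ifelse(arm == "AIA", cfg$outcome_effects[[nm]][1],
                cfg$outcome_effects[[nm]][2])
    out[[nm]] <- runif(n) < p
  }
  out$mrs_discharge <- sample(0:6, n, replace = TRUE, prob = cfg$mrs_probs)
  out
}

#' Generate a synthetic two-arm aneurysm cohort
#'
#' Draws `n_aoi + n_reference` cases from one seeded pseudo-random stream:
#' the AOI arm (`arm == "AIA"`) first, then the reference arm (`arm == "PA"`).
#' Ruptured cases carry Hunt & Hess and Fisher grades; unruptured cases have
#' these fields `NA`. All binary covariates, morphometric measurements, a
#' frontal base-dome-angle in `[0, 360)`, and outcome fields drawn per
#' `outcome_effects` are included. Identical config (including seed) yields an
#' identical table.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble, one row per case, in the canonical case-table schema
#'   (see [case_table_schema()]).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$arm)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  withr::with_seed(config$seed, {
    n <- config$n_aoi + config$n_reference
    arm <- rep(c("AIA", "PA"), c(config$n_aoi, config$n_reference))
    feat <- r_case_features(n, config)
    out <- r_outcomes(arm, config)
    bind_cols(tibble(id = sprintf("case_%03d", seq_len(n)), arm = arm), feat, out)
  })
}

#' Plant perturbed matched twins for recovery experiments
#'
#' For each AOI case, emits one "twin" — a copy whose continuous matching
#' features (age, size) are jittered by `noise_scale` times the AOI-pool
#' standard deviation, whose binary matching features are flipped with
#' probability `flip_prob`, and whose ordinal grades are shifted by one level
#' with probability `flip_prob` — plus `n_decoys` decoy cases drawn fresh from
#' the generator's marginals but constrained to the same rupture status and
#' FDA category, so they compete in the same matching stratum. Twins keep
#' their AOI's rupture status and FDA angle. The true AOI-to-twin mapping is
#' returned so matching recovery can be scored.
#'
#' @param aois A case table of AOI cases (as from [generate_cohort()],
#'   filtered to `arm == "AIA"`).
#' @param noise_scale Fraction of each continuous feature's SD used as the
#'   jitter SD. `0` makes twins exact copies on all matching features.
#' @param flip_prob Probability of flipping each binary matching feature.
#' @param n_decoys Decoy cases per AOI (default 2, so the reference pool
#'   is roughly 36 cases for a 14-case AOI arm).
#' @param seed Integer seed for the perturbation/decoy stream.
#' @param config A [cohort_config()] providing decoy marginals.
#' @return A list with `reference` (the twin + decoy case table, `arm` set to
#'   `"PA"`) and `truth` (tibble with `aoi_id`, `twin_id`).
#' @export
plant_twins <- function(aois, noise_scale = 0, flip_prob = 0, n_decoys = 2,
                        seed = 1L, config = cohort_config()) {
  if (nrow(aois) == 0) {
    am_abort("`aois` must contain at least one case.", "aneumatch_config_error")
  }
  if (noise_scale < 0) {
    am_abort("`noise_scale` must be >= 0.", "aneumatch_config_error")
  }
  if (flip_prob < 0 || flip_prob > 1) {
    am_abort("`flip_prob` must be in [0, 1].", "aneumatch_config_error")
  }
  withr::with_seed(as.integer(seed), {
    n <- nrow(aois)
    sd_or_zero <- function(x) if (n > 1 && sd(x) > 0) sd(x) else 0
    age_sd <- sd_or_zero(aois$age)
    size_sd <- sd_or_zero(aois$size_mm)

    twins <- aois
    twins$id <- paste0("twin_", aois$id)
    twins$arm <- "PA"
    twins$age <- aois$age + rnorm(n, 0, noise_scale * age_sd)
    twins$size_mm <- pmax(aois$size_mm + rnorm(n, 0, noise_scale * size_sd), 0.1)
    flip <- function(x, a, b) ifelse(runif(n) < flip_prob, ifelse(x == a, b, a), x)
    twins$gender <- flip(aois$gender, "male", "female")
    twins$shape <- flip(aois$shape, "regular", "irregular")
    shift_grade <- function(g, lo, hi) {
      moved <- pmin(pmax(g + sample(c(-1L, 1L), n, replace = TRUE), lo), hi)
      ifelse(!is.na(g) & runif(n) < flip_prob, moved, g)
    }
    twins$hunt_hess <- shift_grade(aois$hunt_hess, 1L, 5L)
    twins$fisher_grade <- shift_grade(aois$fisher_grade, 1L, 4L)

    decoys <- NULL
    if (n_decoys > 0) {
      idx <- rep(seq_len(n), each = n_decoys)
      m <- length(idx)
      d <- r_case_features(m, config)
      d$ruptured <- aois$ruptured[idx]
      cat_lo <- (classify_fda(aois$fda_angle[idx]) - 1) * 90
      d$fda_angle <- runif(m, cat_lo, cat_lo + 90)
      d$hunt_hess <- ifelse(
        d$ruptured, sample.int(5L, m, replace = TRUE, prob = config$hunt_hess_probs),
        NA_integer_
      )
      d$fisher_grade <- ifelse(
        d$ruptured, sample.int(4L, m, replace = TRUE, prob = config$fisher_grade_probs),
        NA_integer_
      )
      arm <- rep("PA", m)
      decoys <- bind_cols(
        tibble(id = sprintf("decoy_%03d", seq_len(m)), arm = arm),
        d, r_outcomes(arm, config)
      )
      if ("fda_category" %in% names(aois)) decoys <- derive_morphometrics(decoys)
      decoys <- decoys[names(aois)]
    }
    list(
      reference = bind_rows(twins, decoys),
      truth = tibble(aoi_id = aois$id, twin_id = twins$id)
    )
  })
}

#' Replicated null cohorts for calibrating the comparison engine
#'
#' Generates `n_reps` independent cohorts under the sharp null: every
#' outcome's probability must be identical between arms (an error otherwise).
#' Replicate `i` uses seed `config$seed + i` so the set is reproducible from
#' the base seed alone.
#'
#' @param config A [cohort_config()] with arm-equal `outcome_effects`.
#' @param n_reps Number of replicate cohorts (0 gives an empty list).
#' @return A list of `n_reps` case tables.
#' @export
simulate_null <- function(config, n_reps) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  uneq <- names(Filter(function(e) e[1] != e[2], config$outcome_effects))
  if (length(uneq)) {
    am_abort(
      paste0("simulate_null() requires arm-equal outcome effects; differing: ",
             paste(uneq, collapse = ", ")),
      "aneumatch_config_error"
    )
  }
  if (n_reps < 0) am_abort("`n_reps` must be >= 0.", "aneumatch_config_error")
  lapply(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generate_cohort(cfg)
  })
}
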