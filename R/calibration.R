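#' Type-I error calibration of the comparison engine
#'
#' Runs the full routing + testing chain on replicated null cohorts
#' ([simulate_null()]) and tallies, per routed test, how often it rejects at
#' `alpha`. The default variable panel exercises every route: a
#' 50%-prevalence binary (mostly chi-square), a ~36%-prevalence binary
#' (mostly Fisher), a normal metric (mostly t), a log-normal metric (mixed
#' t / Mann-Whitney) and a discrete ordinal (mostly Mann-Whitney).
#'
#' @param config A [cohort_config()] with arm-equal outcome effects; the
#'   default uses 14 cases per arm.
#' @param n_reps Number of replicate cohorts.
#' @param variables Tibble with `name` and `kind` columns selecting which
#'   case-table variables are compared in each replicate.
#' @param alpha Rejection level.
#' @return A tibble with one row per routed test: `test`, `n_routed`,
#'   `n_rejected`, `rate`.
#' @export
calibrate_type1 <- function(config = cohort_config(n_aoi = 14, n_reference = 14),
                            n_reps = 2000,
                            variables = calibration_variables(),
                            alpha = 0.05) {
  cohorts <- simulate_null(config, n_reps)
  tally <- list()
  for (co in cohorts) {
    is_aoi <- co$arm == "AIA"
    for (i in seq_len(nrow(variables))) {
      x <- co[[variables$name[i]]]
      a <- x[is_aoi & !is.na(x)]
      b <- x[!is_aoi & !is.na(x)]
      if (length(unique(c(a, b))) < 2) next
      routed <- choose_test(a, b, kind = variables$kind[i], alpha = alpha)
      p <- switch(routed$test,
        "chi-square" = chi_square_2xc(two_group_table(a, b))$p.value,
        "fisher-exact" = suppressWarnings(fisher_exact_2x2(two_group_table(a, b)))$p.value,
        "mann-whitney" = mann_whitney_u(as.numeric(a), as.numeric(b))$p.value,
        "t-test" = t_test_groups(as.numeric(a), as.numeric(b),
                                 pooled = isTRUE(routed$trace$pooled))$p.value
      )
      key <- routed$test
      if (is.null(tally[[key]])) tally[[key]] <- c(0L, 0L)
      tally[[key]] <- tally[[key]] + c(1L, as.integer(p < alpha))
    }
  }
  list_rbind(imap(tally, function(v, test) {
    tibble(test = test, n_routed = v[1], n_rejected = v[2], rate = v[2] / v[1])
  })) |> arrange(.data$test)
}

#' @rdname calibrate_type1
#' @export
calibration_variables <- function() {
  tibble(
    name = c("ruptured", "nicotine_abuse", "age", "size_mm", "mrs_discharge"),
    kind = c("binary", "binary", "metric", "metric", "ordinal")
  )
}

#' Planted-twin recovery experiment
#'
#' Replicates the end-to-end matching recovery check: generate an AOI arm,
#' plant one perturbed twin plus decoys per AOI ([plant_twins()]), run the
#' stratified sequential matcher, and score the fraction of AOIs paired with
#' their true twin.
#'
#' @param n_reps Number of seeded replicates.
#' @param noise_scale,flip_prob,n_decoys Perturbation settings passed to
#'   [plant_twins()].
#' @param config Cohort settings for the AOI arm and decoy marginals.
#' @param base_seed Replicate `i` uses cohort seed `base_seed + i` and
#'   planting seed `base_seed + 100000 + i`.
#' @return A tibble with one row per replicate: `replicate`, `n_aoi`,
#'   `n_recovered`, `rate`.
#' @export
twin_recovery <- function(n_reps = 100, noise_scale = 0.05, flip_prob = 0,
                          n_decoys = 2, config = cohort_config(),
                          base_seed = 1L) {
  list_rbind(map(seq_len(n_reps), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    aois <- filter(generate_cohort(cfg), .data$arm == "AIA")
    planted <- plant_twins(aois, noise_scale = noise_scale,
                           flip_prob = flip_prob, n_decoys = n_decoys,
                           seed = base_seed + 100000 + i, config = cfg)
    m <- sequential_match(aois, planted$reference)
    hit <- m$pairs$reference_id ==
      planted$truth$twin_id[match(m$pairs$aoi_id, planted$truth$aoi_id)]
    tibble(replicate = i, n_aoi = nrow(aois), n_recovered = sum(hit),
           rate = mean(hit))
  }))
}
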