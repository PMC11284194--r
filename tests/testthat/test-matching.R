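stratum_cats <- function(stratum) {
  lapply(strsplit(sub(".*/cat", "", stratum), "\\+"), as.integer)
}

test_that("strata separate rupture status and FDA category", {
  co <- derive_morphometrics(generate_cohort(cohort_config(seed = 31)))
  aois <- dplyr::filter(co, arm == "AIA")
  refs <- dplyr::filter(co, arm == "PA")
  st <- stratify_cases(aois, refs)
  joined <- dplyr::inner_join(st$assignments, st$reference_strata,
                              by = "stratum", relationship = "many-to-many")
  ref_rows <- refs[match(joined$reference_id, refs$id), ]
  expect_true(all(joined$ruptured == ref_rows$ruptured))
  # each reference's category belongs to its stratum's category set
  cats <- stratum_cats(joined$stratum)
  expect_true(all(mapply(function(c, cs) c %in% cs, ref_rows$fda_category, cats)))
  expect_true(all(mapply(function(c, cs) c %in% cs, joined$fda_category, cats)))
  # every stratum supports one-to-one matching: at least as many refs as AOIs
  n_a <- table(st$assignments$stratum)
  n_r <- table(st$reference_strata$stratum)
  expect_true(all(n_r[names(n_a)] >= n_a))
})

test_that("an empty FDA stratum merges into a neighbour category and is logged", {
  cases <- tiny_cases()
  aois <- cases[cases$arm == "AIA", ]
  refs <- cases[cases$arm == "PA", ]
  aois$fda_angle <- c(200, 210)            # category 3 AOIs
  refs$fda_angle <- c(280, 290, 300, 310)  # only category 4 references
  st <- stratify_cases(aois, refs)
  expect_equal(unique(st$assignments$stratum), "unruptured/cat3+4")
  expect_equal(st$merges$from_category, c(3L, 3L))
  expect_equal(st$merges$to_category, c(4L, 4L))
  m <- sequential_match(aois, refs)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$log$event[1:2] == "stratum_merge"))
  # merging disabled: unmatchable error listing the case
  expect_error(stratify_cases(aois, refs, fallback_merge = FALSE),
               "c01", class = "aneumatch_unmatchable_error")
})

test_that("ruptured AOIs are never matched to unruptured references", {
  set.seed(61)
  for (s in 1:5) {
    co <- derive_morphometrics(generate_cohort(cohort_config(seed = 400 + s)))
    m <- match_cohort(co)
    left <- co[match(m$pairs$aoi_id, co$id), ]
    right <- co[match(m$pairs$reference_id, co$id), ]
    expect_identical(left$ruptured, right$ruptured)
    # categories agree except inside logged merged strata
    cats <- stratum_cats(m$pairs$stratum)
    merged <- lengths(cats) > 1
    expect_true(all(left$fda_category[!merged] == right$fda_category[!merged]))
    expect_true(all(mapply(function(c, cs) c %in% cs,
                           right$fda_category, cats)))
    if (any(merged)) expect_gt(nrow(m$merges), 0)
  }
})

test_that("zero-noise planted twins are recovered exactly with no conflicts", {
  aois <- dplyr::filter(generate_cohort(cohort_config(seed = 71)), arm == "AIA")
  planted <- plant_twins(aois, noise_scale = 0, flip_prob = 0, n_decoys = 2,
                         seed = 72)
  m <- sequential_match(aois, planted$reference)
  expect_equal(nrow(m$pairs), nrow(aois))
  hit <- m$pairs$reference_id ==
    planted$truth$twin_id[match(m$pairs$aoi_id, planted$truth$aoi_id)]
  expect_true(all(hit))
  expect_true(all(m$pairs$distance == 0))
  expect_equal(sum(m$log$event == "conflict"), 0)
})

test_that("a shared top neighbour produces one logged conflict resolved by distance", {
  cases <- tiny_cases()
  aois <- cases[cases$arm == "AIA", ]
  refs <- cases[cases$arm == "PA", ]
  # make one reference everyone's favourite: clone of AOI c01, nearer to it
  refs$age <- c(50.2, 49.5, 70, 40)
  refs$size_mm <- c(6.05, 5.9, 12, 4)
  refs$gender <- c("female", "female", "male", "male")
  refs$shape <- "regular"
  aois$age <- c(50, 50.45); aois$size_mm <- c(6, 6.12)
  aois$gender <- "female"; aois$shape <- "regular"
  m <- sequential_match(aois, refs)
  conflicts <- m$log[m$log$event == "conflict", ]
  expect_equal(nrow(conflicts), 1)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(anyDuplicated(m$pairs$reference_id), 0)
  # the contested reference went to the closer claimant; the loser fell back
  contested <- conflicts$reference_id
  winner <- m$pairs$aoi_id[m$pairs$reference_id == contested]
  loser <- setdiff(m$pairs$aoi_id, winner)
  d_winner <- m$neighbors[[winner]]$raw_distance[
    m$neighbors[[winner]]$reference_id == contested]
  d_loser <- m$neighbors[[loser]]$raw_distance[
    m$neighbors[[loser]]$reference_id == contested]
  expect_lte(d_winner, d_loser)
  expect_gt(m$pairs$rank[m$pairs$aoi_id == loser], 1)
})

test_that("the contested reference goes to the smaller-distance claimant", {
  # worked two-claimant case: distances 0.5 and 0.9 to the shared reference,
  # symmetric fallbacks -- the rule's assignment also minimizes the total
  # matched distance over the two feasible alternatives
  ns1 <- tibble::tibble(reference_id = c("shared", "x1", "x2"),
                        raw_distance = c(0.5, 1.2, 1.4), weight = 1 / 3)
  ns2 <- tibble::tibble(reference_id = c("shared", "y1", "y2"),
                        raw_distance = c(0.9, 1.2, 1.4), weight = 1 / 3)
  res <- resolve_conflicts("shared", list(a1 = ns1, a2 = ns2))
  expect_equal(res$reference_id[res$aoi_id == "a1"], "shared")
  alt1 <- 0.5 + 1.2  # a1 keeps shared, a2 falls back
  alt2 <- 0.9 + 1.2  # a2 takes shared, a1 falls back
  expect_equal(sum(res$distance), min(alt1, alt2))
  # property over random instances: the winner is always the closer claimant
  set.seed(81)
  for (i in 1:50) {
    d1 <- sort(runif(3)); d2 <- sort(runif(3))
    r <- resolve_conflicts(
      "shared",
      list(a1 = tibble::tibble(reference_id = c("shared", "x1", "x2"),
                               raw_distance = d1, weight = 1 / 3),
           a2 = tibble::tibble(reference_id = c("shared", "y1", "y2"),
                               raw_distance = d2, weight = 1 / 3))
    )
    winner <- r$aoi_id[r$reference_id == "shared"]
    expect_equal(winner, if (d1[1] <= d2[1]) "a1" else "a2")
  }
})

test_that("ties on distance go to the lower case id; deep fallbacks cascade", {
  ns_equal <- function(ids, d) {
    tibble::tibble(reference_id = ids, raw_distance = d, weight = 1 / 3)
  }
  res <- resolve_conflicts(
    "shared",
    list(a2 = ns_equal(c("shared", "u", "v"), c(0.5, 0.8, 0.9)),
         a1 = ns_equal(c("shared", "u", "v"), c(0.5, 0.7, 0.9)))
  )
  expect_equal(res$reference_id[res$aoi_id == "a1"], "shared")
  # loser's second neighbour already taken -> third used
  res2 <- resolve_conflicts(
    "shared",
    list(a1 = ns_equal(c("shared", "u", "v"), c(0.1, 0.8, 0.9)),
         a2 = ns_equal(c("shared", "u", "v"), c(0.2, 0.5, 0.9))),
    taken = "u"
  )
  expect_equal(res2$reference_id[res2$aoi_id == "a2"], "v")
  expect_equal(res2$rank[res2$aoi_id == "a2"], 3)
  # exhausted neighbour list is an unmatchable error
  expect_error(
    resolve_conflicts(
      "shared",
      list(a1 = ns_equal(c("shared", "u", "v"), c(0.1, 0.8, 0.9)),
           a2 = ns_equal(c("shared", "u", "v"), c(0.2, 0.5, 0.9))),
      taken = c("u", "v")
    ),
    class = "aneumatch_unmatchable_error"
  )
})

test_that("the 14-vs-36 workflow yields 14 one-to-one stratum-consistent pairs", {
  co <- derive_morphometrics(generate_cohort(cohort_config(seed = 91)))
  m <- match_cohort(co)
  expect_equal(nrow(m$pairs), 14)
  expect_equal(anyDuplicated(m$pairs$aoi_id), 0)
  expect_equal(anyDuplicated(m$pairs$reference_id), 0)
  g <- glance(m)
  expect_equal(g$n_pairs, 14L)
  expect_identical(tidy(m), m$pairs)
  # all variants select the same pairs (weights differ, ranking does not)
  m_inv <- match_cohort(co, variant = "inverse_distance")
  expect_identical(m_inv$pairs[c("aoi_id", "reference_id")],
                   m$pairs[c("aoi_id", "reference_id")])
})

test_that("matched null cohorts stay balanced on the matching covariates", {
  n_reps <- 60
  vars <- dplyr::filter(baseline_variables(), role == "matching covariate")
  flags <- 0L; n_tests <- 0L
  for (i in seq_len(n_reps)) {
    co <- derive_morphometrics(generate_cohort(cohort_config(seed = 5000 + i)))
    mc <- matched_cases(match_cohort(co), co)
    bt <- suppressWarnings(baseline_table(mc, variables = vars))
    p <- bt$p_value[!is.na(bt$p_value)]
    flags <- flags + sum(p < 0.05)
    n_tests <- n_tests + length(p)
  }
  rate <- flags / n_tests
  # matching under the null must not inflate covariate differences above alpha
  expect_lte(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n_tests))
})
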