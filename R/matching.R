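#' Stratify AOIs and reference candidates by rupture status and FDA category
#'
#' Matching is constrained to strata: an AOI may only be paired with a
#' reference case of the same rupture status and the same frontal
#' base-dome-angle (FDA) category. A category whose reference candidates
#' cannot support its AOIs — none at all, or fewer references than AOIs
#' needing one-to-one matches — is merged with a neighbouring category (the
#' next category up first, the 3-into-4 merge, then down, then two away),
#' cell by cell until every stratum has at least as many references as AOIs;
#' every merge is logged. AOIs that remain unsupportable after merging all
#' four categories are an error.
#'
#' @param aois,references Case tables carrying `ruptured` and either
#'   `fda_category` or `fda_angle` (the category is derived if absent).
#' @param fallback_merge Allow category merging (default TRUE). With merging
#'   disabled, a category without references errors immediately.
#' @return A list with `assignments` (tibble: `aoi_id`, `ruptured`,
#'   `fda_category`, `stratum`), `reference_strata` (tibble: `reference_id`,
#'   `stratum`) and `merges` (tibble: `aoi_id`, `from_category`,
#'   `to_category`, one row per AOI whose own category could not support it).
#' @export
stratify_cases <- function(aois, references, fallback_merge = TRUE) {
  aois <- ensure_fda_category(aois)
  references <- ensure_fda_category(references)
  ids <- c(aois$id, references$id)
  if (anyDuplicated(ids)) {
    am_abort(paste0("Duplicate case id: ", ids[duplicated(ids)][1]),
             "aneumatch_schema_error")
  }

  assign_rows <- list(); ref_rows <- list(); merge_rows <- list()
  for (rupt in unique(aois$ruptured)) {
    a_sub <- aois[aois$ruptured == rupt, , drop = FALSE]
    r_sub <- references[references$ruptured == rupt, , drop = FALSE]
    n_aoi <- tabulate(a_sub$fda_category, 4L)
    n_ref <- tabulate(r_sub$fda_category, 4L)
    deficient <- which(n_aoi > 0 & n_ref < n_aoi)
    groups <- if (fallback_merge) merge_fda_cells(n_aoi, n_ref) else as.list(1:4)
    label <- function(cats) {
      paste0(if (rupt) "ruptured" else "unruptured", "/cat",
             paste(sort(cats), collapse = "+"))
    }
    for (g in groups) {
      ga <- a_sub[a_sub$fda_category %in% g, , drop = FALSE]
      gr <- r_sub[r_sub$fda_category %in% g, , drop = FALSE]
      if (nrow(ga) > 0 && (nrow(gr) == 0 ||
                           (fallback_merge && nrow(gr) < nrow(ga)))) {
        am_abort(
          sprintf("AOI(s) %s (ruptured = %s, FDA categor%s %s) cannot be matched: %d reference candidate(s) for %d AOI(s).",
                  paste(ga$id, collapse = ", "), rupt,
                  if (length(g) > 1) "ies" else "y",
                  paste(sort(g), collapse = "+"), nrow(gr), nrow(ga)),
          "aneumatch_unmatchable_error"
        )
      }
      if (nrow(ga) == 0) next
      assign_rows[[length(assign_rows) + 1]] <- tibble(
        aoi_id = ga$id, ruptured = rupt, fda_category = ga$fda_category,
        stratum = label(g)
      )
      ref_rows[[length(ref_rows) + 1]] <- tibble(
        reference_id = gr$id, stratum = label(g)
      )
      bad_cats <- intersect(g, deficient)
      if (length(g) > 1 && length(bad_cats)) {
        hit <- ga[ga$fda_category %in% bad_cats, , drop = FALSE]
        merge_rows[[length(merge_rows) + 1]] <- tibble(
          aoi_id = hit$id,
          from_category = hit$fda_category,
          to_category = vapply(hit$fda_category,
                               function(c) setdiff(sort(g), c)[1], integer(1))
        )
      }
    }
  }
  list(
    assignments = if (length(assign_rows)) list_rbind(assign_rows) else
      tibble(aoi_id = character(), ruptured = logical(),
             fda_category = integer(), stratum = character()),
    reference_strata = if (length(ref_rows)) list_rbind(ref_rows) else
      tibble(reference_id = character(), stratum = character()),
    merges = if (length(merge_rows)) list_rbind(merge_rows) else
      tibble(aoi_id = character(), from_category = integer(),
             to_category = integer())
  )
}

# Merge FDA category cells until every group holds at least as many
# references as AOIs. Merge preference per group: next category up, then
# down, then two away — generalizing the published 3-into-4 exception.
merge_fda_cells <- function(n_aoi, n_ref) {
  groups <- as.list(1:4)
  repeat {
    a <- vapply(groups, function(g) sum(n_aoi[g]), numeric(1))
    r <- vapply(groups, function(g) sum(n_ref[g]), numeric(1))
    bad <- which(a > 0 & r < a)
    if (!length(bad)) return(groups)
    g_idx <- bad[1]
    cats <- groups[[g_idx]]
    neigh <- unlist(lapply(sort(cats), function(c) c(c + 1, c - 1, c + 2, c - 2)))
    neigh <- unique(neigh[neigh >= 1 & neigh <= 4 & !neigh %in% cats])
    if (!length(neigh)) return(groups)  # nothing left to merge; caller errors
    t_idx <- which(vapply(groups, function(x) neigh[1] %in% x, logical(1)))
    groups[[g_idx]] <- sort(c(groups[[g_idx]], groups[[t_idx]]))
    groups <- groups[-t_idx]
  }
}

ensure_fda_category <- function(cases) {
  if (!"fda_category" %in% names(cases)) {
    if (!"fda_angle" %in% names(cases)) {
      am_abort("Cases need `fda_category` or `fda_angle`.", "aneumatch_schema_error")
    }
    cases$fda_category <- classify_fda(cases$fda_angle)
  }
  if (!"ruptured" %in% names(cases)) {
    am_abort("Cases need a `ruptured` column.", "aneumatch_schema_error")
  }
  cases
}

#' Deterministic adjudication of a contested reference case
#'
#' When several AOIs claim the same reference as their best match, the
#' contested reference goes to the claimant with the smaller raw distance
#' (ties broken by ascending AOI id); each loser falls back to its next —
#' second, then third — neighbour that is not yet assigned. A claimant that
#' exhausts its neighbour list is an error. This deterministic rule stands in
#' for expert review of the lower-ranked matches; supply a custom function
#' via the `adjudicator` argument of [sequential_match()] to replay external
#' (e.g. expert-panel) decisions.
#'
#' @param contested The contested reference case id.
#' @param claimants Named list (names = AOI ids) of neighbour sets as
#'   returned by [knn_neighbors()].
#' @param taken Character vector of reference ids already assigned elsewhere.
#' @return Tibble with one row per claimant: `aoi_id`, `reference_id`,
#'   `distance`, `rank` (the neighbour rank used).
#' @export
resolve_conflicts <- function(contested, claimants, taken = character()) {
  if (length(claimants) < 2) {
    am_abort("Conflict resolution needs at least 2 claimants.",
             "aneumatch_domain_error")
  }
  d_to_contested <- map_dbl(claimants, function(ns) {
    i <- match(contested, ns$reference_id)
    if (is.na(i)) Inf else ns$raw_distance[i]
  })
  ord <- order(d_to_contested, names(claimants))
  winner <- names(claimants)[ord[1]]
  taken <- union(taken, contested)
  rows <- list(tibble(
    aoi_id = winner, reference_id = contested,
    distance = d_to_contested[[winner]],
    rank = match(contested, claimants[[winner]]$reference_id)
  ))
  for (loser in names(claimants)[ord[-1]]) {
    ns <- claimants[[loser]]
    free <- which(!ns$reference_id %in% taken)
    if (!length(free)) {
      am_abort(
        sprintf("AOI `%s` exhausted its %d nearest neighbours during conflict resolution.",
                loser, nrow(ns)),
        "aneumatch_unmatchable_error"
      )
    }
    j <- free[1]
    taken <- c(taken, ns$reference_id[j])
    rows[[length(rows) + 1]] <- tibble(
      aoi_id = loser, reference_id = ns$reference_id[j],
      distance = ns$raw_distance[j], rank = j
    )
  }
  list_rbind(rows)
}

#' Sequentially match AOIs to their nearest stratum-mates
#'
#' Implements the full matched-cohort construction: cases are stratified by
#' rupture status and FDA category ([stratify_cases()]); within each stratum
#' the rupture-specific feature set ([select_matching_features()]) is
#' 0/1-encoded and Z-score standardized over the stratum pool (AOIs plus
#' candidates); each AOI, taken in ascending id order ("next in line"), has
#' its k nearest references retrieved ([knn_neighbors()]) and its top
#' neighbour proposed. References are matched one-to-one without replacement:
#' when a proposed reference is already held, the conflict is adjudicated
#' ([resolve_conflicts()]) and logged.
#'
#' @param aois Case table of AOIs (queries).
#' @param references Case table of reference candidates.
#' @param variant k-NN weighting variant (see [knn_neighbors()]); the
#'   neighbour ranking — and hence the matching — is the same for all
#'   variants, which differ only in the reported neighbour weights.
#' @param k Neighbours retrieved per AOI (default 3); also the fallback depth
#'   available during conflict resolution.
#' @param fallback_merge Merge empty FDA strata into a neighbour category
#'   (default TRUE).
#' @param adjudicator Conflict policy, a function with the signature of
#'   [resolve_conflicts()].
#' @return A `matched_cohort` object: `pairs` (tibble `aoi_id`,
#'   `reference_id`, `distance`, `stratum`), `log` (merges + conflicts),
#'   `neighbors` (per-AOI neighbour sets), `distances` (long within-stratum
#'   AOI x reference distance table), `variant`, `k`. Use [tidy()] /
#'   [glance()] / [autoplot()] on the result.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' m <- sequential_match(dplyr::filter(cohort, arm == "AIA"),
#'                       dplyr::filter(cohort, arm == "PA"))
#' glance(m)
#' @export
sequential_match <- function(aois, references,
                             variant = c("plain", "inverse_distance", "minmax_inverse"),
                             k = 3L, fallback_merge = TRUE,
                             adjudicator = resolve_conflicts) {
  variant <- match.arg(variant)
  aois <- ensure_fda_category(aois)
  references <- ensure_fda_category(references)
  strat <- stratify_cases(aois, references, fallback_merge)

  log_rows <- list()
  if (nrow(strat$merges)) {
    log_rows <- map(seq_len(nrow(strat$merges)), function(i) {
      tibble(
        event = "stratum_merge", aoi_id = strat$merges$aoi_id[i],
        reference_id = NA_character_,
        detail = sprintf("FDA category %d merged into %d (insufficient same-category references)",
                         strat$merges$from_category[i], strat$merges$to_category[i])
      )
    })
  }

  neighbors <- list()
  full_rank <- list()
  dist_rows <- list()
  for (s in unique(strat$assignments$stratum)) {
    aoi_ids <- strat$assignments$aoi_id[strat$assignments$stratum == s]
    ref_ids <- strat$reference_strata$reference_id[strat$reference_strata$stratum == s]
    sub_aois <- aois[match(aoi_ids, aois$id), , drop = FALSE]
    sub_refs <- references[match(ref_ids, references$id), , drop = FALSE]
    ruptured <- sub_aois$ruptured[1]
    spec <- select_matching_features(ruptured, k = k)
    pool <- bind_rows(
      sub_aois[, c("id", spec$name)],
      sub_refs[, c("id", spec$name)]
    )
    m <- encode_features(pool, spec)
    z <- zscore_standardize_quiet(m)
    constant_cols <- colnames(m)[attr(z, "constant")]
    if (length(constant_cols)) {
      log_rows[[length(log_rows) + 1]] <- tibble(
        event = "constant_feature", aoi_id = NA_character_,
        reference_id = NA_character_,
        detail = sprintf("stratum %s: constant feature(s) %s carry no matching information",
                         s, paste(constant_cols, collapse = ", "))
      )
    }
    zr <- z[ref_ids, , drop = FALSE]
    for (a in aoi_ids) {
      ns <- knn_neighbors(z[a, ], zr, spec, variant = variant, k = k)
      neighbors[[a]] <- ns
      full_rank[[a]] <- knn_neighbors(z[a, ], zr, spec, variant = variant,
                                      k = nrow(zr))
      dist_rows[[length(dist_rows) + 1]] <- tibble(
        aoi_id = a, reference_id = ref_ids,
        distance = pool_distances(z[a, ], zr, spec$weight),
        stratum = s
      )
    }
  }

  # sequential assignment, ascending AOI id, 1:1 without replacement
  assigned <- list() # reference_id -> list(aoi_id, distance, rank)
  aoi_order <- sort(strat$assignments$aoi_id)
  for (a in aoi_order) {
    ns <- neighbors[[a]]
    top <- ns$reference_id[1]
    if (is.null(assigned[[top]])) {
      assigned[[top]] <- list(aoi_id = a, distance = ns$raw_distance[1], rank = 1L)
      next
    }
    holder <- assigned[[top]]$aoi_id
    taken_now <- setdiff(names(assigned), top)
    res <- tryCatch(
      adjudicator(
        contested = top,
        claimants = setNames(list(neighbors[[holder]], ns), c(holder, a)),
        taken = taken_now
      ),
      aneumatch_unmatchable_error = function(e) {
        # the loser's k nearest are all taken: widen its candidate ranking to
        # the whole stratum so one-to-one completeness is preserved, and log it
        log_rows[[length(log_rows) + 1]] <<- tibble(
          event = "neighbour_extension", aoi_id = a, reference_id = top,
          detail = sprintf("k = %d nearest neighbours exhausted during adjudication; ranking extended to the full stratum pool", k)
        )
        adjudicator(
          contested = top,
          claimants = setNames(list(full_rank[[holder]], full_rank[[a]]),
                               c(holder, a)),
          taken = taken_now
        )
      }
    )
    assigned[[top]] <- NULL
    for (i in seq_len(nrow(res))) {
      assigned[[res$reference_id[i]]] <- list(
        aoi_id = res$aoi_id[i], distance = res$distance[i], rank = res$rank[i]
      )
    }
    winner <- res$aoi_id[res$reference_id == top]
    loser <- setdiff(res$aoi_id, winner)
    log_rows[[length(log_rows) + 1]] <- tibble(
      event = "conflict", aoi_id = a, reference_id = top,
      detail = sprintf(
        "reference contested by %s; awarded to %s (smaller distance); %s fell back to rank-%d neighbour %s",
        paste(res$aoi_id, collapse = " and "), winner, loser,
        res$rank[res$aoi_id == loser], res$reference_id[res$aoi_id == loser]
      )
    )
  }

  pair_tbl <- list_rbind(imap(assigned, function(v, ref) {
    tibble(aoi_id = v$aoi_id, reference_id = ref, distance = v$distance, rank = v$rank)
  })) |>
    left_join(strat$assignments[, c("aoi_id", "stratum")], by = "aoi_id") |>
    arrange(.data$aoi_id) |>
    select("aoi_id", "reference_id", "distance", "rank", "stratum")

  structure(
    list(
      pairs = pair_tbl,
      log = if (length(log_rows)) list_rbind(log_rows) else
        tibble(event = character(), aoi_id = character(),
               reference_id = character(), detail = character()),
      merges = strat$merges,
      neighbors = neighbors,
      distances = list_rbind(dist_rows),
      variant = variant,
      k = as.integer(k)
    ),
    class = "matched_cohort"
  )
}

zscore_standardize_quiet <- function(m) suppressWarnings(zscore_standardize(m))

#' Match a single case table split by treatment arm
#'
#' Convenience wrapper around [sequential_match()] for the canonical case
#' table: rows with `arm == aoi_arm` become the AOIs, all other rows the
#' reference pool.
#'
#' @param cases Case table with an `arm` column.
#' @param aoi_arm Arm label identifying the AOIs (default `"AIA"`).
#' @inheritParams sequential_match
#' @return A `matched_cohort` (see [sequential_match()]).
#' @export
match_cohort <- function(cases, aoi_arm = "AIA",
                         variant = c("plain", "inverse_distance", "minmax_inverse"),
                         k = 3L, fallback_merge = TRUE,
                         adjudicator = resolve_conflicts) {
  variant <- match.arg(variant)
  aois <- filter(cases, .data$arm == aoi_arm)
  refs <- filter(cases, .data$arm != aoi_arm)
  if (nrow(aois) == 0 || nrow(refs) == 0) {
    am_abort("Both arms must be non-empty.", "aneumatch_config_error")
  }
  sequential_match(aois, refs, variant = variant, k = k,
                   fallback_merge = fallback_merge, adjudicator = adjudicator)
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "Matched cohort: %d pairs (variant %s, k = %d)\n", nrow(x$pairs), x$variant, x$k
  ))
  cat(sprintf("  conflicts adjudicated: %d; stratum merges: %d\n",
              sum(x$log$event == "conflict"), nrow(x$merges)))
  print(x$pairs, ...)
  invisible(x)
}

#' @describeIn sequential_match Tidy the matched pairs into a tibble.
#' @param x A `matched_cohort`.
#' @param ... Unused.
#' @method tidy matched_cohort
#' @export
tidy.matched_cohort <- function(x, ...) x$pairs

#' @describeIn sequential_match One-row summary of the matching run.
#' @method glance matched_cohort
#' @export
glance.matched_cohort <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_conflicts = sum(x$log$event == "conflict"),
    n_merges = nrow(x$merges),
    mean_distance = mean(x$pairs$distance),
    max_distance = max(x$pairs$distance),
    variant = x$variant,
    k = x$k
  )
}
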