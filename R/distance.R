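#' Weighted Euclidean dissimilarity between two standardized cases
#'
#' Computes `dist(x, q) = sqrt(sum_l fw_l * (x_l - q_l)^2)` over the `N`
#' features of the spec. With all weights 1 this is the ordinary Euclidean
#' distance on the Z-scored feature space.
#'
#' @param x,q Numeric vectors of equal length (standardized feature rows).
#' @param weights Non-negative feature weights `fw_l`; either a numeric
#'   vector or a [feature_spec()] (whose `weight` column is used). Defaults
#'   to 1 for every feature.
#' @return A single non-negative number.
#' @examples
#' weighted_distance(c(3, 4), c(0, 0)) # 5
#' @export
weighted_distance <- function(x, q, weights = NULL) {
  if (inherits(weights, "feature_spec")) weights <- weights$weight
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(x) != length(q) || length(x) != length(weights)) {
    am_abort("`x`, `q` and `weights` must have equal length.",
             "aneumatch_domain_error")
  }
  if (any(weights < 0)) {
    am_abort("Feature weights must be >= 0.", "aneumatch_domain_error")
  }
  sqrt(sum(weights * (x - q)^2))
}

# all pool distances from one query row; vectorized over the pool
pool_distances <- function(query, pool, weights) {
  d2 <- sweep(pool, 2, query, "-")^2
  sqrt(as.vector(d2 %*% weights))
}

#' k-nearest-neighbour retrieval under three weighting variants
#'
#' Retrieves the `k` reference cases nearest to a query under the weighted
#' Euclidean dissimilarity, with per-neighbour influence weights per variant:
#'
#' * `plain` — every nearest neighbour has equal impact, weight `1/k`.
#' * `inverse_distance` — weights proportional to `1/d`, normalized to sum 1.
#' * `minmax_inverse` — all pool distances are first min-max rescaled to
#'   `[0, 1]` via `(d - dmin) / (dmax - dmin)`, then inverse-weighted as in
#'   `inverse_distance`. Because the pool minimum always rescales to 0, the
#'   zero-distance rule below gives the top neighbour weight 1 under this
#'   variant.
#'
#' Degenerate cases: if any (rescaled) distance is exactly 0, the
#' zero-distance neighbours share weight 1 equally and all others get 0; if
#' the pool's min-max range is 0 the rescaling is undefined and weights fall
#' back to equal. The neighbour *set* is identical across variants — only the
#' weights differ.
#'
#' @param query Standardized feature row of the query case (the AOI).
#' @param pool Standardized matrix of candidate reference cases (rows named
#'   by case id).
#' @param spec A [feature_spec()] (weights and `k`), or NULL for unit weights.
#' @param variant One of `"plain"`, `"inverse_distance"`, `"minmax_inverse"`.
#' @param k Neighbour count; defaults to the spec's `k` (3).
#' @return A `neighbor_set` tibble with columns `reference_id`,
#'   `raw_distance` (non-decreasing) and `weight` (sums to 1), of
#'   `min(k, nrow(pool))` rows.
#' @export
knn_neighbors <- function(query, pool,
                          spec = NULL,
                          variant = c("plain", "inverse_distance", "minmax_inverse"),
                          k = NULL) {
  variant <- match.arg(variant)
  if (is.null(dim(pool)) || nrow(pool) == 0) {
    am_abort("Reference pool is empty.", "aneumatch_domain_error")
  }
  weights <- if (is.null(spec)) rep(1, ncol(pool)) else spec$weight
  k <- k %||% (if (is.null(spec)) 3L else spec_k(spec))
  d_all <- pool_distances(query, pool, weights)
  ord <- order(d_all, rownames(pool))
  kk <- min(k, nrow(pool))
  sel <- ord[seq_len(kk)]
  d <- d_all[sel]
  w <- switch(variant,
    plain = rep(1 / kk, kk),
    inverse_distance = inverse_weights(d),
    minmax_inverse = {
      rng <- range(d_all)
      if (diff(rng) == 0) rep(1 / kk, kk)
      else inverse_weights((d - rng[1]) / diff(rng))
    }
  )
  structure(
    tibble(reference_id = rownames(pool)[sel], raw_distance = d, weight = w),
    variant = variant,
    class = c("neighbor_set", class(tibble()))
  )
}

# inverse-distance weights, normalized to 1; zero distances absorb all weight
inverse_weights <- function(d) {
  if (any(d == 0)) {
    w <- as.numeric(d == 0)
  } else {
    w <- 1 / d
  }
  w / sum(w)
}
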