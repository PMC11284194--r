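test_that("feature sets follow the rupture-specific matching criteria", {
  un <- select_matching_features(FALSE)
  ru <- select_matching_features(TRUE)
  expect_equal(nrow(un), 4)
  expect_equal(nrow(ru), 6)
  expect_setequal(un$name, c("gender", "age", "shape", "size_mm"))
  expect_true(all(c("hunt_hess", "fisher_grade") %in% ru$name))
  expect_true(all(un$weight == 1) && all(ru$weight == 1))
  expect_identical(spec_k(un), 3L)
  expect_identical(spec_k(ru), 3L)
})

test_that("encoding follows the codebook and preserves row order", {
  cases <- tiny_cases()
  m <- encode_features(cases, select_matching_features(FALSE))
  expect_identical(rownames(m), cases$id)
  expect_equal(unname(m[, "gender"]), c(1, 0, 1, 0, 1, 1))  # female = 1
  expect_equal(unname(m[, "shape"]), c(0, 1, 0, 1, 0, 0))   # irregular = 1
  expect_equal(unname(m[, "age"]), cases$age)
  # ordinal grades pass through as their integer level
  rupt <- dplyr::mutate(cases, ruptured = TRUE, hunt_hess = 3L, fisher_grade = 2L)
  mr <- encode_features(rupt, select_matching_features(TRUE))
  expect_equal(unname(mr[, "hunt_hess"]), rep(3, 6))
  # missing values and unknown categories are named errors
  bad <- cases; bad$age[2] <- NA
  expect_error(encode_features(bad, select_matching_features(FALSE)),
               "c02", class = "aneumatch_missing_error")
  bad2 <- cases; bad2$gender[1] <- "other"
  expect_error(encode_features(bad2, select_matching_features(FALSE)),
               "other", class = "aneumatch_schema_error")
})

test_that("z-score standardization yields unit-variance columns and flags constants", {
  expect_equal(unname(zscore_standardize(matrix(1:3))[, 1]), c(-1, 0, 1))
  expect_warning(z <- zscore_standardize(cbind(a = c(5, 5, 5), b = 1:3)),
                 "constant", ignore.case = TRUE)
  expect_equal(unname(z[, "a"]), c(0, 0, 0))
  expect_identical(unname(attr(z, "constant")), c(TRUE, FALSE))
  set.seed(21)
  m <- matrix(rnorm(200, 10, 4), 50, 4)
  z <- zscore_standardize(m)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  expect_error(zscore_standardize(matrix(1, 1, 2)), class = "aneumatch_domain_error")
})

test_that("weighted distance matches its formula and the metric axioms", {
  expect_equal(weighted_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(weighted_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(weighted_distance(c(1, 2), c(0, 0), weights = c(4, 1)), sqrt(8))
  expect_error(weighted_distance(1:3, 1:2), class = "aneumatch_domain_error")
  expect_error(weighted_distance(1:2, 1:2, weights = c(-1, 1)),
               class = "aneumatch_domain_error")
  set.seed(31)
  for (i in 1:300) {
    x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
    dxy <- weighted_distance(x, y); dyx <- weighted_distance(y, x)
    expect_identical(dxy, dyx)                                   # symmetry
    expect_gte(dxy, 0)                                           # non-negativity
    expect_lte(dxy, weighted_distance(x, z) + weighted_distance(z, y) + 1e-12)
  }
  # zero iff equal on positively weighted coordinates
  expect_equal(weighted_distance(c(1, 9), c(1, 4), weights = c(1, 0)), 0)
  expect_gt(weighted_distance(c(1, 9), c(1.1, 9)), 0)
})

test_that("scale and shift of a raw feature leave standardized distances unchanged", {
  set.seed(41)
  m <- cbind(age = rnorm(30, 55, 10), size = rlnorm(30, 2, 0.5))
  z1 <- zscore_standardize(m)
  m2 <- m; m2[, "size"] <- m[, "size"] * 37 + 5
  z2 <- zscore_standardize(m2)
  d1 <- as.vector(dist(z1)); d2 <- as.vector(dist(z2))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("k-NN retrieval agrees with a brute-force sort and weights by variant", {
  set.seed(51)
  pool <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("r%02d", 1:10), NULL))
  q <- rnorm(4)
  ns <- knn_neighbors(q, pool, k = 3)
  ora <- oracle_knn(q, pool, rep(1, 4), 3)
  expect_identical(ns$reference_id, ora$reference_id)
  expect_equal(ns$raw_distance, ora$raw_distance)
  expect_true(all(diff(ns$raw_distance) >= 0))
  expect_equal(ns$weight, rep(1 / 3, 3))
  # variant agreement on the neighbour set
  ns2 <- knn_neighbors(q, pool, k = 3, variant = "inverse_distance")
  ns3 <- knn_neighbors(q, pool, k = 3, variant = "minmax_inverse")
  expect_identical(ns2$reference_id, ns$reference_id)
  expect_identical(ns3$reference_id, ns$reference_id)
  expect_equal(sum(ns2$weight), 1)
  expect_equal(sum(ns3$weight), 1)
  # the pool minimum min-max-rescales to 0, absorbing all variant-3 weight
  expect_equal(ns3$weight, c(1, 0, 0))
})

test_that("neighbour weights follow the stated inverse and min-max formulas", {
  # distances (1, 2, 4) -> inverse weights (4/7, 2/7, 1/7)
  pool <- matrix(c(1, 2, 4), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  ns <- knn_neighbors(0, pool, k = 3, variant = "inverse_distance")
  expect_equal(ns$weight, c(4 / 7, 2 / 7, 1 / 7))
  # pool distances {2, 4, 6} min-max rescale to {0, 0.5, 1}
  d <- c(2, 4, 6)
  expect_equal((d - min(d)) / (max(d) - min(d)), c(0, 0.5, 1))
  # zero raw distance absorbs all inverse-distance weight
  pool0 <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  ns0 <- knn_neighbors(0, pool0, k = 3, variant = "inverse_distance")
  expect_equal(ns0$weight, c(1, 0, 0))
  # all-equal pool distances: min-max undefined, equal weights
  poole <- matrix(c(3, 3, 3), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  nse <- knn_neighbors(0, poole, k = 3, variant = "minmax_inverse")
  expect_equal(nse$weight, rep(1 / 3, 3))
  expect_error(knn_neighbors(0, matrix(numeric(0), 0, 1), k = 3),
               class = "aneumatch_domain_error")
})

test_that("small pools return min(k, pool size) neighbours", {
  pool <- matrix(c(1, 2), ncol = 1, dimnames = list(c("a", "b"), NULL))
  ns <- knn_neighbors(0, pool, k = 3)
  expect_equal(nrow(ns), 2)
  expect_equal(ns$weight, rep(0.5, 2))
})
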