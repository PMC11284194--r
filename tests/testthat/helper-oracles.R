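# Independent oracles, implemented from first principles and kept free of
# the package's own code paths.

# brute-force k-NN: all pool distances by an explicit per-row loop and sort
oracle_knn <- function(query, pool, weights, k) {
  d <- vapply(seq_len(nrow(pool)),
              function(i) sqrt(sum(weights * (query - pool[i, ])^2)),
              numeric(1))
  ord <- order(d, rownames(pool))
  sel <- ord[seq_len(min(k, nrow(pool)))]
  data.frame(reference_id = rownames(pool)[sel], raw_distance = d[sel])
}

# two-sided Fisher p by full enumeration of tables with the observed margins,
# point probabilities from binomial coefficients
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- r1 + r2
  a_vals <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, a_vals) * choose(r2, c1 - a_vals) / choose(N, c1)
  obs <- pr[a_vals == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all C(n, nA) group labelings
oracle_mwu_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# permutation two-sided p for the pooled t statistic
oracle_perm_t_p <- function(a, b, n_perm = 10000) {
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  vals <- c(a, b); na <- length(a)
  t_obs <- abs(pooled_t(a, b))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(vals), na)
    if (abs(pooled_t(vals[idx], vals[-idx])) >= t_obs) hits <- hits + 1L
  }
  hits / n_perm
}

# 99% binomial (normal-approximation) band around a nominal rate
binom99_band <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(lower = p - 2.576 * se, upper = p + 2.576 * se)
}

# tiny hand-built case table: two AOIs and four references in one stratum
tiny_cases <- function() {
  tibble::tibble(
    id = sprintf("c%02d", 1:6),
    arm = c("AIA", "AIA", "PA", "PA", "PA", "PA"),
    gender = c("female", "male", "female", "male", "female", "female"),
    age = c(50, 60, 51, 61, 70, 40),
    ruptured = FALSE,
    hunt_hess = NA_integer_,
    fisher_grade = NA_integer_,
    size_mm = c(6, 9, 6.2, 9.1, 12, 4),
    shape = c("regular", "irregular", "regular", "irregular", "regular", "regular"),
    fda_angle = c(45, 50, 40, 55, 60, 30)
  )
}
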