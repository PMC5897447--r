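# Independent oracles used to check the package's GP and rank-product
# arithmetic. These deliberately avoid the package's own code paths: dense
# linear algebra via solve()/determinant(), full joint enumeration for the
# rank-product null.

# log N(y | 0, K) by explicit inverse and determinant
oracle_mvn_logdens <- function(y, K) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(K) %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    0.5 * n * log(2 * pi)
}

# leave-one-out predictive log densities by n explicit refits at fixed
# hyperparameters; K includes the noise variance on the diagonal
oracle_loo_refit <- function(y, K) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    Kt <- K[-i, -i, drop = FALSE]
    k <- K[i, -i]
    w <- solve(Kt, y[-i])
    mu <- sum(k * w)
    v <- K[i, i] - sum(k * solve(Kt, k))
    dnorm(y[i], mu, sqrt(v), log = TRUE)
  }, numeric(1))
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exhaustive rank-product null over the full joint space of per-pair rank
# permutations: for each of the (m!)^k equally likely configurations, count
# proteins with null RP <= each observed RP, and average. Returns the
# expected counts (the numerator of pfp).
oracle_rp_expected <- function(rp_obs, m, k) {
  perms <- all_perms(m)
  idx <- expand.grid(rep(list(seq_len(nrow(perms))), k))
  counts <- numeric(length(rp_obs))
  for (r in seq_len(nrow(idx))) {
    ranks <- sapply(seq_len(k), function(j) perms[idx[r, j], ])
    rp_null <- exp(rowSums(log(ranks)) / k)
    counts <- counts + vapply(rp_obs, function(t)
      sum(rp_null <= t + 1e-9), numeric(1))
  }
  counts / nrow(idx)
}

# Spearman rho from first principles: Pearson correlation of the ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# step-up BH by direct arithmetic
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}
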