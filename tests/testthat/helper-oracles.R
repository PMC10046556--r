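# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package code paths.

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# mean finite off-diagonal distance (ordered pairs)
oracle_char_path <- function(A) {
  D <- oracle_floyd_warshall(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# global efficiency from the Floyd-Warshall oracle
oracle_global_eff <- function(A) {
  D <- oracle_floyd_warshall(A)
  n <- nrow(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# local efficiency by explicitly rebuilding every neighbour subgraph
oracle_local_eff <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_global_eff(A[nb, nb, drop = FALSE])
  }
  vals
}

# average clustering by counting triangles over all node triples
oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (u in seq_along(nb)) {
      for (v in seq_len(u - 1)) {
        if (A[nb[u], nb[v]] != 0) tri <- tri + 1
      }
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

# Greenhouse-Geisser epsilon via the eigenvalues of the double-centered
# covariance matrix of the k repeated measures (Box's formulation);
# algebraically equivalent to the contrast-based estimate but coded
# independently of it
oracle_box_epsilon <- function(M) {
  k <- ncol(M)
  S <- stats::cov(M)
  J <- diag(k) - matrix(1 / k, k, k)
  Sc <- J %*% S %*% J
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(abs(lam), 1)]
  min(1, max(1 / (k - 1), sum(lam)^2 / ((k - 1) * sum(lam^2))))
}

# exact power of the two-sided paired t-test at effect size delta (in SD
# units of the paired differences)
oracle_paired_t_power <- function(delta, n, alpha = 0.05) {
  df <- n - 1
  ncp <- delta * sqrt(n)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

# random undirected adjacency matrix at a given edge probability
random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.integer(stats::runif(length(ut)) < p)
  A + t(A)
}

# analytic phase series with a constant lag: returns list(zx, zy)
const_lag_pair <- function(n, lag, f = 0.01) {
  t <- seq_len(n)
  list(zx = exp(1i * 2 * pi * f * t),
       zy = exp(1i * (2 * pi * f * t - lag)))
}
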