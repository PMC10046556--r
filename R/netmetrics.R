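#' Pooled median threshold for a group of connectivity matrices
#'
#' Pools the upper-triangle values of all matrices of one group (by default
#' all scenarios of one test session of one subject) and returns their
#' median. Binarizing every scenario of a test at this common threshold
#' keeps graph densities comparable across scenarios within the test, which
#' is the comparison the analysis makes.
#'
#' @param matrices List of `connectivity_matrix` objects sharing channel
#'   labels.
#' @return Scalar threshold.
#' @export
median_threshold <- function(matrices) {
  if (!length(matrices)) stop("empty group: no matrices to pool")
  labs <- matrices[[1]]$channel_labels
  vals <- unlist(lapply(matrices, function(m) {
    if (!identical(m$channel_labels, labs)) {
      stop("all matrices in a group must share channel labels")
    }
    m$values[upper.tri(m$values)]
  }))
  stats::median(vals)
}

#' Binarize a connectivity matrix at a threshold
#'
#' Edges are entries strictly greater than the threshold, so an all-ties
#' matrix yields an empty graph and a pooled median yields a density near
#' 0.5 within the pooled group.
#'
#' @param cm A `connectivity_matrix`.
#' @param threshold Scalar threshold, e.g. from [median_threshold()].
#' @return Object of class `binary_graph`: list with logical `adjacency`,
#'   `threshold`, `density`, `condition`, `channel_labels`.
#' @export
binarize <- function(cm, threshold) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  A <- cm$values > threshold
  diag(A) <- FALSE
  n <- nrow(A)
  structure(
    list(adjacency = A, threshold = threshold,
         density = sum(A) / (n * (n - 1)),
         condition = cm$condition, channel_labels = cm$channel_labels),
    class = "binary_graph"
  )
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param adjacency Logical or 0/1 symmetric matrix; the diagonal is cleared.
#' @param condition Optional metadata.
#' @return A `binary_graph`.
#' @export
binary_graph <- function(adjacency, condition = NULL) {
  A <- adjacency != 0
  if (!isTRUE(all(A == t(A)))) stop("adjacency must be symmetric")
  diag(A) <- FALSE
  n <- nrow(A)
  labels <- rownames(A) %||% paste0("n", seq_len(n))
  dimnames(A) <- list(labels, labels)
  structure(
    list(adjacency = A, threshold = NA_real_,
         density = sum(A) / (n * (n - 1)),
         condition = condition, channel_labels = labels),
    class = "binary_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first search from every node; unreachable pairs are `Inf`.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return N x N numeric matrix of hop distances, zero diagonal.
#' @export
shortest_path_lengths <- function(g) {
  A <- if (inherits(g, "binary_graph")) g$adjacency else (g != 0)
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(D[s, nxt])]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over ordered node pairs,
#' \eqn{L = \frac{1}{N(N-1)} \sum_{i} \sum_{j \ne i} \min\{L_{ij}\}}.
#' Unreachable pairs are excluded from the average (and counted), so a
#' rarely disconnected graph does not yield an infinite L.
#'
#' @param g A `binary_graph`, adjacency matrix, or a precomputed distance
#'   matrix from [shortest_path_lengths()] (square with zero diagonal).
#' @return Scalar L with attribute `unreachable_pairs` (count of ordered
#'   pairs excluded).
#' @export
char_path_length <- function(g) {
  D <- as_dist_matrix(g)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(finite)) stop("no finite node pairs: graph has no edges")
  n_unreach <- sum(!finite)
  if (n_unreach > 0) {
    warning(sprintf("%d unreachable ordered pair(s) excluded from L", n_unreach))
  }
  structure(mean(off[finite]), unreachable_pairs = n_unreach)
}

as_dist_matrix <- function(g) {
  if (inherits(g, "binary_graph")) return(shortest_path_lengths(g))
  stopifnot(is.matrix(g))
  off <- g[row(g) != col(g)]
  # an adjacency matrix only holds 0/1 off-diagonal; hop distances exceed 1
  # or are Inf as soon as the graph is not complete
  if (is.logical(g) || all(off %in% c(0, 1))) return(shortest_path_lengths(g))
  g
}

#' Global efficiency
#'
#' Mean reciprocal shortest-path length over ordered pairs,
#' \eqn{E_{global} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/\min\{L_{ij}\}};
#' unreachable pairs contribute 0, so no exclusion is needed.
#'
#' @param g A `binary_graph`, adjacency matrix, or distance matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  D <- as_dist_matrix(g)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 nodes")
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (the node itself excluded),
#' \eqn{E_{local} = \frac{1}{N}\sum_i E_{global}(G_i)}. Nodes with fewer
#' than two neighbours score 0.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return list with `per_node` (length-N vector) and `mean`.
#' @export
local_efficiency <- function(g) {
  A <- if (inherits(g, "binary_graph")) g$adjacency else (g != 0)
  n <- nrow(A)
  per_node <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    if (length(nb) < 2L) next
    per_node[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  names(per_node) <- rownames(A)
  list(per_node = per_node, mean = mean(per_node))
}

#' Average clustering coefficient
#'
#' Per-node transitivity \eqn{2E_i / (k_i (k_i - 1))}, where \eqn{k_i} is
#' the degree of node i and \eqn{E_i} the number of edges among its
#' neighbours; degree-0/1 nodes score 0. Returns the node average,
#' \eqn{C = \frac{1}{N}\sum_i 2E_i/(k_i(k_i-1))}.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  A <- if (inherits(g, "binary_graph")) g$adjacency else (g != 0)
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2L) next
    Ei <- sum(A[nb, nb]) / 2
    ci[i] <- 2 * Ei / (k * (k - 1))
  }
  mean(ci)
}

#' Degree-preserving surrogate ensemble
#'
#' Generates `n` randomized surrogates of a graph by degree-preserving edge
#' swaps (10 x |edges| attempted swaps per surrogate) and returns the mean
#' clustering coefficient and characteristic path length of the ensemble —
#' the normalizers C_random and L_random for small-worldness. If the degree
#' sequence admits no swap at all (e.g. a star), density-matched
#' Erdős–Rényi surrogates are used instead, with a warning.
#'
#' @param g A `binary_graph` or adjacency matrix with at least one edge.
#' @param n Number of surrogates (default 100).
#' @param seed Integer seed for the ensemble.
#' @return list with `C_random`, `L_random`, `C_each`, `L_each`, `n`,
#'   `fallback` (logical: density-matched surrogates used).
#' @export
surrogate_ensemble <- function(g, n = 100, seed = 1L) {
  A <- if (inherits(g, "binary_graph")) g$adjacency else (g != 0)
  m_edges <- sum(A) / 2
  if (m_edges < 1) stop("graph has no edges; surrogates undefined")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  C_each <- numeric(n)
  L_each <- numeric(n)
  any_swap <- FALSE
  for (k in seq_len(n)) {
    S <- rewire_preserving_degree(A, attempts = 10L * m_edges)
    if (attr(S, "swaps") > 0) any_swap <- TRUE
    C_each[k] <- clustering_coefficient(S)
    L_each[k] <- suppressWarnings(as.numeric(char_path_length(S)))
  }
  fallback <- FALSE
  if (!any_swap) {
    warning("degree sequence admits no rewiring; falling back to density-matched random graphs")
    fallback <- TRUE
    nn <- nrow(A)
    for (k in seq_len(n)) {
      S <- sample_gnm_adjacency(nn, m_edges)
      C_each[k] <- clustering_coefficient(S)
      L_each[k] <- suppressWarnings(as.numeric(char_path_length(S)))
    }
  }
  list(C_random = mean(C_each), L_random = mean(L_each),
       C_each = C_each, L_each = L_each, n = n, fallback = fallback)
}

# Maslov–Sneppen double edge swap on an adjacency matrix
rewire_preserving_degree <- function(A, attempts) {
  edges <- which(upper.tri(A) & A, arr.ind = TRUE)
  m <- nrow(edges)
  swaps <- 0L
  if (m >= 2L) {
    for (t in seq_len(attempts)) {
      pick <- sample.int(m, 2L)
      a <- edges[pick[1L], 1L]; b <- edges[pick[1L], 2L]
      c <- edges[pick[2L], 1L]; d <- edges[pick[2L], 2L]
      # randomize orientation: (a,b),(c,d) -> (a,d),(c,b)  or  (a,c),(b,d)
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (a == d || c == b || a == c || b == d) next
      if (A[a, d] || A[c, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c, d] <- A[d, c] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c, b] <- A[b, c] <- TRUE
      edges[pick[1L], ] <- sort(c(a, d))
      edges[pick[2L], ] <- sort(c(c, b))
      swaps <- swaps + 1L
    }
  }
  attr(A, "swaps") <- swaps
  A
}

# uniform random graph with a fixed number of edges
sample_gnm_adjacency <- function(n, m) {
  A <- matrix(FALSE, n, n)
  ut <- which(upper.tri(A))
  on_idx <- sample(ut, m)
  A[on_idx] <- TRUE
  A | t(A)
}

#' Watts–Strogatz small-world test graph
#'
#' Ring lattice of `n` nodes each wired to its `k` nearest neighbours
#' (`k/2` per side), with each lattice edge's far endpoint rewired to a
#' uniform random node with probability `p` (self-loops and duplicate edges
#' rejected). Canonical positive control for the small-world criterion.
#'
#' @param n Nodes. @param k Even lattice degree. @param p Rewiring
#'   probability. @param seed Integer seed.
#' @return A `binary_graph`.
#' @export
sample_ws_graph <- function(n = 24, k = 4, p = 0.1, seed = 1L) {
  if (k %% 2 != 0) stop("k must be even")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(k / 2)) {
      t <- ((i - 1 + j) %% n) + 1
      A[i, t] <- A[t, i] <- TRUE
    }
  }
  edges <- which(upper.tri(A) & A, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    if (stats::runif(1) < p) {
      i <- edges[e, 1L]
      new_t <- sample.int(n, 1L)
      if (new_t == i || A[i, new_t]) next
      j <- edges[e, 2L]
      A[i, j] <- A[j, i] <- FALSE
      A[i, new_t] <- A[new_t, i] <- TRUE
    }
  }
  binary_graph(A)
}

#' Small-worldness from surrogate normalizers
#'
#' \eqn{\gamma = C / C_{random}}, \eqn{\lambda = L / L_{random}},
#' \eqn{\sigma = \gamma / \lambda}; a network is called small-world when
#' \eqn{\sigma > 1}.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param ensemble Result of [surrogate_ensemble()] on the same graph.
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
small_worldness <- function(g, ensemble) {
  if (ensemble$C_random <= 0 || ensemble$L_random <= 0) {
    stop("surrogate normalizers must be positive")
  }
  C <- clustering_coefficient(g)
  L <- suppressWarnings(as.numeric(char_path_length(g)))
  gamma <- C / ensemble$C_random
  lambda <- L / ensemble$L_random
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All graph metrics of a binary graph
#'
#' Convenience wrapper computing L, E_global, per-node and mean E_local, C,
#' and the surrogate-normalized gamma/lambda/sigma in one call.
#'
#' @param g A `binary_graph`.
#' @param n_surrogates Surrogate count for the small-world normalizers
#'   (default 100); set to 0 to skip gamma/lambda/sigma.
#' @param seed Seed for the surrogate ensemble.
#' @return Object of class `graph_metrics`.
#' @export
graph_metrics <- function(g, n_surrogates = 100, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  D <- shortest_path_lengths(g)
  L <- suppressWarnings(char_path_length(D))
  eloc <- local_efficiency(g)
  C <- clustering_coefficient(g)
  gls <- list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  if (n_surrogates > 0 && sum(g$adjacency) > 0) {
    ens <- surrogate_ensemble(g, n = n_surrogates, seed = seed)
    if (ens$C_random > 0 && ens$L_random > 0) {
      gls <- small_worldness(g, ens)
    }  # else: normalizers undefined (e.g. triangle-free surrogates) -> NA
  }
  structure(
    list(L = as.numeric(L), E_global = global_efficiency(D),
         E_local_per_node = eloc$per_node, E_local_mean = eloc$mean,
         C = C, gamma = gls$gamma, lambda = gls$lambda, sigma = gls$sigma,
         n_surrogates = n_surrogates,
         unreachable_pairs = attr(L, "unreachable_pairs"),
         condition = g$condition),
    class = "graph_metrics"
  )
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("<graph_metrics> L=%.3f E_global=%.3f E_local=%.3f C=%.3f gamma=%.3f lambda=%.3f sigma=%.3f\n",
              x$L, x$E_global, x$E_local_mean, x$C, x$gamma, x$lambda, x$sigma))
  invisible(x)
}
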