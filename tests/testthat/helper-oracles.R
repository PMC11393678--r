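# Independent brute-force oracles used to cross-check the implementation.

# Ridge with unpenalized intercept via the augmented normal equations
# (Xa' Xa + diag(0, lambda, ..., lambda))^-1 Xa' y, Xa = [1 X].
oracle_ridge <- function(X, y, lambda) {
  Xa <- cbind(1, X)
  D <- diag(c(0, rep(lambda, ncol(X))))
  as.numeric(solve(crossprod(Xa) + D, crossprod(Xa, y)))
}

# All set partitions of 1..n (n small), as lists of membership vectors.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# Exhaustive modularity maximization on a weighted undirected igraph.
# Ties are real (e.g. isolated nodes move freely), so all optimal
# community counts are returned alongside the count of the first optimum.
oracle_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  mods <- vapply(all_partitions(n),
                 function(p) igraph::modularity(g, p, weights = w),
                 numeric(1))
  best <- max(mods)
  counts <- vapply(all_partitions(n), function(p) length(unique(p)), integer(1))
  optimal_counts <- sort(unique(counts[mods > best - 1e-9]))
  list(modularity = best,
       n_communities = counts[which.max(mods)],
       optimal_counts = optimal_counts)
}

# Exhaustive weighted betweenness (directed), distance = 1/weight:
# enumerate all simple paths between every ordered pair, find the shortest
# total distance, and count the fraction passing through each node.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  names <- igraph::V(g)$name
  bc <- setNames(rep(0, n), names)
  dist_of <- function(path) {
    d <- 0
    for (i in seq_len(length(path) - 1)) {
      eid <- igraph::get_edge_ids(g, c(path[i], path[i + 1]))
      if (eid == 0) return(Inf)
      d <- d + 1 / igraph::E(g)$weight[eid]
    }
    d
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- igraph::all_simple_paths(g, from = s, to = t, mode = "out")
    if (!length(paths)) next
    dists <- vapply(paths, dist_of, numeric(1))
    dmin <- min(dists)
    if (!is.finite(dmin)) next
    short <- paths[abs(dists - dmin) < 1e-12]
    thru <- rep(0, n)
    for (p in short) {
      inner <- setdiff(as.integer(p), c(s, t))
      thru[inner] <- thru[inner] + 1
    }
    bc <- bc + thru / length(short)
  }
  bc
}

# Noiseless counts from a known production model: S random full rank,
# U_i = (A0_i + sum_{j != i} A_ij S_j) / beta. Recovers (A0, A) exactly
# under linear regression. Intercepts are shifted upward where needed so
# U stays positive (no clipping, which would break exactness); the
# adjusted intercepts are returned alongside the counts.
make_production_counts <- function(A0, A, n_cells, beta = 1, seed = 1) {
  M <- length(A0)
  set.seed(seed)
  S <- matrix(runif(n_cells * M, 0.5, 3), n_cells, M)
  raw <- S %*% t(A)
  A0 <- A0 + pmax(0, 0.1 - apply(raw, 2, min) - A0)
  U <- sweep(raw, 2L, A0, `+`) / beta
  counts <- splicing_counts(U, S, ordering = seq_len(n_cells),
                            gene_names = paste0("g", seq_len(M)))
  list(counts = counts, A0 = A0, A = A)
}

# Counts at exact splicing/degradation balance: U_i = gamma_i S_i / beta.
make_balance_counts <- function(gammas, n_cells, beta = 1, seed = 1) {
  M <- length(gammas)
  set.seed(seed)
  S <- matrix(runif(n_cells * M, 0.5, 3), n_cells, M)
  U <- sweep(S, 2L, gammas / beta, `*`)
  splicing_counts(U, S, ordering = seq_len(n_cells),
                  gene_names = paste0("g", seq_len(M)))
}

# Small random weighted graphs for oracle comparisons.
random_weighted_graph <- function(n, p = 0.5, directed = FALSE) {
  repeat {
    adj <- matrix(runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    if (!directed) adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    if (any(adj)) break
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = if (directed) "directed" else "undirected")
  igraph::V(g)$name <- letters[seq_len(n)]
  igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.2, 2), 3)
  g
}
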