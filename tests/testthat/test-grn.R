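toy_fit <- function(A, genes = rownames(A)) {
  splicing_fit(genes, rep(0, nrow(A)), A, 1, rep(1, nrow(A)))
}

test_that("edges are rescaled by sender expression and silent senders drop out", {
  A <- matrix(c(0, 1, -2,
                0.5, 0, 1,
                -1, 2, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expr <- c(a = 2, b = 1, c = 0)  # min-max: a -> 1, b -> 0.5, c -> 0
  g <- build_grn(toy_fit(A), expr, edge_threshold = 0)
  el <- igraph::as_data_frame(g)
  # all of c's outgoing edges have weight 0 and are dropped
  expect_false("c" %in% el$from)
  # weight(j -> i) = A[i, j] * scaled(j), hand-computed
  w_ab <- el$raw[el$from == "a" & el$to == "b"]
  expect_equal(w_ab, 0.5 * 1)           # A[b, a] * scaled(a)
  w_ba <- el$raw[el$from == "b" & el$to == "a"]
  expect_equal(w_ba, 1 * 0.5)           # A[a, b] * scaled(b)
  expect_equal(el$sign[el$from == "a" & el$to == "c"], "inhibition")
  # quantile threshold at 0.5 keeps only the larger half of |weights|
  g2 <- build_grn(toy_fit(A), expr, edge_threshold = 0.5)
  kept <- abs(igraph::E(g2)$raw)
  all_w <- abs(el$raw)
  expect_true(all(kept >= quantile(all_w, 0.5)))

  # zero interaction matrix -> empty edge set, nodes retained
  g0 <- build_grn(toy_fit(matrix(0, 3, 3, dimnames = dimnames(A))), expr)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 3)
})

test_that("genes excluded from a window appear as isolated nodes when embedded", {
  A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit <- splicing_fit(c("a", "b"), c(0, 0), A, 1, c(1, 1),
                      excluded_genes = "z")
  g <- build_grn(fit, c(a = 1, b = 2, z = 0), all_genes = c("a", "b", "z"),
                 edge_threshold = 0)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::degree(g, "z"), c(z = 0))
})

test_that("community detection handles canonical graphs", {
  # two disconnected triangles -> 2 communities under both algorithms
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::E(g)$weight <- 1
  for (alg in c("greedy_modularity", "girvan_newman")) {
    expect_equal(detect_communities(g, alg)$n_communities, 2)
  }
  # complete graph K5 -> 1 community under greedy modularity
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$weight <- 1
  expect_equal(detect_communities(k5, "greedy_modularity")$n_communities, 1)
  # empty graph -> 0; isolated nodes each count
  empty <- igraph::make_empty_graph(0)
  expect_equal(detect_communities(empty)$n_communities, 0)
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("x", "y", "z")
  expect_equal(detect_communities(iso)$n_communities, 3)
})

test_that("barbell graph splits into its two cliques (exhaustive oracle)", {
  # two K4 joined by one edge
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- letters[1:8]
  igraph::E(g)$weight <- 1
  oracle <- oracle_best_modularity(g)
  expect_equal(oracle$n_communities, 2)
  for (alg in c("greedy_modularity", "girvan_newman")) {
    expect_equal(detect_communities(g, alg)$n_communities, 2)
  }
  # removing the bridge leaves two disconnected cliques; the count cannot
  # decrease and still matches the exhaustive oracle
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("a", "e")))
  got2 <- detect_communities(g2, "greedy_modularity")
  oracle2 <- oracle_best_modularity(g2)
  expect_true(got2$n_communities %in% oracle2$optimal_counts)
  expect_gte(got2$n_communities, 2)
})

test_that("community counts match the exhaustive modularity oracle on small graphs", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    g <- random_weighted_graph(n, p = 0.6)
    oracle <- oracle_best_modularity(g)
    got <- detect_communities(g, "greedy_modularity")
    # the found partition attains the brute-force optimum, and its count is
    # among the counts of the (possibly tied) optimal partitions
    expect_equal(got$modularity, oracle$modularity, tolerance = 1e-9,
                 info = sprintf("rep %d (n = %d)", rep, n))
    expect_true(got$n_communities %in% oracle$optimal_counts,
                info = sprintf("rep %d (n = %d)", rep, n))
  }
})

test_that("community count is invariant under global weight rescaling", {
  set.seed(14)
  g <- random_weighted_graph(6, p = 0.5)
  base <- detect_communities(g, "greedy_modularity")$n_communities
  g2 <- g
  igraph::E(g2)$weight <- igraph::E(g2)$weight * 7.3
  expect_equal(detect_communities(g2, "greedy_modularity")$n_communities, base)
  expect_equal(detect_communities(g2, "girvan_newman")$n_communities,
               detect_communities(g, "girvan_newman")$n_communities)
})

test_that("betweenness ranking matches canonical cases and the path oracle", {
  # star: hub first
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  igraph::E(star)$weight <- 1
  expect_equal(betweenness_ranking(star, 1)$gene, "hub")

  # path a - b - c: b first
  path <- igraph::make_graph(~ a - b, b - c)
  igraph::E(path)$weight <- 1
  expect_equal(betweenness_ranking(path, 1)$gene, "b")
  expect_error(betweenness_ranking(path, 10), "exceeds")

  # 5-node weighted digraphs vs exhaustive all-pairs path enumeration
  set.seed(15)
  for (rep in 1:6) {
    g <- random_weighted_graph(5, p = 0.5, directed = TRUE)
    oracle <- oracle_betweenness(g)
    got <- betweenness_ranking(g, 5)
    expect_equal(got$betweenness,
                 unname(oracle[got$gene]), tolerance = 1e-10,
                 info = sprintf("rep %d", rep))
  }
})

test_that("edge weight distribution summarises |weights| deterministically", {
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - a)
  igraph::E(g)$weight <- c(1, 2, 3, 4)
  s <- edge_weight_distribution(g)
  expect_equal(sort(s$values), c(1, 2, 3, 4))
  expect_equal(s$iqr, IQR(c(1, 2, 3, 4), type = 7))
  expect_equal(s$n_edges, 4)
  # all-equal weights -> IQR 0
  igraph::E(g)$weight <- rep(2, 4)
  expect_equal(edge_weight_distribution(g)$iqr, 0)
  expect_equal(edge_weight_distribution(igraph::make_empty_graph(0))$n_edges, 0)
})

test_that("community trajectory is constant for identical windows and follows components", {
  # two windows with identical fits -> identical counts
  A <- matrix(c(0, 1, 0, 0,
                1, 0, 0, 0,
                0, 0, 0, 1,
                0, 0, 1, 0), 4, 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  fit <- toy_fit(A)
  S <- matrix(rep(c(2, 2, 2, 2), each = 40), 40, 4,
              dimnames = list(NULL, letters[1:4]))
  counts <- splicing_counts(S * 0.5, S, ordering = 1:40, gene_names = letters[1:4])
  scan <- structure(list(
    fits = list(fit, fit),
    windows = tibble::tibble(window = 1:2, start = c(1, 21), end = c(20, 40),
                             position = c(10, 30),
                             cell_ids = list(counts$cell_ids[1:20],
                                             counts$cell_ids[21:40])),
    summary = tibble::tibble(window = 1:2)
  ), class = "lineage_scan")
  ct <- community_trajectory(scan, counts, algorithms = "greedy_modularity",
                             edge_threshold = 0)
  # a-b and c-d are disconnected pairs -> 2 communities, constant
  expect_equal(ct$n_communities, c(2, 2))
})

test_that("GRN exports round-trip as edge-list CSV and GraphML", {
  A <- matrix(c(0, 1.5, -0.5, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  g <- build_grn(toy_fit(A), c(a = 1, b = 2), edge_threshold = 0)
  csv <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  out <- write_grn(g, csv, gml)
  expect_true(file.exists(csv) && file.exists(gml))
  back <- read.csv(csv)
  expect_equal(nrow(back), igraph::ecount(g))
  expect_true(all(c("source", "target", "sign", "weight") %in% names(back)))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 2)
})
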