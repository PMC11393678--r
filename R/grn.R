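#' Build a directed GRN from a window fit
#'
#' The interaction matrix is read as a directed gene regulatory network:
#' edge j -> i carries the coefficient `A[i, j]`, rescaled by the expression
#' of the sender (regulator) gene so that a silent regulator activates no
#' edges. The sender scaling is the per-gene mean spliced expression in the
#' window, min-max scaled across genes; zero-weight edges are dropped, and
#' remaining edges whose absolute weight falls below the `edge_threshold`
#' quantile of the nonzero absolute weights are pruned.
#'
#' @param fit A [splicing_fit()].
#' @param mean_expression Named length-M vector of per-gene mean spliced
#'   expression in the window (raw scale; min-max scaling is applied here).
#' @param edge_threshold Quantile (in \[0, 1)) of nonzero absolute weights
#'   below which edges are dropped. Default 0.75.
#' @param all_genes Optional superset of gene names for the node set.
#'   Genes absent from the fit (e.g. excluded in this window for all-zero
#'   spliced counts) become isolated nodes with no incoming or outgoing
#'   edges; `mean_expression` must cover them as well.
#' @return A directed `igraph` graph whose edges carry attributes `weight`
#'   (absolute rescaled magnitude), `raw` (signed weight) and `sign`
#'   (`"activation"` or `"inhibition"`). All genes remain as nodes, so
#'   isolated genes are preserved.
#' @export
build_grn <- function(fit, mean_expression, edge_threshold = 0.75,
                      all_genes = NULL) {
  stopifnot(inherits(fit, "splicing_fit"))
  genes <- all_genes %||% fit$gene_names
  if (!all(fit$gene_names %in% genes)) {
    abort("`all_genes` must contain every fitted gene.")
  }
  M <- length(genes)
  expr <- mean_expression[genes]
  if (any(is.na(expr))) abort("`mean_expression` must cover every gene.")
  rng <- range(expr)
  scaled <- if (rng[2] == rng[1]) rep(1, M) else (expr - rng[1]) / (rng[2] - rng[1])
  names(scaled) <- genes

  A <- matrix(0, M, M, dimnames = list(genes, genes))
  A[fit$gene_names, fit$gene_names] <- fit$interaction_matrix
  W <- sweep(A, 2L, scaled, `*`)  # weight(j -> i) = A[i, j] * scaled[j]
  edges <- tibble::tibble(
    from = rep(genes, times = M),
    to = rep(genes, each = M),
    raw = as.vector(t(W))
  ) |>
    dplyr::filter(.data$from != .data$to, .data$raw != 0)

  if (nrow(edges)) {
    cut <- quantile(abs(edges$raw), edge_threshold, names = FALSE)
    edges <- dplyr::filter(edges, abs(.data$raw) >= cut)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = genes)
  )
  igraph::E(g)$raw <- edges$raw
  igraph::E(g)$weight <- abs(edges$raw)
  igraph::E(g)$sign <- ifelse(edges$raw > 0, "activation", "inhibition")
  igraph::V(g)$expression <- unname(scaled)
  g
}

# undirected |weight| projection used by the modularity algorithms;
# antiparallel edge pairs are collapsed by summing their magnitudes.
as_undirected_weighted <- function(graph) {
  igraph::as_undirected(
    graph, mode = "collapse",
    edge.attr.comb = list(weight = "sum", raw = "ignore", sign = "ignore")
  )
}

#' Community structure of a window GRN
#'
#' The directed graph is projected to an undirected graph with edge weight
#' equal to the absolute rescaled weight (antiparallel edges summed).
#' `greedy_modularity` is Clauset-Newman-Moore greedy modularity
#' maximization; `girvan_newman` divisively removes the edge of highest
#' betweenness (shortest paths measured with distance 1/weight) and keeps
#' the partition along the hierarchy with maximal weighted modularity.
#' Isolated nodes each count as their own community; a graph with no nodes
#' has count 0.
#'
#' @param graph A directed `igraph` from [build_grn()] (or any weighted
#'   graph).
#' @param algorithm `"greedy_modularity"` or `"girvan_newman"`.
#' @return A list with `membership` (named integer vector), `n_communities`
#'   and `modularity`.
#' @export
detect_communities <- function(graph,
                               algorithm = c("greedy_modularity", "girvan_newman")) {
  algorithm <- match.arg(algorithm)
  if (igraph::vcount(graph) == 0L) {
    return(list(membership = integer(0), n_communities = 0L, modularity = NA_real_))
  }
  und <- if (igraph::is_directed(graph)) as_undirected_weighted(graph) else graph
  w <- igraph::E(und)$weight %||% rep(1, igraph::ecount(und))
  if (igraph::ecount(und) == 0L) {
    memb <- seq_len(igraph::vcount(und))
    names(memb) <- igraph::V(und)$name
    return(list(membership = memb, n_communities = length(memb),
                modularity = NA_real_))
  }

  if (algorithm == "greedy_modularity") {
    cl <- igraph::cluster_fast_greedy(und, weights = w)
    # cut the agglomerative dendrogram at its best-modularity level
    # (evaluated explicitly: the stored cut can be off at near-ties)
    n_min <- length(unique(igraph::membership(cl)))
    memb <- igraph::membership(cl)
    mod <- igraph::modularity(und, memb, weights = w)
    for (k in seq_len(igraph::vcount(und))) {
      mk <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = k)),
                     error = function(e) NULL)
      if (is.null(mk)) next
      modk <- igraph::modularity(und, mk, weights = w)
      if (modk > mod + 1e-12) {
        memb <- mk
        mod <- modk
      }
    }
  } else {
    memb <- girvan_newman_membership(und)
    mod <- igraph::modularity(und, memb, weights = igraph::E(und)$weight)
  }
  memb <- setNames(as.integer(memb), igraph::V(und)$name)
  list(membership = memb, n_communities = length(unique(memb)), modularity = mod)
}

# Divisive Girvan-Newman: edge betweenness uses 1/weight as distance,
# modularity uses weight as strength; best-modularity level returned.
girvan_newman_membership <- function(und) {
  g <- und
  w_full <- igraph::E(und)$weight
  best_mod <- -Inf
  best_memb <- igraph::components(und)$membership
  repeat {
    memb <- igraph::components(g)$membership
    mod <- igraph::modularity(und, memb, weights = w_full)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_memb <- memb
    }
    if (igraph::ecount(g) == 0L) break
    eb <- igraph::edge_betweenness(g, weights = 1 / igraph::E(g)$weight)
    g <- igraph::delete_edges(g, which.max(eb))
  }
  best_memb
}

#' Genes ranked by betweenness centrality
#'
#' Weighted betweenness on the directed GRN, with shortest-path distance
#' `1/|weight|` (strong edges are short). Ties are broken alphabetically.
#'
#' @param graph A directed weighted `igraph`.
#' @param k Number of top genes to return (`k` <= number of nodes).
#' @return A tibble with columns `gene`, `betweenness`, sorted by rank.
#' @export
betweenness_ranking <- function(graph, k = igraph::vcount(graph)) {
  n <- igraph::vcount(graph)
  if (k > n) abort("`k` exceeds the number of nodes.")
  w <- igraph::E(graph)$weight
  bc <- igraph::betweenness(
    graph, directed = igraph::is_directed(graph),
    weights = if (length(w)) 1 / w else NULL
  )
  ord <- order(-bc, names(bc))
  tibble::tibble(
    gene = names(bc)[ord][seq_len(k)],
    betweenness = unname(bc[ord])[seq_len(k)]
  )
}

#' Edge-weight distribution of a GRN
#'
#' @param graph A weighted `igraph`.
#' @return A list with `values` (absolute edge weights), `iqr`
#'   (interquartile range, quantile type 7), `median` and `n_edges`. An
#'   edgeless graph yields an empty summary.
#' @export
edge_weight_distribution <- function(graph) {
  w <- abs(igraph::E(graph)$weight %||% numeric(0))
  if (!length(w)) {
    return(list(values = numeric(0), iqr = NA_real_, median = NA_real_, n_edges = 0L))
  }
  list(values = w, iqr = IQR(w, type = 7), median = stats::median(w), n_edges = length(w))
}

#' GRN community structure along the lineage
#'
#' Rebuilds the per-window GRN from each stored full-window fit (sender
#' scaling from that window's mean spliced expression) and applies the
#' requested community detection algorithm(s), tracing how modular the
#' regulatory network is along the lineage.
#'
#' @param scan A [scan_lineage()] result.
#' @param counts The [splicing_counts()] the scan was run on.
#' @param algorithms Character vector among `"greedy_modularity"`,
#'   `"girvan_newman"`.
#' @param edge_threshold Passed to [build_grn()].
#' @return A tibble with columns `window`, `position`, `algorithm`,
#'   `n_communities`, `modularity`, `n_edges`, `edge_iqr`.
#' @export
community_trajectory <- function(scan, counts,
                                 algorithms = c("greedy_modularity", "girvan_newman"),
                                 edge_threshold = 0.75) {
  stopifnot(inherits(scan, "lineage_scan"), inherits(counts, "splicing_counts"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  for (w in seq_len(nrow(scan$windows))) {
    fit <- scan$fits[[w]]
    if (is.null(fit)) next
    cells <- scan$windows$cell_ids[[w]]
    idx <- match(cells, counts$cell_ids)
    genes <- intersect(counts$gene_names, union(fit$gene_names, fit$excluded_genes))
    expr <- colMeans(counts$spliced[idx, genes, drop = FALSE])
    g <- build_grn(fit, expr, edge_threshold = edge_threshold, all_genes = genes)
    ew <- edge_weight_distribution(g)
    for (alg in algorithms) {
      com <- detect_communities(g, alg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        window = scan$windows$window[w],
        position = scan$windows$position[w],
        algorithm = alg,
        n_communities = com$n_communities,
        modularity = com$modularity,
        n_edges = ew$n_edges,
        edge_iqr = ew$iqr
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a window GRN to disk
#'
#' Writes the edge list as CSV (`source`, `target`, `sign`, `weight`) and,
#' optionally, GraphML.
#'
#' @param graph A GRN from [build_grn()].
#' @param csv Path for the edge-list CSV.
#' @param graphml Optional path for a GraphML export.
#' @return Invisibly, the edge tibble written.
#' @export
write_grn <- function(graph, csv, graphml = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  out <- tibble::tibble(
    source = el$from %||% character(0),
    target = el$to %||% character(0),
    sign = el$sign %||% character(0),
    weight = el$raw %||% numeric(0)
  )
  write.csv(out, csv, row.names = FALSE)
  if (!is.null(graphml)) igraph::write_graph(graph, graphml, format = "graphml")
  invisible(out)
}
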