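#' Write splicing counts to an MTX + CSV directory
#'
#' Layout: `unspliced.mtx` / `spliced.mtx` (MatrixMarket, cells x genes),
#' `unspliced_cells.csv` / `spliced_cells.csv` / `*_genes.csv` per-layer
#' barcode and feature tables, and `cells.csv` holding `cell_id`,
#' `ordering` and (when present) `branch`. All CSVs are comma-separated
#' with a header row, UTF-8, '.' decimal.
#'
#' @param counts A [splicing_counts()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_splicing_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "splicing_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (layer in c("unspliced", "spliced")) {
    m <- Matrix::Matrix(counts[[layer]], sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, paste0(layer, ".mtx")))
    write.csv(data.frame(cell_id = counts$cell_ids),
              file.path(dir, paste0(layer, "_cells.csv")), row.names = FALSE)
    write.csv(data.frame(gene = counts$gene_names),
              file.path(dir, paste0(layer, "_genes.csv")), row.names = FALSE)
  }
  meta <- data.frame(cell_id = counts$cell_ids, ordering = counts$ordering)
  if (!is.null(counts$branch_labels)) meta$branch <- counts$branch_labels
  write.csv(meta, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

read_layer <- function(mtx, cells_csv, genes_csv) {
  for (f in c(mtx, cells_csv, genes_csv)) {
    if (!file.exists(f)) abort(paste0("missing input file: ", f))
  }
  m <- as.matrix(Matrix::readMM(mtx))
  cells <- read.csv(cells_csv)[[1]]
  genes <- read.csv(genes_csv)[[1]]
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    abort(sprintf(
      "shape mismatch in %s: matrix is %d x %d but %d cells / %d genes listed.",
      mtx, nrow(m), ncol(m), length(cells), length(genes)
    ))
  }
  if (anyDuplicated(genes)) abort(paste0("duplicate gene names in ", genes_csv))
  dimnames(m) <- list(cells, genes)
  m
}

#' Read splicing counts from an MTX + CSV directory
#'
#' Counterpart of [write_splicing_counts()]. The two layers are aligned on
#' the intersection of their cell ids and gene names, kept in the order of
#' appearance in the unspliced layer; dropped cells/genes are reported.
#'
#' @param dir Directory written by [write_splicing_counts()] (or following
#'   the same layout).
#' @return A [splicing_counts()] object.
#' @export
read_splicing_counts <- function(dir) {
  U <- read_layer(file.path(dir, "unspliced.mtx"),
                  file.path(dir, "unspliced_cells.csv"),
                  file.path(dir, "unspliced_genes.csv"))
  S <- read_layer(file.path(dir, "spliced.mtx"),
                  file.path(dir, "spliced_cells.csv"),
                  file.path(dir, "spliced_genes.csv"))
  cells <- intersect(rownames(U), rownames(S))
  genes <- intersect(colnames(U), colnames(S))
  dropped_cells <- (nrow(U) - length(cells)) + (nrow(S) - length(cells))
  dropped_genes <- (ncol(U) - length(genes)) + (ncol(S) - length(genes))
  if (dropped_cells > 0 || dropped_genes > 0) {
    inform(sprintf(
      "aligned layers on %d shared cells / %d shared genes (dropped %d cell and %d gene entries present in a single layer).",
      length(cells), length(genes), dropped_cells, dropped_genes
    ))
  }
  if (!length(cells) || !length(genes)) abort("the two layers share no cells or no genes.")

  meta_path <- file.path(dir, "cells.csv")
  if (!file.exists(meta_path)) abort(paste0("missing input file: ", meta_path))
  meta <- read.csv(meta_path)
  ord <- meta$ordering[match(cells, meta$cell_id)]
  if (any(is.na(ord))) abort("cells.csv does not cover every shared cell.")
  branch <- if ("branch" %in% names(meta)) meta$branch[match(cells, meta$cell_id)] else NULL
  splicing_counts(
    U[cells, genes, drop = FALSE], S[cells, genes, drop = FALSE],
    ordering = ord, gene_names = genes, cell_ids = cells,
    branch_labels = branch
  )
}

#' Pipeline run configuration
#'
#' @param input Directory holding the MTX + CSV count layout (see
#'   [read_splicing_counts()]).
#' @param output Output directory.
#' @param genes Optional explicit gene list (overrides `n_genes`).
#' @param width,increment,n_genes,n_iterations,regression_kind,shrinkage,seed
#'   Window-scan parameters, as in [window_config()].
#' @param edge_threshold,algorithm GRN options, as in [build_grn()] and
#'   [detect_communities()].
#' @param smooth_sigma Bandwidth for the instability score.
#' @return A list of class `run_config`, serializable to JSON.
#' @export
run_config <- function(input, output, genes = NULL,
                       width = 100L, increment = 20L, n_genes = NULL,
                       n_iterations = 10L, regression_kind = "linear",
                       shrinkage = 0, seed = 1L,
                       edge_threshold = 0.75,
                       algorithm = "greedy_modularity",
                       smooth_sigma = 1) {
  structure(
    list(
      input = input, output = output, genes = genes,
      width = width, increment = increment, n_genes = n_genes,
      n_iterations = n_iterations, regression_kind = regression_kind,
      shrinkage = shrinkage, seed = seed,
      edge_threshold = edge_threshold, algorithm = algorithm,
      smooth_sigma = smooth_sigma
    ),
    class = "run_config"
  )
}

#' Run the full inference pipeline
#'
#' Gene selection, lineage scan, instability score and GRN community
#' trajectory, with all results written to the output directory:
#' `profile.csv` (one row per window x iteration), `summary.csv`,
#' `scores.csv` (per-cell instability), `communities.csv`, per-window GRN
#' edge lists under `grn/`, and `manifest.json` recording the configuration
#' and seed. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the scan, scores and community tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  counts <- stage("read_counts", read_splicing_counts(config$input))
  counts <- stage("select_genes", {
    if (!is.null(config$genes)) select_genes(counts, genes = config$genes)
    else if (!is.null(config$n_genes)) select_genes(counts, n_genes = config$n_genes)
    else counts
  })
  cfg <- window_config(
    width = config$width, increment = config$increment,
    n_iterations = config$n_iterations,
    regression_kind = config$regression_kind,
    shrinkage = config$shrinkage, seed = config$seed
  )
  scan <- stage("scan_lineage", scan_lineage(counts, cfg))
  scores <- stage("instability_score",
                  instability_score(scan, counts, sigma = config$smooth_sigma))
  comm <- stage("community_trajectory",
                community_trajectory(scan, counts,
                                     algorithms = config$algorithm,
                                     edge_threshold = config$edge_threshold))

  out <- config$output
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write.csv(scan$profile, file.path(out, "profile.csv"), row.names = FALSE)
  write.csv(scan$summary, file.path(out, "summary.csv"), row.names = FALSE)
  write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE)
  write.csv(comm, file.path(out, "communities.csv"), row.names = FALSE)
  grn_dir <- file.path(out, "grn")
  if (!dir.exists(grn_dir)) dir.create(grn_dir)
  for (w in seq_along(scan$fits)) {
    fit <- scan$fits[[w]]
    if (is.null(fit)) next
    cells <- scan$windows$cell_ids[[w]]
    genes <- intersect(counts$gene_names, union(fit$gene_names, fit$excluded_genes))
    expr <- colMeans(counts$spliced[match(cells, counts$cell_ids),
                                    genes, drop = FALSE])
    g <- build_grn(fit, expr, edge_threshold = config$edge_threshold,
                   all_genes = genes)
    write_grn(g,
              csv = file.path(grn_dir, sprintf("window_%03d_edges.csv", w)),
              graphml = file.path(grn_dir, sprintf("window_%03d.graphml", w)))
  }
  manifest <- list(
    config = unclass(config),
    n_cells = length(counts$cell_ids),
    n_genes = length(counts$gene_names),
    n_windows = nrow(scan$summary),
    package_version = as.character(utils::packageVersion("tipscan"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scan = scan, scores = scores, communities = comm))
}
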