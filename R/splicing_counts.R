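#' Paired unspliced/spliced count container
#'
#' Bundles the two cells-by-genes count matrices required by the splicing
#' model together with the per-cell lineage ordering (pseudotime or an
#' experimental time rank) and optional branch labels for multi-fate
#' lineages.
#'
#' @param unspliced,spliced Nonnegative numeric matrices (cells x genes) of
#'   identical dimension and gene order. Sparse `Matrix` classes are
#'   accepted and densified.
#' @param ordering Numeric vector, one finite value per cell, ordering the
#'   cells along the lineage. Low values are the start of the transition.
#' @param gene_names,cell_ids Character vectors; default to the matrix
#'   dimnames or generated labels.
#' @param branch_labels Optional character vector, one label per cell,
#'   assigning each cell to a lineage branch.
#'
#' @return An object of class `splicing_counts`: a list with elements
#'   `unspliced`, `spliced`, `gene_names`, `cell_ids`, `ordering`,
#'   `branch_labels`.
#' @export
splicing_counts <- function(unspliced, spliced, ordering,
                            gene_names = NULL, cell_ids = NULL,
                            branch_labels = NULL) {
  U <- as.matrix(unspliced)
  S <- as.matrix(spliced)
  storage.mode(U) <- "double"
  storage.mode(S) <- "double"
  if (!all(dim(U) == dim(S))) {
    abort("`unspliced` and `spliced` must have identical dimensions.")
  }
  if (nrow(U) < 2L) abort("at least 2 cells are required.")
  if (any(!is.finite(U)) || any(!is.finite(S))) {
    abort("count matrices must be finite.")
  }
  if (any(U < 0) || any(S < 0)) abort("counts must be nonnegative.")

  gene_names <- gene_names %||% colnames(U) %||% paste0("g", seq_len(ncol(U)))
  cell_ids <- cell_ids %||% rownames(U) %||% sprintf("cell_%05d", seq_len(nrow(U)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(U)) abort("`gene_names` length must match gene count.")
  if (anyDuplicated(gene_names)) abort("duplicate gene names are not allowed.")
  if (length(cell_ids) != nrow(U)) abort("`cell_ids` length must match cell count.")

  ordering <- as.numeric(ordering)
  if (length(ordering) != nrow(U) || any(!is.finite(ordering))) {
    abort("`ordering` must be a finite numeric vector, one value per cell.")
  }
  if (!is.null(branch_labels)) {
    branch_labels <- as.character(branch_labels)
    if (length(branch_labels) != nrow(U)) {
      abort("`branch_labels` length must match cell count.")
    }
  }
  dimnames(U) <- dimnames(S) <- list(cell_ids, gene_names)

  structure(
    list(
      unspliced = U, spliced = S,
      gene_names = gene_names, cell_ids = cell_ids,
      ordering = ordering, branch_labels = branch_labels
    ),
    class = "splicing_counts"
  )
}

#' @export
print.splicing_counts <- function(x, ...) {
  cat(sprintf(
    "<splicing_counts> %d cells x %d genes; ordering in [%.3g, %.3g]%s\n",
    length(x$cell_ids), length(x$gene_names),
    min(x$ordering), max(x$ordering),
    if (is.null(x$branch_labels)) "" else
      sprintf("; branches: %s", paste(sort(unique(x$branch_labels)), collapse = ", "))
  ))
  invisible(x)
}

#' @export
dim.splicing_counts <- function(x) {
  c(length(x$cell_ids), length(x$gene_names))
}

#' Subset a splicing_counts object by cell
#'
#' @param counts A [splicing_counts()] object.
#' @param cells Character vector of cell ids, or logical/integer index.
#' @return A `splicing_counts` restricted to those cells, in the given order.
#' @export
subset_cells <- function(counts, cells) {
  stopifnot(inherits(counts, "splicing_counts"))
  if (is.character(cells)) {
    missing <- setdiff(cells, counts$cell_ids)
    if (length(missing)) {
      abort(paste0("unknown cell ids: ", paste(head(missing, 5), collapse = ", ")))
    }
    idx <- match(cells, counts$cell_ids)
  } else {
    idx <- seq_along(counts$cell_ids)[cells]
  }
  splicing_counts(
    counts$unspliced[idx, , drop = FALSE],
    counts$spliced[idx, , drop = FALSE],
    ordering = counts$ordering[idx],
    gene_names = counts$gene_names,
    cell_ids = counts$cell_ids[idx],
    branch_labels = if (is.null(counts$branch_labels)) NULL else counts$branch_labels[idx]
  )
}

#' Restrict to a gene subset
#'
#' Either keeps a user-supplied gene list verbatim (in the input matrix's
#' column order), or keeps the `n_genes` genes with highest mean spliced
#' expression, ties broken alphabetically. Column order of retained genes is
#' always the original matrix order, so the selection is deterministic.
#'
#' @param counts A [splicing_counts()] object.
#' @param n_genes Number of top-expressed genes to keep (ignored when
#'   `genes` is given).
#' @param genes Optional character vector of gene names to keep verbatim.
#' @return A `splicing_counts` with the selected gene columns.
#' @export
select_genes <- function(counts, n_genes = NULL, genes = NULL) {
  stopifnot(inherits(counts, "splicing_counts"))
  if (!is.null(genes)) {
    missing <- setdiff(genes, counts$gene_names)
    if (length(missing)) {
      abort(paste0(
        "genes not present in the data: ",
        paste(missing, collapse = ", ")
      ))
    }
    keep <- counts$gene_names %in% genes
  } else {
    if (is.null(n_genes)) abort("supply either `n_genes` or `genes`.")
    M <- length(counts$gene_names)
    if (n_genes > M) abort("`n_genes` exceeds the number of genes.")
    means <- colMeans(counts$spliced)
    rank_order <- order(-means, counts$gene_names)
    keep_names <- counts$gene_names[rank_order[seq_len(n_genes)]]
    keep <- counts$gene_names %in% keep_names
  }
  splicing_counts(
    counts$unspliced[, keep, drop = FALSE],
    counts$spliced[, keep, drop = FALSE],
    ordering = counts$ordering,
    gene_names = counts$gene_names[keep],
    cell_ids = counts$cell_ids,
    branch_labels = counts$branch_labels
  )
}

#' Per-cell signature score
#'
#' Mean expression of a gene signature: each signature gene's spliced
#' expression is min-max scaled across cells (a constant gene contributes
#' 0), then averaged per cell. Used e.g. for a mesenchymal score along an
#' epithelial-mesenchymal lineage.
#'
#' @param counts A [splicing_counts()] object.
#' @param signature Character vector of gene names; genes absent from the
#'   data are ignored, but the intersection must be nonempty.
#' @return A tibble with columns `cell_id`, `ordering`, `score`.
#' @export
signature_score <- function(counts, signature) {
  stopifnot(inherits(counts, "splicing_counts"))
  genes <- intersect(signature, counts$gene_names)
  if (!length(genes)) abort("no signature gene is present in the data.")
  S <- counts$spliced[, genes, drop = FALSE]
  scaled <- apply(S, 2L, function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  })
  scaled <- matrix(scaled, nrow = nrow(S))
  tibble::tibble(
    cell_id = counts$cell_ids,
    ordering = counts$ordering,
    score = rowMeans(scaled)
  )
}
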