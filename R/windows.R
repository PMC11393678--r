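#' Sliding-window inference configuration
#'
#' Free parameters of the lineage scan: the width of the inference window
#' (in cells), the increment between successive windows, the number of top
#' genes retained, and the subsampling scheme that generates per-window
#' error bars.
#'
#' @param width Cells per window (integer, >= 4).
#' @param increment Cells advanced between windows (integer >= 1).
#' @param n_genes Number of top-expressed genes used in the model; `NULL`
#'   keeps all genes (e.g. after an explicit [select_genes()] call).
#' @param n_iterations Subsampling repeats per window used for error bars
#'   (default 10).
#' @param subsample_fraction Fraction of window cells used per iteration
#'   (default 0.9; 1 makes all iterations identical).
#' @param regression_kind `"linear"`, `"ridge"` or `"lasso"`.
#' @param shrinkage Penalty weight lambda (0 for plain linear regression).
#' @param beta Splicing rate; default 1 (time measured in units of 1/beta).
#' @param seed Integer seed controlling the subsampling draws.
#' @return An object of class `window_config`.
#' @export
window_config <- function(width, increment = 1L, n_genes = NULL,
                          n_iterations = 10L, subsample_fraction = 0.9,
                          regression_kind = c("linear", "ridge", "lasso"),
                          shrinkage = 0, beta = 1, seed = 1L) {
  regression_kind <- match.arg(regression_kind)
  width <- as.integer(width)
  increment <- as.integer(increment)
  if (is.na(width) || width < 4L) abort("`width` must be an integer >= 4.")
  if (is.na(increment) || increment < 1L) abort("`increment` must be >= 1.")
  if (!is.null(n_genes)) n_genes <- as.integer(n_genes)
  if (n_iterations < 1L) abort("`n_iterations` must be >= 1.")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must be in (0, 1].")
  }
  if (shrinkage < 0) abort("`shrinkage` must be nonnegative.")
  structure(
    list(
      width = width, increment = increment, n_genes = n_genes,
      n_iterations = as.integer(n_iterations),
      subsample_fraction = subsample_fraction,
      regression_kind = regression_kind, shrinkage = shrinkage,
      beta = beta, seed = as.integer(seed)
    ),
    class = "window_config"
  )
}

#' Enumerate sliding windows over an ordered lineage
#'
#' Windows are contiguous index ranges of `width` cells advanced by
#' `increment`; a trailing partial window is dropped, giving
#' `floor((N - width) / increment) + 1` windows.
#'
#' @param n_cells Number of cells N (cells assumed already sorted by
#'   ordering value, ties broken by cell id).
#' @param config A [window_config()], or its `width`/`increment` fields.
#' @return A tibble with columns `window`, `start`, `end` (1-based,
#'   inclusive).
#' @export
make_windows <- function(n_cells, config) {
  width <- config$width
  increment <- config$increment
  if (width > n_cells) {
    abort(sprintf("window width (%d) exceeds the number of cells (%d).", width, n_cells))
  }
  n_win <- (n_cells - width) %/% increment + 1L
  starts <- (seq_len(n_win) - 1L) * increment + 1L
  tibble::tibble(window = seq_len(n_win), start = starts, end = starts + width - 1L)
}

# Ridge with unpenalized intercept via centered normal equations:
# minimize ||a0 + X b - y||^2 + lambda ||b||^2.
ridge_solve <- function(X, y, lambda) {
  p <- ncol(X)
  if (p == 0L) return(list(a0 = mean(y), b = numeric(0)))
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  b <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  list(a0 = ym - sum(xm * b), b = as.numeric(b))
}

# Lasso with unpenalized intercept: minimize ||a0 + X b - y||^2 + lambda |b|_1.
# glmnet minimizes (1/2N) RSS + lambda_g |b|_1, hence lambda_g = lambda / (2N).
lasso_solve <- function(X, y, lambda) {
  p <- ncol(X)
  n <- length(y)
  if (p == 0L) return(list(a0 = mean(y), b = numeric(0)))
  if (p == 1L) {
    # soft-threshold closed form (glmnet requires >= 2 predictors)
    xm <- mean(X[, 1]); ym <- mean(y)
    xc <- X[, 1] - xm; yc <- y - ym
    sxx <- sum(xc^2)
    if (sxx == 0) return(list(a0 = ym, b = 0))
    rho <- sum(xc * yc)
    b <- sign(rho) * max(0, abs(rho) - lambda / 2) / sxx
    return(list(a0 = ym - xm * b, b = b))
  }
  fit <- glmnet::glmnet(
    X, y,
    alpha = 1, lambda = lambda / (2 * n),
    standardize = FALSE, intercept = TRUE, thresh = 1e-12
  )
  cf <- as.numeric(stats::coef(fit))
  list(a0 = cf[1], b = cf[-1])
}

linear_solve <- function(X, y) {
  Xa <- cbind(1, X)
  cf <- qr.coef(qr(Xa), y)
  cf[is.na(cf)] <- 0
  list(a0 = cf[1], b = as.numeric(cf[-1]))
}

#' Fit the splicing model within one window
#'
#' For each gene i, the unspliced production balance is solved as a
#' regression of `beta * U_i` on the spliced expression of all other genes
#' (plus an intercept), with an optional ridge or lasso penalty applied to
#' the interaction coefficients only, never to the intercept. The
#' degradation rate of each gene is obtained from the spliced steady-state
#' balance by through-origin least squares,
#' `gamma_i = beta * sum(U_i S_i) / sum(S_i^2)` (the single-cell limit of
#' which is the ratio `beta * U_i / S_i`).
#'
#' Genes whose spliced counts are all zero in the window have an undefined
#' degradation rate; they are excluded from this window's model (rows and
#' columns) and recorded in the fit's `excluded_genes`, with a message.
#' The same applies to genes expressed in almost no window cell (fewer
#' nonzero spliced counts than `max(3, 2%)` of the window): a regressor
#' supported on a handful of cells is not identifiable and its
#' through-origin degradation fit is dominated by noise, so the gene is
#' treated as silent in this window.
#'
#' @param counts A [splicing_counts()] restricted to the cells of one
#'   window (>= 2 cells).
#' @param config A [window_config()].
#' @return A [splicing_fit()] for the genes usable in this window.
#' @export
fit_window <- function(counts, config) {
  stopifnot(inherits(counts, "splicing_counts"))
  U <- counts$unspliced
  S <- counts$spliced
  if (nrow(U) < 2L) abort("a window must contain at least 2 cells.")
  beta <- config$beta %||% 1
  lambda <- config$shrinkage
  kind <- config$regression_kind

  n_expressed <- colSums(S > 0)
  min_expressed <- max(3, ceiling(0.02 * nrow(S)))
  keep <- n_expressed >= min(min_expressed, nrow(S))
  excluded <- counts$gene_names[!keep]
  if (length(excluded)) {
    inform(paste0(
      "excluding gene(s) with (near) all-zero spliced counts in window: ",
      paste(excluded, collapse = ", ")
    ))
  }
  genes <- counts$gene_names[keep]
  U <- U[, keep, drop = FALSE]
  S <- S[, keep, drop = FALSE]
  M <- length(genes)
  if (M < 1L) abort("no usable gene in this window (all spliced counts zero).")

  A <- matrix(0, M, M, dimnames = list(genes, genes))
  intercepts <- numeric(M)
  for (i in seq_len(M)) {
    y <- beta * U[, i]
    X <- S[, -i, drop = FALSE]
    sol <- switch(kind,
      linear = linear_solve(X, y),
      ridge = ridge_solve(X, y, lambda),
      lasso = lasso_solve(X, y, lambda)
    )
    intercepts[i] <- sol$a0
    if (M > 1L) A[i, -i] <- sol$b
  }
  gammas <- beta * colSums(U * S) / colSums(S^2)

  splicing_fit(
    gene_names = genes, intercepts = intercepts, interaction_matrix = A,
    beta = beta, gammas = gammas, shrinkage = lambda,
    regression_kind = kind, excluded_genes = excluded
  )
}
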