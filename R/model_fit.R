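#' Fitted multivariate splicing model for one window
#'
#' Parameters of the linear splicing system
#' \deqn{dU_i/dt = A_{i0} + \sum_{j \ne i} A_{ij} S_j - \beta U_i,\qquad
#'       dS_i/dt = \beta U_i - \gamma_i S_i,}
#' where `A` is the cross-species (gene-gene) interaction matrix, `beta` the
#' shared splicing rate (1 after rescaling time in units of 1/beta), and
#' `gammas` the per-gene degradation/dilution rates.
#'
#' @param gene_names Character vector of M gene identifiers.
#' @param intercepts Length-M numeric, baseline unspliced production.
#' @param interaction_matrix M x M numeric matrix with an exactly-zero
#'   diagonal (self terms are carried by the splicing/degradation rates).
#' @param beta Positive scalar splicing rate; default 1.
#' @param gammas Length-M nonnegative degradation rates. Non-finite entries
#'   are retained and flagged (the Jacobian assembly refuses them by name),
#'   never silently dropped.
#' @param shrinkage Nonnegative penalty weight used in the fit.
#' @param regression_kind One of `"linear"`, `"ridge"`, `"lasso"`.
#' @param excluded_genes Character vector of genes dropped before fitting
#'   (e.g. all-zero spliced counts in the window).
#'
#' @return An object of class `splicing_fit`.
#' @export
splicing_fit <- function(gene_names, intercepts, interaction_matrix,
                         beta = 1, gammas, shrinkage = 0,
                         regression_kind = c("linear", "ridge", "lasso"),
                         excluded_genes = character()) {
  regression_kind <- match.arg(regression_kind)
  gene_names <- as.character(gene_names)
  M <- length(gene_names)
  A <- as.matrix(interaction_matrix)
  if (!all(dim(A) == c(M, M))) abort("`interaction_matrix` must be M x M.")
  if (M >= 1 && any(diag(A) != 0)) {
    abort("the diagonal of `interaction_matrix` must be exactly zero.")
  }
  if (length(intercepts) != M) abort("`intercepts` must have length M.")
  if (length(gammas) != M) abort("`gammas` must have length M.")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a positive finite scalar.")
  }
  if (any(is.finite(gammas) & gammas < 0)) abort("`gammas` must be nonnegative.")
  if (shrinkage < 0) abort("`shrinkage` must be nonnegative.")
  dimnames(A) <- list(gene_names, gene_names)
  structure(
    list(
      gene_names = gene_names,
      intercepts = setNames(as.numeric(intercepts), gene_names),
      interaction_matrix = A,
      beta = beta,
      gammas = setNames(as.numeric(gammas), gene_names),
      shrinkage = shrinkage,
      regression_kind = regression_kind,
      excluded_genes = as.character(excluded_genes)
    ),
    class = "splicing_fit"
  )
}

#' @export
print.splicing_fit <- function(x, ...) {
  cat(sprintf(
    "<splicing_fit> %d genes, %s regression (lambda = %g), beta = %g\n",
    length(x$gene_names), x$regression_kind, x$shrinkage, x$beta
  ))
  if (length(x$excluded_genes)) {
    cat("  excluded genes:", paste(x$excluded_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the splicing-model Jacobian and its spectrum
#'
#' The Jacobian of the 2M-dimensional system, with state ordered as
#' (U1..UM, S1..SM), is composed of four quadrants:
#' upper-left `-beta * I` (splicing loss of unspliced RNA), upper-right `A`
#' (transcriptional regulation by spliced species), lower-left `beta * I`
#' (splicing gain), lower-right `-diag(gammas)` (degradation). Its
#' eigenvalues determine local stability: any eigenvalue with positive real
#' part marks an unstable state.
#'
#' @param fit A [splicing_fit()] object.
#' @return An object of class `jacobian_spectrum`: list with `jacobian`
#'   (2M x 2M), `eigenvalues` (complex, length 2M), `largest_real`,
#'   `n_positive`, `frac_positive`, `gene_names`.
#' @export
assemble_jacobian <- function(fit) {
  stopifnot(inherits(fit, "splicing_fit"))
  M <- length(fit$gene_names)
  if (M < 1L) abort("the fit must contain at least one gene.")
  bad_g <- fit$gene_names[!is.finite(fit$gammas)]
  if (length(bad_g)) {
    abort(paste0(
      "non-finite degradation rate for gene(s): ",
      paste(bad_g, collapse = ", ")
    ))
  }
  bad_a <- fit$gene_names[apply(fit$interaction_matrix, 1L, function(r) any(!is.finite(r)))]
  if (length(bad_a)) {
    abort(paste0(
      "non-finite interaction coefficients for gene(s): ",
      paste(bad_a, collapse = ", ")
    ))
  }
  I_M <- diag(1, M)
  J <- rbind(
    cbind(-fit$beta * I_M, fit$interaction_matrix),
    cbind(fit$beta * I_M, -diag(fit$gammas, nrow = M))
  )
  state_names <- c(paste0("u_", fit$gene_names), paste0("s_", fit$gene_names))
  dimnames(J) <- list(state_names, state_names)
  ev <- eigen(J, only.values = TRUE)$values
  metrics <- spectral_metrics(ev)
  structure(
    c(list(jacobian = J, eigenvalues = ev, gene_names = fit$gene_names), metrics),
    class = "jacobian_spectrum"
  )
}

#' @export
print.jacobian_spectrum <- function(x, ...) {
  cat(sprintf(
    "<jacobian_spectrum> %d genes; largest Re(eigenvalue) = %.4g; %d/%d positive\n",
    length(x$gene_names), x$largest_real, x$n_positive, length(x$eigenvalues)
  ))
  invisible(x)
}

#' Stability metrics of an eigenvalue spectrum
#'
#' Positivity is judged on real parts with a strict inequality, so a
#' marginal eigenvalue exactly at zero (the bifurcation point itself) counts
#' as non-positive.
#'
#' @param eigenvalues Nonempty numeric or complex vector.
#' @return A list with `largest_real` (max real part), `n_positive` (count
#'   with real part > 0) and `frac_positive` (`n_positive` over the total
#'   eigenvalue count).
#' @export
spectral_metrics <- function(eigenvalues) {
  if (length(eigenvalues) == 0L) abort("`eigenvalues` must be nonempty.")
  re <- Re(eigenvalues)
  n_pos <- sum(re > 0)
  list(
    largest_real = max(re),
    n_positive = n_pos,
    frac_positive = n_pos / length(eigenvalues)
  )
}

#' @describeIn splicing_fit Tidy the fitted coefficients: one row per model
#'   term (`"(Intercept)"` or a regulator gene) and target gene.
#' @param x A `splicing_fit`.
#' @param ... Unused.
#' @export
tidy.splicing_fit <- function(x, ...) {
  M <- length(x$gene_names)
  inter <- tibble::tibble(
    target = x$gene_names,
    term = "(Intercept)",
    estimate = unname(x$intercepts)
  )
  coefs <- tibble::tibble(
    target = rep(x$gene_names, times = M),
    term = rep(x$gene_names, each = M),
    estimate = as.vector(x$interaction_matrix)
  )
  coefs <- dplyr::filter(coefs, .data$target != .data$term)
  dplyr::bind_rows(inter, coefs)
}

#' @describeIn splicing_fit One-row model summary.
#' @export
glance.splicing_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_names),
    beta = x$beta,
    shrinkage = x$shrinkage,
    regression_kind = x$regression_kind,
    n_excluded = length(x$excluded_genes)
  )
}
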