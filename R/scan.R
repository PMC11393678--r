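#' Scan a lineage with a sliding inference window
#'
#' Cells are sorted by their ordering value (ties broken by cell id for
#' determinism), a sliding window of `config$width` cells advances by
#' `config$increment`, and the splicing model is fitted within each window.
#' Each window yields one full-window fit (stored, used downstream for GRN
#' reconstruction) and `config$n_iterations` fits on seeded random
#' subsamples of `config$subsample_fraction` of the window's cells, from
#' whose Jacobian spectra the per-window mean and standard deviation of
#' each stability metric are computed.
#'
#' A window whose fit fails is marked missing (NA metrics) without aborting
#' the scan. The window's lineage coordinate is the mean ordering value of
#' its cells.
#'
#' @param counts A [splicing_counts()] object (gene-selected; or set
#'   `config$n_genes` to select top-expressed genes here).
#' @param config A [window_config()].
#' @return An object of class `lineage_scan`: list with
#'   \describe{
#'     \item{profile}{tibble, one row per window x iteration with
#'       `largest_real`, `n_positive`, `frac_positive`, `n_genes_used`.}
#'     \item{summary}{tibble, one row per window with position and
#'       mean/sd of each metric across iterations.}
#'     \item{fits}{list of full-window [splicing_fit()] objects (NULL for
#'       failed windows).}
#'     \item{windows}{tibble of window index ranges with cell ids.}
#'     \item{cell_ids, ordering}{cells in scan order.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
scan_lineage <- function(counts, config) {
  stopifnot(inherits(counts, "splicing_counts"), inherits(config, "window_config"))
  if (!is.null(config$n_genes) && config$n_genes < length(counts$gene_names)) {
    counts <- select_genes(counts, n_genes = config$n_genes)
  }
  ord <- order(counts$ordering, counts$cell_ids)
  counts <- subset_cells(counts, ord)
  N <- length(counts$cell_ids)
  wins <- make_windows(N, config)

  set.seed(config$seed)
  fits <- vector("list", nrow(wins))
  prof <- vector("list", nrow(wins))
  positions <- numeric(nrow(wins))
  window_cells <- vector("list", nrow(wins))

  for (w in seq_len(nrow(wins))) {
    idx <- wins$start[w]:wins$end[w]
    window_cells[[w]] <- counts$cell_ids[idx]
    positions[w] <- mean(counts$ordering[idx])
    wcounts <- subset_cells(counts, idx)

    full <- tryCatch(
      suppressMessages(fit_window(wcounts, config)),
      error = function(e) NULL
    )
    fits[[w]] <- full

    n_sub <- max(2L, floor(config$subsample_fraction * length(idx)))
    rows <- vector("list", config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      sub <- sort(sample(length(idx), n_sub))
      m <- tryCatch({
        f <- suppressMessages(fit_window(subset_cells(wcounts, sub), config))
        js <- assemble_jacobian(f)
        list(
          largest_real = js$largest_real, n_positive = js$n_positive,
          frac_positive = js$frac_positive, n_genes_used = length(f$gene_names)
        )
      }, error = function(e) {
        list(largest_real = NA_real_, n_positive = NA_integer_,
             frac_positive = NA_real_, n_genes_used = NA_integer_)
      })
      rows[[it]] <- tibble::tibble(
        window = w, position = positions[w], iteration = it,
        largest_real = m$largest_real, n_positive = m$n_positive,
        frac_positive = m$frac_positive, n_genes_used = m$n_genes_used
      )
    }
    prof[[w]] <- dplyr::bind_rows(rows)
  }

  profile <- dplyr::bind_rows(prof)
  summ <- profile |>
    dplyr::group_by(.data$window, .data$position) |>
    dplyr::summarise(
      dplyr::across(
        c("largest_real", "n_positive", "frac_positive"),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          sd = ~ sd(.x, na.rm = TRUE)
        )
      ),
      n_ok = sum(is.finite(.data$largest_real)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$window)
  summ$largest_real_mean[summ$n_ok == 0] <- NA_real_

  structure(
    list(
      profile = profile, summary = summ, fits = fits,
      windows = dplyr::mutate(wins, position = positions,
                              cell_ids = window_cells),
      cell_ids = counts$cell_ids, ordering = counts$ordering,
      config = config
    ),
    class = "lineage_scan"
  )
}

#' @export
print.lineage_scan <- function(x, ...) {
  cat(sprintf(
    "<lineage_scan> %d windows (width %d, increment %d) over %d cells\n",
    nrow(x$summary), x$config$width, x$config$increment, length(x$cell_ids)
  ))
  ok <- is.finite(x$summary$largest_real_mean)
  if (any(ok)) {
    cat(sprintf(
      "  mean largest Re(eig): min %.4g, max %.4g\n",
      min(x$summary$largest_real_mean[ok]), max(x$summary$largest_real_mean[ok])
    ))
  }
  invisible(x)
}

#' @describeIn scan_lineage Per-window, per-iteration stability metrics.
#' @param x A `lineage_scan`.
#' @param ... Unused.
#' @export
tidy.lineage_scan <- function(x, ...) x$profile

#' @describeIn scan_lineage One-row scan summary.
#' @export
glance.lineage_scan <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_ids),
    n_windows = nrow(x$summary),
    width = x$config$width,
    increment = x$config$increment,
    n_iterations = x$config$n_iterations,
    regression_kind = x$config$regression_kind,
    shrinkage = x$config$shrinkage,
    seed = x$config$seed,
    peak_largest_real = max(x$summary$largest_real_mean, na.rm = TRUE)
  )
}

#' Gaussian smoothing of a per-window profile
#'
#' Discrete Gaussian convolution with reflecting boundaries; the kernel is
#' renormalized to sum to one so a constant series is unchanged. `sigma` is
#' expressed in window units; `sigma = 0` is the identity.
#'
#' @param series Finite numeric vector.
#' @param sigma Nonnegative kernel standard deviation, in index units.
#' @return Numeric vector of the same length.
#' @export
smooth_profile <- function(series, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a nonnegative scalar.")
  }
  if (any(!is.finite(series))) abort("`series` must be finite.")
  n <- length(series)
  if (sigma == 0 || n <= 1L) return(series)
  r <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  # reflecting padding: (..x2 x1 | x1 x2 .. xn | xn x(n-1)..)
  reflect <- function(i) {
    m <- (i - 1) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  padded <- series[reflect((1L - r):(n + r))]
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Per-cell instability score
#'
#' Maps window-level instability back to cells. For each branch scan, the
#' per-window mean largest eigenvalue real part is Gaussian-smoothed
#' ([smooth_profile()]), clamped below at zero, and each cell receives the
#' value of the window whose lineage position is nearest its own ordering
#' value (cells outside all windows thus inherit the nearest window's
#' score). With several branch scans the global score of a cell is the
#' maximum over the branches containing it; a cell in no branch scores 0
#' with a warning.
#'
#' @param scans A single `lineage_scan` or a named list of them (one per
#'   branch).
#' @param counts The [splicing_counts()] covering all cells to score.
#' @param sigma Smoothing bandwidth in window units (default 1).
#' @return A tibble with `cell_id`, `ordering`, `score`, and with one
#'   `score_<branch>` column per branch when several scans are given.
#' @export
instability_score <- function(scans, counts, sigma = 1) {
  stopifnot(inherits(counts, "splicing_counts"))
  if (inherits(scans, "lineage_scan")) scans <- list(lineage = scans)
  if (!length(scans)) abort("`scans` must contain at least one lineage_scan.")
  if (is.null(names(scans))) names(scans) <- paste0("branch", seq_along(scans))

  out <- tibble::tibble(cell_id = counts$cell_ids, ordering = counts$ordering)
  branch_scores <- matrix(NA_real_, nrow(out), length(scans),
                          dimnames = list(NULL, names(scans)))
  for (b in seq_along(scans)) {
    sc <- scans[[b]]
    summ <- sc$summary[is.finite(sc$summary$largest_real_mean), ]
    if (!nrow(summ)) next
    smoothed <- pmax(0, smooth_profile(summ$largest_real_mean, sigma))
    member <- counts$cell_ids %in% sc$cell_ids
    if (!any(member)) next
    nearest <- vapply(
      counts$ordering[member],
      function(p) which.min(abs(summ$position - p)),
      integer(1)
    )
    branch_scores[member, b] <- smoothed[nearest]
  }
  uncovered <- rowSums(!is.na(branch_scores)) == 0
  if (any(uncovered)) {
    warn(sprintf("%d cell(s) belong to no branch scan; scored 0.", sum(uncovered)))
  }
  score <- apply(branch_scores, 1L, function(r) {
    if (all(is.na(r))) 0 else max(r, na.rm = TRUE)
  })
  out$score <- score
  if (length(scans) > 1L) {
    for (b in names(scans)) out[[paste0("score_", b)]] <- branch_scores[, b]
  }
  out
}
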