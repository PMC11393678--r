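test_that("window enumeration matches the arithmetic and a brute-force count", {
  cfg <- window_config(width = 20, increment = 10)
  w <- make_windows(100, cfg)
  expect_equal(nrow(w), 9)
  expect_equal(c(w$start[1], w$end[1]), c(1, 20))
  expect_equal(c(w$start[9], w$end[9]), c(81, 100))

  w2 <- make_windows(20, window_config(width = 20, increment = 5))
  expect_equal(nrow(w2), 1)

  # brute-force enumeration of valid start positions
  brute <- sum(seq(1, 57, by = 7) + 20 - 1 <= 57)
  w3 <- make_windows(57, window_config(width = 20, increment = 7))
  expect_equal(nrow(w3), brute)
  expect_equal(nrow(w3), 6)

  expect_error(make_windows(10, window_config(width = 20)), "exceeds")
})

test_that("window_config validates its fields", {
  expect_error(window_config(width = 2), ">= 4")
  expect_error(window_config(width = 10, increment = 0), ">= 1")
  expect_error(window_config(width = 10, subsample_fraction = 0), "\\(0, 1\\]")
  expect_error(window_config(width = 10, shrinkage = -1), "nonnegative")
})

test_that("gene selection keeps top-expressed genes, ties alphabetical", {
  S <- cbind(b = c(3, 3), a = c(1, 1), c = c(3, 3))
  U <- S * 0.5
  counts <- splicing_counts(U, S, ordering = 1:2, gene_names = c("b", "a", "c"))

  # n_genes = M is the identity
  expect_equal(select_genes(counts, n_genes = 3)$gene_names, c("b", "a", "c"))

  # means (3, 1, 3): keep b and c (tie broken alphabetically is irrelevant
  # here since a is lowest), order preserved from the input matrix
  sel <- select_genes(counts, n_genes = 2)
  expect_equal(sel$gene_names, c("b", "c"))

  # explicit user list, verbatim columns in input order
  sel2 <- select_genes(counts, genes = c("c", "a"))
  expect_equal(sel2$gene_names, c("a", "c"))

  expect_error(select_genes(counts, genes = c("a", "zz")), "zz")
})

test_that("alphabetical tie-break is applied among equal means", {
  S <- cbind(z = c(2, 2), m = c(2, 2), a = c(2, 2))
  counts <- splicing_counts(S * 0, S, ordering = 1:2, gene_names = c("z", "m", "a"))
  sel <- select_genes(counts, n_genes = 2)
  # all means tie at 2: alphabetical rank keeps a and m
  expect_equal(sel$gene_names, c("m", "a"))
})

test_that("noiseless production data are recovered exactly by the linear fit", {
  # U = (0.5 + 0.3 * S2) / beta for gene 1
  set.seed(1)
  S2 <- runif(50, 0.5, 3)
  S <- cbind(g1 = runif(50, 0.5, 3), g2 = S2)
  U <- cbind(g1 = 0.5 + 0.3 * S2, g2 = 0.2 + 0.1 * S[, "g1"])
  counts <- splicing_counts(U, S, ordering = 1:50)
  fit <- fit_window(counts, window_config(width = 50))
  expect_lt(abs(fit$intercepts["g1"] - 0.5), 1e-8)
  expect_lt(abs(fit$interaction_matrix["g1", "g2"] - 0.3), 1e-8)
  expect_lt(abs(fit$intercepts["g2"] - 0.2), 1e-8)
  expect_lt(abs(fit$interaction_matrix["g2", "g1"] - 0.1), 1e-8)
})

test_that("degradation rates come from through-origin least squares", {
  # U_i = 0.5 * S_i exactly, beta = 1 -> gamma_i = 0.5 (the ratio rule)
  counts <- make_balance_counts(c(0.5, 0.5), n_cells = 30)
  fit <- fit_window(counts, window_config(width = 30))
  expect_equal(unname(fit$gammas), c(0.5, 0.5), tolerance = 1e-12)

  # general through-origin formula on arbitrary data
  set.seed(3)
  U <- matrix(runif(40, 0, 2), 20, 2)
  S <- matrix(runif(40, 0.1, 2), 20, 2)
  counts2 <- splicing_counts(U, S, ordering = 1:20, gene_names = c("a", "b"))
  fit2 <- fit_window(counts2, window_config(width = 20))
  expect_equal(unname(fit2$gammas), colSums(U * S) / colSums(S^2),
               tolerance = 1e-12)
})

test_that("ridge fits match the closed-form normal-equations oracle", {
  set.seed(5)
  n <- 40
  S <- matrix(runif(n * 3, 0.5, 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  U <- matrix(runif(n * 3, 0.5, 2), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  counts <- splicing_counts(U, S, ordering = 1:n, gene_names = c("a", "b", "c"))

  norms <- c()
  for (lambda in c(0, 1, 10, 1000)) {
    fit <- fit_window(counts, window_config(width = n, regression_kind = "ridge",
                                            shrinkage = lambda))
    for (i in 1:3) {
      cf <- oracle_ridge(S[, -i, drop = FALSE], U[, i], lambda)
      expect_lt(abs(fit$intercepts[i] - cf[1]), 1e-10)
      expect_lt(max(abs(fit$interaction_matrix[i, -i] - cf[-1])), 1e-10)
    }
    norms <- c(norms, sqrt(sum(fit$interaction_matrix^2)))
  }
  # coefficient L2 norm shrinks monotonically along the lambda path
  expect_true(all(diff(norms) < 0))
})

test_that("lasso shrinks coefficients and zeroes them at large lambda", {
  set.seed(6)
  n <- 60
  S <- matrix(runif(n * 3, 0.5, 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  U <- cbind(a = 1 + 0.5 * S[, "b"] + runif(n, 0, 0.05),
             b = 0.5 + 0.2 * S[, "c"] + runif(n, 0, 0.05),
             c = runif(n, 0.5, 1))
  counts <- splicing_counts(U, S, ordering = 1:n, gene_names = c("a", "b", "c"))
  f0 <- fit_window(counts, window_config(width = n, regression_kind = "lasso",
                                         shrinkage = 0.01))
  fbig <- fit_window(counts, window_config(width = n, regression_kind = "lasso",
                                           shrinkage = 1e5))
  expect_lt(sum(abs(fbig$interaction_matrix)), sum(abs(f0$interaction_matrix)))
  expect_equal(sum(fbig$interaction_matrix != 0), 0)
  # with lasso off, gene a's dependence on b is still found
  expect_gt(f0$interaction_matrix["a", "b"], 0.3)
})

test_that("single-predictor lasso matches its soft-threshold closed form", {
  set.seed(8)
  n <- 30
  S <- matrix(runif(n * 2, 0.5, 3), n, 2, dimnames = list(NULL, c("a", "b")))
  U <- cbind(a = 1 + 0.4 * S[, "b"], b = 0.5 + 0.6 * S[, "a"])
  counts <- splicing_counts(U, S, ordering = 1:n, gene_names = c("a", "b"))
  lambda <- 2
  fit <- fit_window(counts, window_config(width = n, regression_kind = "lasso",
                                          shrinkage = lambda))
  x <- S[, 2] - mean(S[, 2]); y <- U[, 1] - mean(U[, 1])
  rho <- sum(x * y)
  b_hat <- sign(rho) * max(0, abs(rho) - lambda / 2) / sum(x^2)
  expect_equal(unname(fit$interaction_matrix["a", "b"]), b_hat, tolerance = 1e-10)
})

test_that("genes with (near) zero spliced expression are excluded, not dropped silently", {
  set.seed(9)
  n <- 30
  S <- cbind(on = runif(n, 1, 2), off = rep(0, n))
  U <- cbind(on = runif(n, 0.5, 1), off = rep(0, n))
  counts <- splicing_counts(U, S, ordering = 1:n, gene_names = c("on", "off"))
  expect_message(
    fit <- fit_window(counts, window_config(width = n)),
    "off"
  )
  expect_equal(fit$gene_names, "on")
  expect_equal(fit$excluded_genes, "off")
  # the Jacobian for this window shrinks to the realized dimension
  expect_equal(dim(assemble_jacobian(fit)$jacobian), c(2, 2))
})

test_that("exact parameter recovery scales to M = 10 with 5M cells", {
  set.seed(10)
  for (M in c(2, 5, 10)) {
    A0 <- runif(M, 0.2, 1)
    A <- matrix(rnorm(M * M, sd = 0.3), M, M); diag(A) <- 0
    made <- make_production_counts(A0, A, n_cells = 5 * M, seed = M)
    fit <- fit_window(made$counts, window_config(width = 5 * M))
    rel <- abs(fit$interaction_matrix - made$A) / pmax(abs(made$A), 1e-8)
    rel[made$A == 0] <- abs(fit$interaction_matrix)[made$A == 0]
    expect_lt(max(rel), 1e-6)
    expect_lt(max(abs(fit$intercepts - made$A0) / made$A0), 1e-6)
  }
})
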