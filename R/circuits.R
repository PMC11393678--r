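#' Specification of a splicing-aware regulatory circuit
#'
#' Defines a small gene circuit in which each gene i has an unspliced
#' precursor U_i produced at rate
#' `basal_i + sum of Hill terms in the spliced regulators`, spliced at rate
#' `beta` and degraded at rate `gamma_i`:
#' \deqn{dU_i/dt = b_i + \sum_k h_k(S_{reg(k)}),\qquad
#'       dS_i/dt = \beta U_i - \gamma_i S_i,}
#' with Hill terms `rate * K^n / (K^n + S^n)` (repression) or
#' `rate * S^n / (K^n + S^n)` (activation). One designated scalar (a term's
#' `rate` or `K`, or a gene's `basal`) may be ramped in time to drive a
#' bifurcation.
#'
#' @param genes Character vector of gene names.
#' @param basal Named numeric vector of basal production rates (>= 0).
#' @param terms Data frame with columns `target`, `regulator`, `rate`, `K`,
#'   `n`, `type` (`"activation"` or `"repression"`); Hill coefficients
#'   `n >= 1`.
#' @param beta Splicing rate (> 0), shared by all genes.
#' @param gammas Named numeric vector of degradation rates (>= 0).
#' @param sigma Noise amplitude for stochastic simulation (>= 0).
#' @param noise `"multiplicative"` (sigma * x * dW, default) or
#'   `"additive"` (sigma * dW).
#' @param ramp Optional ramp schedule: a list with `gene`, `field`
#'   (`"basal"`, `"rate"` or `"K"`), `regulator` (for term fields), `from`,
#'   `to`, `t_start`, `t_end`; the value interpolates linearly in time and
#'   is clamped outside the ramp window.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(genes, basal, terms, beta = 1, gammas,
                         sigma = 0.05, noise = c("multiplicative", "additive"),
                         ramp = NULL) {
  noise <- match.arg(noise)
  genes <- as.character(genes)
  M <- length(genes)
  basal <- basal[genes]
  gammas <- gammas[genes]
  if (any(is.na(basal)) || any(basal < 0)) abort("`basal` must cover all genes, >= 0.")
  if (any(is.na(gammas)) || any(gammas < 0)) abort("`gammas` must cover all genes, >= 0.")
  if (beta <= 0) abort("`beta` must be positive.")
  if (sigma < 0) abort("`sigma` must be nonnegative.")
  terms <- as.data.frame(terms)
  needed <- c("target", "regulator", "rate", "K", "n", "type")
  if (!all(needed %in% names(terms))) {
    abort(paste0("`terms` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(terms)) {
    if (!all(terms$target %in% genes) || !all(terms$regulator %in% genes)) {
      abort("term targets/regulators must be circuit genes.")
    }
    if (any(terms$rate < 0) || any(terms$K <= 0)) abort("term rates >= 0 and K > 0 required.")
    if (any(terms$n < 1)) abort("Hill coefficients must be >= 1.")
    if (!all(terms$type %in% c("activation", "repression"))) {
      abort('term `type` must be "activation" or "repression".')
    }
  }
  if (!is.null(ramp)) {
    stopifnot(
      ramp$field %in% c("basal", "rate", "K"),
      all(ramp$gene %in% genes),
      is.numeric(ramp$from), is.numeric(ramp$to),
      ramp$t_end > ramp$t_start
    )
  }
  structure(
    list(genes = genes, basal = basal, terms = terms, beta = beta,
         gammas = gammas, sigma = sigma, noise = noise, ramp = ramp),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf(
    "<circuit_spec> genes: %s; %d Hill terms; beta = %g; sigma = %g (%s noise)\n",
    paste(x$genes, collapse = ", "), nrow(x$terms), x$beta, x$sigma, x$noise
  ))
  if (!is.null(x$ramp)) {
    cat(sprintf(
      "  ramp: %s of %s%s from %g to %g over t in [%g, %g]\n",
      x$ramp$field, paste(x$ramp$gene, collapse = "/"),
      if (x$ramp$field == "basal") "" else
        paste0(" <- ", paste(x$ramp$regulator, collapse = "/")),
      x$ramp$from, x$ramp$to, x$ramp$t_start, x$ramp$t_end
    ))
  }
  invisible(x)
}

#' Value of the ramped bifurcation parameter at a time point
#'
#' @param spec A [circuit_spec()].
#' @param t Numeric vector of times.
#' @return The ramp parameter value(s); the ramp start value if the spec
#'   has no ramp.
#' @export
ramp_value <- function(spec, t) {
  r <- spec$ramp
  if (is.null(r)) return(rep(NA_real_, length(t)))
  frac <- pmin(1, pmax(0, (t - r$t_start) / (r$t_end - r$t_start)))
  r$from + frac * (r$to - r$from)
}

# Effective parameter tables at a given ramp value.
effective_params <- function(spec, rv) {
  basal <- spec$basal
  terms <- spec$terms
  r <- spec$ramp
  if (!is.null(r) && !is.na(rv)) {
    if (r$field == "basal") {
      basal[r$gene] <- rv
    } else {
      # `gene`/`regulator` may be parallel vectors targeting several terms
      hit <- paste(terms$target, terms$regulator) %in%
        paste(r$gene, r$regulator)
      terms[[r$field]][hit] <- rv
    }
  }
  list(basal = basal, terms = terms)
}

# Production rates for spliced-state matrix S (cells x genes) at ramp value rv.
circuit_production <- function(spec, S, rv = NA_real_) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1, dimnames = list(NULL, spec$genes))
  p <- effective_params(spec, rv)
  P <- matrix(rep(p$basal, each = nrow(S)), nrow = nrow(S),
              dimnames = list(NULL, spec$genes))
  tm <- p$terms
  for (k in seq_len(nrow(tm))) {
    s <- pmax(S[, tm$regulator[k]], 0)
    Kn <- tm$K[k]^tm$n[k]
    sn <- s^tm$n[k]
    h <- if (tm$type[k] == "repression") Kn / (Kn + sn) else sn / (Kn + sn)
    P[, tm$target[k]] <- P[, tm$target[k]] + tm$rate[k] * h
  }
  P
}

# d(production_i)/d(S_j) at a single spliced state vector.
production_jacobian <- function(spec, s, rv = NA_real_) {
  M <- length(spec$genes)
  p <- effective_params(spec, rv)
  dP <- matrix(0, M, M, dimnames = list(spec$genes, spec$genes))
  tm <- p$terms
  for (k in seq_len(nrow(tm))) {
    x <- max(s[tm$regulator[k]], 0)
    n <- tm$n[k]
    Kn <- tm$K[k]^n
    xn <- x^n
    d <- tm$rate[k] * n * Kn * ifelse(x > 0, x^(n - 1), if (n == 1) 1 else 0) /
      (Kn + xn)^2
    if (tm$type[k] == "repression") d <- -d
    dP[tm$target[k], tm$regulator[k]] <- dP[tm$target[k], tm$regulator[k]] + d
  }
  dP
}

#' Analytic circuit Jacobian at a state
#'
#' Jacobian of the full 2M-dimensional splicing circuit at state
#' `(U, S)`, with the same quadrant structure as the inferred model:
#' upper-left `-beta I`, upper-right the Hill-term derivative matrix,
#' lower-left `beta I`, lower-right `-diag(gammas)`.
#'
#' @param spec A [circuit_spec()].
#' @param state Numeric vector `c(U, S)` of length 2M (unspliced first).
#' @param t Time at which to evaluate the ramped parameter (default:
#'   ramp start).
#' @return A 2M x 2M matrix.
#' @export
circuit_jacobian <- function(spec, state, t = -Inf) {
  M <- length(spec$genes)
  s <- state[(M + 1):(2 * M)]
  names(s) <- spec$genes
  dP <- production_jacobian(spec, s, ramp_value(spec, t))
  rbind(
    cbind(-spec$beta * diag(1, M), dP),
    cbind(spec$beta * diag(1, M), -diag(spec$gammas, nrow = M))
  )
}

#' Fixed points of a circuit at a frozen parameter value
#'
#' Locates the steady states of the deterministic circuit by Newton
#' iteration from a dense grid of starting points in spliced-state space
#' (at steady state `U = production(S)/beta` and
#' `gamma_i S_i = production_i(S)`, so the search reduces to M dimensions),
#' followed by deduplication and stability classification via the full
#' 2M-dimensional Jacobian.
#'
#' @param spec A [circuit_spec()].
#' @param rv Frozen ramp-parameter value (default: the ramp's `from`, or
#'   `NA` for a ramp-free spec).
#' @param n_grid Grid points per dimension for Newton starts.
#' @param s_max Upper bound of the search box per gene; default
#'   1.2 * (max achievable production) / gamma.
#' @param tol Newton convergence tolerance on the steady-state residual.
#' @param grid_genes Genes over which the start grid is laid out; genes
#'   outside this set start at zero (useful when some genes are slaved
#'   reporters that do not feed back, which keeps the grid small). By
#'   default, genes that participate in no Hill term (pure basal
#'   production, e.g. dimensionality-padding genes) are left off the grid
#'   since their steady state is unique given the rest. Newton iteration
#'   always runs on the full system.
#' @return A tibble with one row per fixed point: spliced coordinates
#'   `s_<gene>`, unspliced `u_<gene>`, `stable` (logical) and
#'   `largest_real` (leading Jacobian eigenvalue real part).
#' @export
find_fixed_points <- function(spec, rv = NULL, n_grid = 6, s_max = NULL,
                              tol = 1e-10, grid_genes = NULL) {
  if (is.null(grid_genes)) {
    wired <- unique(c(spec$terms$target, spec$terms$regulator))
    grid_genes <- if (length(wired)) wired else spec$genes
  }
  M <- length(spec$genes)
  if (is.null(rv)) rv <- if (is.null(spec$ramp)) NA_real_ else spec$ramp$from
  p <- effective_params(spec, rv)
  if (is.null(s_max)) {
    max_prod <- p$basal
    for (k in seq_len(nrow(p$terms))) {
      max_prod[p$terms$target[k]] <- max_prod[p$terms$target[k]] + p$terms$rate[k]
    }
    s_max <- 1.2 * max_prod / pmax(spec$gammas, 1e-8)
  }
  resid <- function(s) {
    as.numeric(circuit_production(spec, matrix(s, 1, dimnames = list(NULL, spec$genes)), rv)) -
      spec$gammas * s
  }
  jac_red <- function(s) {
    names(s) <- spec$genes
    production_jacobian(spec, s, rv) - diag(spec$gammas, nrow = M)
  }
  grids <- lapply(seq_len(M), function(i) {
    if (spec$genes[i] %in% grid_genes) seq(0, s_max[i], length.out = n_grid) else 0
  })
  starts <- as.matrix(expand.grid(grids))
  sols <- list()
  for (r in seq_len(nrow(starts))) {
    s <- starts[r, ]
    ok <- FALSE
    for (iter in 1:60) {
      g <- resid(s)
      if (max(abs(g)) < tol) { ok <- TRUE; break }
      J <- jac_red(s)
      step <- tryCatch(solve(J, g), error = function(e) NULL)
      if (is.null(step)) break
      # dampen to stay in a sane box
      s_new <- s - step
      if (any(!is.finite(s_new)) || any(s_new < -0.5) || any(s_new > 10 * s_max)) break
      s <- pmax(s_new, 0)
    }
    if (ok && all(s >= -1e-9)) sols[[length(sols) + 1L]] <- pmax(s, 0)
  }
  if (!length(sols)) {
    return(tibble::tibble())
  }
  smat <- unique(round(do.call(rbind, sols), 6))
  rows <- lapply(seq_len(nrow(smat)), function(i) {
    s <- smat[i, ]
    names(s) <- spec$genes
    u <- spec$gammas * s / spec$beta
    ev <- eigen(circuit_jacobian_at(spec, u, s, rv), only.values = TRUE)$values
    lr <- max(Re(ev))
    out <- c(setNames(s, paste0("s_", spec$genes)),
             setNames(u, paste0("u_", spec$genes)))
    tibble::tibble(!!!as.list(out), stable = lr < -1e-8, largest_real = lr)
  })
  dplyr::bind_rows(rows)
}

# internal variant taking the ramp value directly
circuit_jacobian_at <- function(spec, u, s, rv) {
  M <- length(spec$genes)
  names(s) <- spec$genes
  dP <- production_jacobian(spec, s, rv)
  rbind(
    cbind(-spec$beta * diag(1, M), dP),
    cbind(spec$beta * diag(1, M), -diag(spec$gammas, nrow = M))
  )
}

#' Locate a bifurcation of the frozen-parameter circuit
#'
#' Brute-force continuation oracle: counts stable fixed points (via
#' [find_fixed_points()]) at the bracket ends and bisects on the parameter
#' until the interval containing the change in count is narrower than
#' `tol`. The two bracket values must differ in their stable-state count.
#'
#' @param spec A [circuit_spec()].
#' @param lower,upper Parameter bracket (in ramp-parameter units).
#' @param tol Bisection tolerance (default 1e-6).
#' @param n_grid,... Passed to [find_fixed_points()].
#' @return The bifurcation parameter value (bracket midpoint at
#'   convergence).
#' @export
locate_bifurcation <- function(spec, lower, upper, tol = 1e-6, n_grid = 6, ...) {
  count <- function(p) {
    fp <- find_fixed_points(spec, rv = p, n_grid = n_grid, ...)
    if (!nrow(fp)) 0L else sum(fp$stable)
  }
  n_lo <- count(lower)
  n_hi <- count(upper)
  if (n_lo == n_hi) {
    abort("the bracket does not contain a change in stable fixed-point count.")
  }
  while (abs(upper - lower) > tol) {
    mid <- (lower + upper) / 2
    if (count(mid) == n_lo) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Splicing-aware toggle switch circuit
#'
#' Two genes X and Y that mutually repress each other's unspliced
#' production, each with a splicing layer. The ramped bifurcation parameter
#' is the repression threshold of the X -| Y edge: lowering it strengthens
#' the feedback inhibition of Y by X, driving a saddle-node transition from
#' the Y-high/X-low state to the X-high state. Defaults are bistable at the
#' ramp start and monostable at the ramp end (verifiable with
#' [find_fixed_points()]).
#'
#' Optionally, `n_extra` constitutively expressed, non-interacting genes can
#' be appended to raise the dimensionality of the benchmark (used for
#' sensitivity analyses of the gene-count parameter); they do not alter the
#' fixed-point structure of the X/Y core.
#'
#' @param a Maximal production rate of both genes.
#' @param K Repression threshold (both edges; the X -| Y one is ramped).
#' @param n Hill coefficient.
#' @param gamma Degradation rate of all genes.
#' @param beta Splicing rate.
#' @param sigma Noise amplitude.
#' @param K_ramp Length-2 vector: start and end value of the ramped
#'   threshold.
#' @param t_ramp Length-2 vector: ramp start and end times.
#' @param n_extra Number of appended independent genes.
#' @param extra_basal Basal production rate of the appended genes.
#' @return A [circuit_spec()] with genes `X`, `Y` (and `H1`, `H2`, ...).
#' @export
toggle_switch_spec <- function(a = 2, K = 1, n = 4, gamma = 1, beta = 1,
                               sigma = 0.05, K_ramp = c(1, 0.2),
                               t_ramp = c(20, 80),
                               n_extra = 0, extra_basal = 0.3) {
  genes <- c("X", "Y")
  terms <- data.frame(
    target = c("X", "Y"), regulator = c("Y", "X"),
    rate = a, K = K, n = n, type = "repression"
  )
  basal <- c(X = 0, Y = 0)
  gm <- c(X = gamma, Y = gamma)
  if (n_extra > 0) {
    extra <- paste0("H", seq_len(n_extra))
    genes <- c(genes, extra)
    basal <- c(basal, setNames(rep(extra_basal, n_extra), extra))
    gm <- c(gm, setNames(rep(gamma, n_extra), extra))
  }
  circuit_spec(
    genes = genes, basal = basal, terms = terms, beta = beta, gammas = gm,
    sigma = sigma,
    ramp = list(gene = "Y", regulator = "X", field = "K",
                from = K_ramp[1], to = K_ramp[2],
                t_start = t_ramp[1], t_end = t_ramp[2])
  )
}

#' Tristable epithelial-mesenchymal circuit
#'
#' A mutual-inhibition pair with self-activation (epithelial regulator
#' `miR200`, mesenchymal regulator `ZEB1`) whose parameters admit three
#' stable states: epithelial (miR200 high), hybrid E/M (both intermediate)
#' and mesenchymal (ZEB1 high). Four slaved marker genes (`CDH1` and
#' `EPCAM` activated by miR200, `VIM` and `FN1` activated by ZEB1) enrich
#' the reconstructed GRN without changing the attractor count. The ramped
#' parameter is the basal production of ZEB1 (an EMT-inducing signal);
#' raising it destroys the epithelial and hybrid states in two successive
#' saddle-node bifurcations, so a slow ramp carries cells E -> I -> M.
#'
#' @param a Self-activation rate of the two core genes.
#' @param b Mutual-inhibition rate of the two core genes.
#' @param K Hill threshold of the core interactions.
#' @param n Hill coefficient.
#' @param marker_rate Production rate of the marker genes.
#' @param gamma,beta,sigma As in [toggle_switch_spec()].
#' @param signal_ramp Start and end basal ZEB1 production.
#' @param t_ramp Ramp start and end times.
#' @return A [circuit_spec()] with genes `miR200`, `ZEB1`, `CDH1`,
#'   `EPCAM`, `VIM`, `FN1`.
#' @export
emt_tristable_spec <- function(a = 0.86, b = 1, K = 0.5, n = 4,
                               marker_rate = 1.5, gamma = 1, beta = 1,
                               sigma = 0.08, signal_ramp = c(0, 0.5),
                               t_ramp = c(30, 270)) {
  genes <- c("miR200", "ZEB1", "CDH1", "EPCAM", "VIM", "FN1")
  terms <- data.frame(
    target =    c("miR200", "miR200", "ZEB1", "ZEB1",
                  "CDH1", "EPCAM", "VIM", "FN1"),
    regulator = c("miR200", "ZEB1", "ZEB1", "miR200",
                  "miR200", "miR200", "ZEB1", "ZEB1"),
    rate =      c(a, b, a, b, rep(marker_rate, 4)),
    K =         K,
    n =         n,
    type = c("activation", "repression", "activation", "repression",
             rep("activation", 4))
  )
  circuit_spec(
    genes = genes,
    basal = setNames(c(0, signal_ramp[1], 0, 0, 0, 0), genes),
    terms = terms, beta = beta,
    gammas = setNames(rep(gamma, 6), genes),
    sigma = sigma,
    ramp = list(gene = "ZEB1", field = "basal", regulator = NA,
                from = signal_ramp[1], to = signal_ramp[2],
                t_start = t_ramp[1], t_end = t_ramp[2])
  )
}

#' Trifurcating fate circuit
#'
#' Three master regulators `T1`, `T2`, `T3` in all-to-all mutual
#' repression, each with a self-activation loop whose strength is ramped.
#' At the ramp start the symmetric co-expressed state (the progenitor
#' state S) is the only attractor. As self-activation grows, three
#' committed attractors appear at a distance (each with exactly one
#' regulator silenced and the other two on) while the progenitor state is
#' still stable, and shortly after the progenitor destabilizes
#' (a subcritical symmetry breaking), so stochastic trajectories jump to
#' one of three branches. The ground-truth branch marker is the silenced
#' regulator.
#'
#' @param c_rep Mutual repression rate.
#' @param K Hill threshold.
#' @param n Hill coefficient.
#' @param gamma,beta,sigma As in [toggle_switch_spec()].
#' @param a_ramp Start and end self-activation rate.
#' @param t_ramp Ramp start and end times.
#' @return A [circuit_spec()] with genes `T1`, `T2`, `T3`.
#' @export
trifurcating_spec <- function(c_rep = 0.75, K = 1, n = 4, gamma = 1, beta = 1,
                              sigma = 0.025, a_ramp = c(0, 1.2),
                              t_ramp = c(20, 60)) {
  genes <- c("T1", "T2", "T3")
  pairs <- expand.grid(target = genes, regulator = genes,
                       stringsAsFactors = FALSE)
  rep_terms <- pairs[pairs$target != pairs$regulator, ]
  terms <- rbind(
    data.frame(target = rep_terms$target, regulator = rep_terms$regulator,
               rate = c_rep, K = K, n = n, type = "repression"),
    data.frame(target = genes, regulator = genes,
               rate = a_ramp[1], K = K, n = n, type = "activation")
  )
  circuit_spec(
    genes = genes,
    basal = setNames(rep(0, 3), genes),
    terms = terms, beta = beta,
    gammas = setNames(rep(gamma, 3), genes),
    sigma = sigma,
    # the ramp scales all three self-activation loops symmetrically
    ramp = list(gene = genes, regulator = genes, field = "rate",
                from = a_ramp[1], to = a_ramp[2],
                t_start = t_ramp[1], t_end = t_ramp[2])
  )
}
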