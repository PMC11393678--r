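#' Deterministic circuit simulation
#'
#' Integrates the 2M-dimensional splicing circuit with `deSolve::ode`
#' (adaptive `lsoda`, absolute/relative tolerance 1e-8) while the designated
#' bifurcation parameter follows the spec's ramp schedule. The analytic
#' Jacobian is evaluated at every output state with the current ramped
#' parameter, giving the ground-truth largest eigenvalue along the
#' trajectory.
#'
#' @param spec A [circuit_spec()].
#' @param x0 Initial state `c(U, S)` of length 2M; default: the steady
#'   state reached from small positive values at the ramp-start parameter.
#' @param t_grid Increasing numeric vector of output times.
#' @param eigen_times Times at which to evaluate the analytic Jacobian
#'   spectrum (default: all of `t_grid`; restrict to save time on very
#'   dense grids).
#' @return An object of class `circuit_trajectory`: tibble-backed list with
#'   `times`, state matrices `U`, `S`, `ramp` (parameter value per time)
#'   and `largest_real` (analytic leading eigenvalue per `eigen_times`
#'   entry, NA elsewhere).
#' @export
simulate_deterministic <- function(spec, x0 = NULL, t_grid,
                                   eigen_times = t_grid) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (is.unsorted(t_grid, strictly = TRUE)) abort("`t_grid` must be strictly increasing.")
  M <- length(spec$genes)
  if (is.null(x0)) {
    s0 <- rep(0.05, M)
    relax <- deSolve::ode(
      y = c(rep(0.05, M), s0), times = c(0, 500),
      func = circuit_deriv_desolve, parms = list(spec = spec, t_off = t_grid[1]),
      atol = 1e-8, rtol = 1e-8
    )
    x0 <- as.numeric(relax[nrow(relax), -1])
  }
  if (length(x0) != 2 * M) abort("`x0` must have length 2M.")

  sol <- deSolve::ode(
    y = x0, times = t_grid, func = circuit_deriv_desolve,
    parms = list(spec = spec, t_off = NULL),
    atol = 1e-8, rtol = 1e-8
  )
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed; see deSolve diagnostics.")
  }
  times <- sol[, 1]
  states <- sol[, -1, drop = FALSE]
  U <- states[, seq_len(M), drop = FALSE]
  S <- states[, M + seq_len(M), drop = FALSE]
  colnames(U) <- colnames(S) <- spec$genes

  lr <- rep(NA_real_, length(times))
  eval_idx <- which(times %in% eigen_times)
  for (i in eval_idx) {
    J <- circuit_jacobian_at(spec, U[i, ], S[i, ], ramp_value(spec, times[i]))
    lr[i] <- max(Re(eigen(J, only.values = TRUE)$values))
  }
  structure(
    list(times = times, U = U, S = S,
         ramp = ramp_value(spec, times), largest_real = lr, spec = spec),
    class = "circuit_trajectory"
  )
}

# deSolve rhs; `t_off` freezes the ramp at a fixed time when non-NULL.
circuit_deriv_desolve <- function(t, y, parms) {
  spec <- parms$spec
  M <- length(spec$genes)
  u <- y[seq_len(M)]
  s <- y[M + seq_len(M)]
  rv <- ramp_value(spec, parms$t_off %||% t)
  P <- as.numeric(circuit_production(
    spec, matrix(pmax(s, 0), 1, dimnames = list(NULL, spec$genes)), rv
  ))
  list(c(P - spec$beta * u, spec$beta * u - spec$gammas * s))
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf(
    "<circuit_trajectory> %d time points over [%g, %g]; genes: %s\n",
    length(x$times), min(x$times), max(x$times),
    paste(x$spec$genes, collapse = ", ")
  ))
  invisible(x)
}

#' Locate the eigenvalue zero crossing of a slow deterministic ramp
#'
#' Runs a quasi-static deterministic simulation across the given ramp
#' parameter bracket and returns the ramp-parameter value at which the
#' analytic largest eigenvalue along the trajectory first crosses zero
#' (linear interpolation between output points). The slower the ramp
#' (`duration`), the closer this lies to the true fold; it is the
#' simulation-side counterpart of the [locate_bifurcation()] continuation
#' oracle.
#'
#' @param spec A [circuit_spec()] with a ramp.
#' @param bracket Optional length-2 vector of ramp-parameter values to scan
#'   (default: the spec's full ramp range).
#' @param duration Time over which the bracket is traversed.
#' @param n_out Number of output points.
#' @param x0 Initial state (default: attractor at the bracket start, via
#'   [circuit_start_state()] when `maximize` is given).
#' @param maximize Passed to [circuit_start_state()] for the default start.
#' @return The ramp-parameter value at the first zero crossing (NA if none).
#' @export
eigen_crossing <- function(spec, bracket = NULL, duration = 4000,
                           n_out = 4000, x0 = NULL, maximize = NULL) {
  stopifnot(inherits(spec, "circuit_spec"), !is.null(spec$ramp))
  r <- spec$ramp
  if (!is.null(bracket)) {
    r$from <- bracket[1]
    r$to <- bracket[2]
  }
  r$t_start <- 0
  r$t_end <- duration
  spec$ramp <- r
  # start from the attractor at the bracket's first parameter value
  if (is.null(x0) && !is.null(maximize)) {
    x0 <- circuit_start_state(spec, maximize = maximize)
  }
  t_grid <- seq(0, duration, length.out = n_out + 1)
  traj <- simulate_deterministic(spec, x0 = x0, t_grid = t_grid)
  lr <- traj$largest_real
  cross <- which(lr[-length(lr)] <= 0 & lr[-1] > 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  frac <- -lr[i] / (lr[i + 1] - lr[i])
  p <- traj$ramp
  p[i] + frac * (p[i + 1] - p[i])
}

#' Initial state on a chosen attractor
#'
#' Returns the full state `c(U, S)` of a stable fixed point at the
#' ramp-start parameter value. When `maximize` names a gene, the stable
#' fixed point with the highest spliced expression of that gene is chosen
#' (e.g. the Y-high state of the toggle switch, or the epithelial state of
#' the EMT circuit); otherwise the stable point with the lowest total
#' expression is returned.
#'
#' @param spec A [circuit_spec()].
#' @param maximize Optional gene name.
#' @return Numeric state vector of length 2M.
#' @export
circuit_start_state <- function(spec, maximize = NULL) {
  fp <- find_fixed_points(spec)
  fp <- fp[fp$stable, , drop = FALSE]
  if (!nrow(fp)) abort("no stable fixed point at the ramp-start parameter.")
  scol <- paste0("s_", spec$genes)
  ucol <- paste0("u_", spec$genes)
  pick <- if (!is.null(maximize)) {
    which.max(fp[[paste0("s_", maximize)]])
  } else {
    which.min(rowSums(as.matrix(fp[, scol])))
  }
  c(as.numeric(fp[pick, ucol]), as.numeric(fp[pick, scol]))
}

#' Stochastic circuit simulation and cell sampling
#'
#' Euler-Maruyama integration with fixed step `dt` of `n_cells` independent
#' trajectories sharing the spec's parameter ramp. Noise is multiplicative
#' (`sigma * x * dW`, chemical-Langevin style) or additive per the spec;
#' negative excursions are clipped at zero each step and the clipped
#' fraction is reported. Every trajectory is recorded at `sample_times`,
#' and each (trajectory, time) snapshot becomes one cell of the returned
#' [splicing_counts()], with ordering equal to the sampling time.
#'
#' @param spec A [circuit_spec()].
#' @param n_cells Number of independent trajectories.
#' @param t_grid Length-2 vector `c(t0, t1)` of the simulated interval.
#' @param sample_times Times at which cells are sampled (default: 40
#'   evenly spaced times over `t_grid`).
#' @param dt Euler-Maruyama step.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param x0 Initial state `c(U, S)` shared by all trajectories (default as
#'   in [simulate_deterministic()]).
#' @param zero_floor Sampled abundances below this value are recorded as
#'   exact zeros (default 1e-6): the state variables are molecule counts,
#'   so sub-molecule residues of a silenced gene are noise, and recording
#'   them as zero lets the per-window fit exclude the gene cleanly.
#' @return An object of class `simulated_lineage`: list with `counts` (a
#'   [splicing_counts()]; cell ids encode trajectory and sample index),
#'   `truth` (ramp values at sample times, clipped fraction, spec) and
#'   `trajectory_of` (integer trajectory index per cell).
#' @export
simulate_stochastic <- function(spec, n_cells, t_grid, sample_times = NULL,
                                dt = 0.01, seed = 1, x0 = NULL,
                                zero_floor = 1e-6) {
  stopifnot(inherits(spec, "circuit_spec"), length(t_grid) == 2L)
  if (spec$sigma < 0) abort("noise amplitude must be nonnegative.")
  M <- length(spec$genes)
  if (is.null(sample_times)) {
    sample_times <- seq(t_grid[1], t_grid[2], length.out = 40)
  }
  if (is.null(x0)) {
    x0 <- simulate_deterministic(
      spec, t_grid = c(t_grid[1], t_grid[1] + 1e-6)
    )
    x0 <- c(x0$U[1, ], x0$S[1, ])
  }
  # explicit-Euler linear stability bound for the relaxation rates
  if (dt * max(spec$beta, spec$gammas) >= 2) {
    abort(sprintf(
      "step too large: dt = %g violates the Euler stability bound 2/max(beta, gamma) = %g; try a smaller `dt`.",
      dt, 2 / max(spec$beta, spec$gammas)
    ))
  }
  set.seed(seed)
  n_steps <- ceiling((t_grid[2] - t_grid[1]) / dt)
  Umat <- matrix(rep(x0[seq_len(M)], each = n_cells), n_cells, M)
  Smat <- matrix(rep(x0[M + seq_len(M)], each = n_cells), n_cells, M)
  colnames(Umat) <- colnames(Smat) <- spec$genes

  snapshots_U <- vector("list", length(sample_times))
  snapshots_S <- vector("list", length(sample_times))
  sample_steps <- pmin(pmax(round((sample_times - t_grid[1]) / dt), 0), n_steps)
  clipped <- 0
  total <- 0
  t <- t_grid[1]
  take <- which(sample_steps == 0L)
  for (k in take) {
    snapshots_U[[k]] <- Umat
    snapshots_S[[k]] <- Smat
  }
  sq_dt <- sqrt(dt)
  for (step in seq_len(n_steps)) {
    rv <- ramp_value(spec, t)
    P <- circuit_production(spec, Smat, rv)
    dU_det <- (P - spec$beta * Umat) * dt
    dS_det <- (spec$beta * Umat - sweep(Smat, 2L, spec$gammas, `*`)) * dt
    if (spec$sigma > 0) {
      Zu <- matrix(rnorm(n_cells * M), n_cells, M)
      Zs <- matrix(rnorm(n_cells * M), n_cells, M)
      if (spec$noise == "multiplicative") {
        dU_noise <- spec$sigma * Umat * sq_dt * Zu
        dS_noise <- spec$sigma * Smat * sq_dt * Zs
      } else {
        dU_noise <- spec$sigma * sq_dt * Zu
        dS_noise <- spec$sigma * sq_dt * Zs
      }
    } else {
      dU_noise <- dS_noise <- 0
    }
    Umat <- Umat + dU_det + dU_noise
    Smat <- Smat + dS_det + dS_noise
    if (any(!is.finite(Umat)) || any(!is.finite(Smat)) ||
        max(Umat, Smat) > 1e8) {
      # these circuits are bounded by production/degradation balance, so
      # runaway magnitudes indicate numerical instability of the step
      abort("stochastic integration blew up; try a smaller `dt`.")
    }
    neg <- sum(Umat < 0) + sum(Smat < 0)
    clipped <- clipped + neg
    total <- total + 2 * n_cells * M
    Umat[Umat < 0] <- 0
    Smat[Smat < 0] <- 0
    t <- t + dt
    take <- which(sample_steps == step)
    for (k in take) {
      snapshots_U[[k]] <- Umat
      snapshots_S[[k]] <- Smat
    }
  }

  n_t <- length(sample_times)
  Uall <- do.call(rbind, snapshots_U)
  Sall <- do.call(rbind, snapshots_S)
  Uall[Uall < zero_floor] <- 0
  Sall[Sall < zero_floor] <- 0
  traj_of <- rep(seq_len(n_cells), times = n_t)
  time_of <- rep(sample_times, each = n_cells)
  ids <- sprintf("c%04d_t%03d", traj_of, rep(seq_len(n_t), each = n_cells))
  counts <- splicing_counts(
    Uall, Sall, ordering = time_of,
    gene_names = spec$genes, cell_ids = ids
  )
  structure(
    list(
      counts = counts,
      trajectory_of = setNames(traj_of, ids),
      truth = list(
        sample_times = sample_times,
        ramp_at_sample = ramp_value(spec, sample_times),
        clipped_fraction = clipped / max(total, 1),
        seed = seed, dt = dt, spec = spec
      )
    ),
    class = "simulated_lineage"
  )
}

#' @export
print.simulated_lineage <- function(x, ...) {
  cat(sprintf(
    "<simulated_lineage> %d cells (%d trajectories x %d times); clipped %.3g%%\n",
    length(x$counts$cell_ids), max(x$trajectory_of),
    length(x$truth$sample_times), 100 * x$truth$clipped_fraction
  ))
  invisible(x)
}

#' Assign trifurcation branch labels from terminal marker expression
#'
#' Labels every cell of a trifurcating simulation with the branch its
#' trajectory committed to. In the trifurcating circuit, commitment
#' silences exactly one of the three master regulators (the other two stay
#' on), so a trajectory's branch is named after the regulator that is OFF
#' in its terminal spliced state. Trajectories whose terminal state shows
#' no clear silencing (range of regulator expression below `threshold`,
#' e.g. still near the symmetric progenitor state) are labelled
#' `"uncommitted"`.
#'
#' @param sim A `simulated_lineage` from [simulate_stochastic()] of a
#'   [trifurcating_spec()].
#' @param threshold Minimal spread between the most- and least-expressed
#'   regulator at the terminal time for a trajectory to count as committed.
#' @return The input `sim` with `counts$branch_labels` filled in and a
#'   `branch_of_trajectory` element added.
#' @export
label_branches <- function(sim, threshold = 0.8) {
  stopifnot(inherits(sim, "simulated_lineage"))
  counts <- sim$counts
  genes <- counts$gene_names
  last_time <- max(counts$ordering)
  terminal <- counts$ordering == last_time
  term_traj <- sim$trajectory_of[terminal]
  term_S <- counts$spliced[terminal, , drop = FALSE]
  silenced <- genes[apply(term_S, 1L, which.min)]
  committed <- apply(term_S, 1L, function(s) diff(range(s))) >= threshold
  branch <- ifelse(committed, silenced, "uncommitted")
  branch_of_traj <- setNames(branch, term_traj)[as.character(sort(unique(term_traj)))]
  labels <- unname(branch_of_traj[as.character(sim$trajectory_of)])
  sim$counts$branch_labels <- labels
  sim$branch_of_trajectory <- branch_of_traj
  sim
}
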