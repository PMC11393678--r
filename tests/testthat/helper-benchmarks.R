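# Shared simulated benchmarks, built once per test run.
.bench_cache <- new.env(parent = emptyenv())

bench <- function(name, builder) {
  if (!exists(name, envir = .bench_cache)) {
    assign(name, builder(), envir = .bench_cache)
  }
  get(name, envir = .bench_cache)
}

toggle_bench <- function() {
  bench("toggle", function() {
    spec <- toggle_switch_spec()
    x0 <- circuit_start_state(spec, maximize = "Y")
    sim <- simulate_stochastic(spec, n_cells = 100, t_grid = c(0, 100),
                               sample_times = seq(2.5, 100, by = 2.5),
                               dt = 0.01, seed = 7, x0 = x0)
    cfg <- window_config(width = 400, increment = 100, seed = 11)
    list(spec = spec, x0 = x0, sim = sim, cfg = cfg,
         scan = scan_lineage(sim$counts, cfg))
  })
}

emt_bench <- function() {
  bench("emt", function() {
    spec <- emt_tristable_spec()
    x0 <- circuit_start_state(spec, maximize = "miR200")
    sim <- simulate_stochastic(spec, n_cells = 100, t_grid = c(0, 360),
                               sample_times = seq(5, 360, by = 5),
                               dt = 0.01, seed = 3, x0 = x0)
    cfg <- window_config(width = 600, increment = 150, seed = 5)
    list(spec = spec, x0 = x0, sim = sim, cfg = cfg,
         scan = scan_lineage(sim$counts, cfg))
  })
}

trif_bench <- function() {
  bench("trif", function() {
    spec <- trifurcating_spec()
    x0 <- circuit_start_state(spec)
    sim <- simulate_stochastic(spec, n_cells = 150, t_grid = c(0, 120),
                               sample_times = seq(2.5, 120, by = 2.5),
                               dt = 0.01, seed = 2, x0 = x0)
    sim <- label_branches(sim)
    counts <- sim$counts
    scans <- list()
    for (b in c("T1", "T2", "T3")) {
      cells <- counts$cell_ids[counts$branch_labels == b]
      cfg <- window_config(width = 320, increment = 80, seed = 5)
      scans[[b]] <- scan_lineage(subset_cells(counts, cells), cfg)
    }
    list(spec = spec, sim = sim, counts = counts, scans = scans)
  })
}
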