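# tipscan

Tipping-point detection along single-cell lineages from RNA splicing
dynamics.

## The problem

During fate transitions — differentiation, the epithelial–mesenchymal
transition (EMT), reprogramming — cells leave one stable expression state
and pass through an unstable intermediate before settling into the next.
Locating these *tipping points* from snapshot single-cell RNA-seq is hard
because snapshots carry no explicit dynamics. tipscan exploits the
temporal information hidden in the ratio of unspliced (nascent) to spliced
(mature) transcripts: for each gene $i$,

$$\frac{dU_i}{dt} = A_{i0} + \sum_{j\ne i} A_{ij}\,S_j - \beta U_i,
\qquad \frac{dS_i}{dt} = \beta U_i - \gamma_i S_i,$$

with splicing rate $\beta$ (set to 1 by measuring time in units of
$1/\beta$), degradation rates $\gamma_i$, and a gene–gene interaction
matrix $A$. A window sliding along a cell ordering (pseudotime or
experimental time) fits this model by regression in each window, assembles
the $2M \times 2M$ Jacobian

$$J = \begin{pmatrix} -\beta I & A \\ \beta I & -\mathrm{diag}(\gamma)\end{pmatrix},$$

and tracks its eigenvalues: windows where the largest real part turns
positive are the tipping points. The per-window $A$ doubles as a directed
gene regulatory network (GRN), whose community structure and edge-weight
spread quantify how regulation rearranges across the transition.

The package is aimed at computational biologists who have spliced and
unspliced count matrices (e.g. from velocyto or kallisto) plus a cell
ordering, and at modellers who want a fully synthetic, ground-truthed
sandbox: it ships stochastic simulators for a bistable toggle switch, a
tristable EMT circuit and a trifurcating fate circuit, together with
brute-force fixed-point and bifurcation oracles.

## Worked example: finding the toggle-switch tipping point

Simulate 100 cells/trajectories through a saddle-node transition (the
feedback-inhibition ramp destroys the Y-high state), then scan the lineage:

```r
library(tipscan)

spec <- toggle_switch_spec()
spec
#> <circuit_spec> genes: X, Y; 2 Hill terms; beta = 1; sigma = 0.05 (multiplicative noise)
#>   ramp: K of Y <- X from 1 to 0.2 over t in [20, 80]

x0  <- circuit_start_state(spec, maximize = "Y")   # start on the Y-high attractor
sim <- simulate_stochastic(spec, n_cells = 100, t_grid = c(0, 100),
                           sample_times = seq(2.5, 100, by = 2.5),
                           dt = 0.01, seed = 1, x0 = x0)
sim
#> <simulated_lineage> 4000 cells (100 trajectories x 40 times); clipped 0%

scan <- scan_lineage(sim$counts, window_config(width = 400, increment = 100, seed = 1))
scan
#> <lineage_scan> 37 windows (width 400, increment 100) over 4000 cells
#>   mean largest Re(eig): min -0.5222, max 0.0694
```

The profile is negative (stable) at both ends and spikes above zero in one
narrow region:

```r
s <- scan$summary
s[which.max(s$largest_real_mean) + (-1:1),
  c("window", "position", "largest_real_mean", "largest_real_sd")]
#> # A tibble: 3 × 4
#>   window position largest_real_mean largest_real_sd
#>    <int>    <dbl>             <dbl>           <dbl>
#> 1     28     73.8           -0.0233         0.00631
#> 2     29     76.2            0.0694         0.00209
#> 3     30     78.8            0.0142         0.00411
```

The inferred tipping point (window centred at t = 76.2, largest eigenvalue
0.069 ± 0.002 over 10 subsampling iterations) can be checked against the
ground truth, a brute-force continuation of the circuit's fixed points:

```r
kstar <- locate_bifurcation(spec, lower = 1, upper = 0.2, tol = 1e-7)
kstar
#> [1] 0.2943807        # fold of the Y-high branch, in ramp-parameter units
# the ramp passes this value at t* = 72.9 — within one window span (10 t units)
```

`autoplot(scan)` draws the profile with error bars;
`instability_score(scan, sim$counts)` maps it back to per-cell scores;
`community_trajectory(scan, sim$counts)` tracks GRN communities per
window; `tidy()`/`glance()` return broom-style tibbles. The same pipeline
runs from the shell:

```sh
exec/tipscan simulate toggle --n-cells 100 --seed 1 --out sim/
exec/tipscan infer --input sim/ --width 400 --increment 100 --seed 1 --out out/
```

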