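---
title: "Detecting tipping points along single-cell lineages with tipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tipping points along single-cell lineages with tipscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipscan)
```

## The model

Cell-fate commitment is often pictured as motion on an attractor landscape:
stable cell states are valleys, and a transition passes through an unstable
ridge — a *tipping point* — where the cell has left one attractor but not
yet reached the next. tipscan infers the local stability of cells along a
lineage directly from single-cell RNA-seq data, using the fact that
unspliced (nascent) and spliced (mature) transcript counts carry a time
delay relative to each other.

Per gene $i$, the package's linear splicing model is

$$\frac{dU_i}{dt} = A_{i0} + \sum_{j \ne i} A_{ij} S_j - \beta U_i, \qquad
  \frac{dS_i}{dt} = \beta U_i - \gamma_i S_i,$$

where $U_i, S_i$ are unspliced and spliced abundances, $\beta$ the shared
splicing rate, $\gamma_i$ a per-gene degradation/dilution rate, and
$A_{ij}$ the transcriptional effect of (spliced) gene $j$ on the production
of gene $i$ — positive for activation, negative for inhibition, and exactly
zero on the diagonal (self terms are carried by $\beta$ and $\gamma_i$). A
shared splicing rate lets time be measured in units of $1/\beta$, so
$\beta = 1$ by default. The assumption that justifies fitting the
production balance at quasi-steady state is timescale separation: splicing
relaxes in minutes while fate transitions take days.

The Jacobian of this $2M$-dimensional system, with state ordered
$(U_1..U_M, S_1..S_M)$, has four quadrants:

$$J = \begin{pmatrix} -\beta I & A \\ \beta I & -\operatorname{diag}(\gamma) \end{pmatrix}.$$

Any eigenvalue of $J$ with positive real part marks local instability. When
all $\gamma_i = \gamma_0$, each eigenvalue $\mu$ of $A$ maps to a pair of
Jacobian eigenvalues through $(\lambda+\beta)(\lambda+\gamma_0)=\beta\mu$;
this closed-form identity is used as an oracle in the test suite.

## The sliding-window scan

Cells are sorted by a lineage ordering (pseudotime, or the rank of an
experimental time label), ties broken by cell id so the scan is
deterministic. A window of `width` cells advances by `increment`; inside
each window, each gene's production balance is solved as a regression of
$\beta U_i$ on the spliced expression of the other genes,

$$\min_{A_{i0}, \{A_{ij}\}} \sum_{c} \Big(A_{i0} + \sum_{j \ne i} A_{ij} S_{jc} - \beta U_{ic}\Big)^2 + \lambda F,$$

with an optional ridge ($F = \sum A_{ij}^2$) or lasso
($F = \sum |A_{ij}|$) penalty on the interaction coefficients only — never
on the intercept, the standard convention for penalized regression.
Degradation rates come from the spliced balance at steady state by
through-origin least squares,
$\gamma_i = \beta \sum_c U_{ic} S_{ic} / \sum_c S_{ic}^2$, whose
single-cell limit is the ratio $\beta U_i / S_i$. Ridge fits use the
closed-form centered normal equations (they are checked against an
independent normal-equations oracle at $10^{-10}$); lasso fits use
coordinate descent via glmnet, with the penalty rescaled to the objective
above.

Error bars come from refitting each window `n_iterations` (default 10)
times on random subsamples of `subsample_fraction` (default 0.9) of its
cells, without replacement and fully seeded. This reproduces
iteration-to-iteration spread without inventing a noise model. Windows are
defined by cell count rather than by pseudotime span so every fit has the
same statistical power; a window's lineage coordinate is the mean ordering
of its cells.

Genes whose spliced counts are zero — or nonzero in fewer than
`max(3, 2%)` of a window's cells — are excluded from that window's model
and recorded on the fit, never dropped silently: a regressor supported on
a handful of cells is not identifiable, and its through-origin degradation
fit is pure noise. The window's Jacobian shrinks to the realized dimension
and the positive-eigenvalue fraction uses that dimension.

### Free parameters

| parameter | default | units | role |
|---|---|---|---|
| `width` | data-dependent | cells | statistical power vs. lineage resolution |
| `increment` | data-dependent | cells | sampling density of the profile |
| `n_genes` | all | genes | model dimension (top mean spliced expression) |
| `n_iterations` | 10 | – | subsampling repeats for error bars |
| `subsample_fraction` | 0.9 | – | fraction of window cells per repeat |
| `shrinkage` | 0 | – | ridge/lasso penalty $\lambda$ |
| `beta` | 1 | 1/time | splicing rate (sets the time unit) |

As a rule of thumb the window should hold at least five cells per model
gene (the exact-recovery tests run at that ratio), and the increment a
quarter of the width.

## Stability read-outs

Three spectral metrics are tracked per window: the largest eigenvalue real
part, the number of eigenvalues with strictly positive real part, and that
count divided by the number of eigenvalues. Strict positivity means a
marginal eigenvalue exactly at zero — the bifurcation point itself —
counts as non-positive; complex eigenvalues are judged by real part, the
standard linear-stability criterion.

The per-cell *instability score* maps window-level stability back to
cells: the per-window mean largest eigenvalue is Gaussian-smoothed
(reflecting boundaries, kernel renormalized to sum to one), clamped below
at zero, and each cell inherits the value of the window nearest its
ordering value. For multi-branch lineages the scan runs per branch and a
cell's global score is the maximum over the branches containing it — a
deliberate design choice: it preserves "unstable in any branch means
unstable", and unlike a sum it does not inflate scores for cells shared
by many branches. The smoothing bandwidth is one
window by default; for lineages whose transition spans only a couple of
windows (the trifurcating benchmark) half a window retains the spike.

## GRN reconstruction

Within a window, the fitted interaction matrix is read as a directed,
signed gene regulatory network: edge $j \to i$ carries $A_{ij}$, rescaled
by the expression of the sender (regulator) gene so that a silent
regulator activates no edges. The sender scale is the per-gene mean
spliced expression in the window, min–max scaled across genes — min–max
keeps "zero expression implies zero edge" exact. Edges below the 0.75
quantile of nonzero absolute weights are pruned (the quantile, rather than
an absolute cutoff, keeps the pruning comparable across windows whose
coefficient scales differ). Genes excluded from the window's fit remain in
the graph as isolated nodes.

Community structure is computed on the undirected projection with edge
weight equal to the absolute rescaled weight (antiparallel edges summed),
because the modularity-based algorithms are undirected. Greedy modularity
(Clauset–Newman–Moore) cuts its agglomerative dendrogram at the
best-modularity level, re-evaluated explicitly at every cut since the
stored cut can be off at near-ties. Girvan–Newman removes the edge of
highest betweenness — shortest paths measured with distance $1/|w|$ — and
returns the partition along the divisive hierarchy with maximal weighted
modularity. Isolated genes each count as one community. Betweenness
rankings use the directed graph with the same $1/|w|$ distances, ties
broken alphabetically.

## Benchmark circuits

The package ships three stochastic circuit simulators with ground truth,
so the whole pipeline can be exercised and checked without external data.
All three use Hill-function production, a splicing layer per gene
($U \to S$), Euler–Maruyama integration with multiplicative noise
$\sigma x\,dW$ (chemical-Langevin style; additive available), per-step
clipping at zero, and a linear ramp of one designated bifurcation
parameter. Sampled abundances below $10^{-6}$ are recorded as exact zeros:
the variables are molecule counts, and sub-molecule residue on a silenced
gene is integration noise. Ground truth comes from a brute-force
fixed-point oracle (dense Newton starts on a grid in spliced-state space,
deduplication, stability via the analytic Jacobian) and a bisection
continuation that locates each bifurcation to $10^{-6}$ in the ramp
parameter.

**Toggle switch** — two genes X and Y under mutual Hill repression
($a = 2$, $K = 1$, $n = 4$, $\gamma = 1$, $\sigma = 0.05$): bistable at
the ramp start, with the ramp tightening the repression threshold of the
X⊣Y edge (strengthening the feedback inhibition of Y by X) until the
Y-high state is annihilated in a saddle-node at $K^* \approx 0.294$. An
optional set of constitutively expressed, non-interacting genes
(`n_extra`, basal rate 0.3) pads the dimension for sensitivity analyses
without altering the fixed-point structure.

**Tristable EMT circuit** — an epithelial regulator (miR200-like) and a
mesenchymal regulator (ZEB1-like) with mutual inhibition and
self-activation ($a = 0.86$, $b = 1$, $K = 0.5$, $n = 4$), plus four
slaved marker genes (CDH1/EPCAM activated by the epithelial side, VIM/FN1
by the mesenchymal side) that enrich the reconstructed GRN without
changing the attractor count. The self-activation strength sits just below
the self-sustainment threshold ($\approx 0.877$): close enough for a
robustly stable hybrid state, below it so the hybrid dies at finite
signal. Ramping the mesenchymal basal production (an EMT-inducing signal)
from 0 to 0.5 destroys first the epithelial state
($s_1^* \approx 0.197$), then the hybrid ($s_2^* \approx 0.377$) — two
successive saddle-nodes, so a slow ramp carries cells E → I → M and the
inferred profile shows two spikes. The simulated horizon extends well past
the second fold (to $t = 360$ for the default ramp) so the last windows
hold settled mesenchymal cells; the transition is strongly asynchronous
(cells traverse a near-tangency of the epithelial self-activation), which
is realistic but smears the spikes, and is the reason the benchmark's
spike amplitudes are small ($\sim 0.01$) rather than order one.

**Trifurcating circuit** — three master regulators in all-to-all mutual
repression ($c = 0.75$, $K = 1$, $n = 4$) with a ramped self-activation
loop. At the ramp start the symmetric co-expressed state is the only
attractor (the progenitor state S). As self-activation grows, three
committed attractors appear at a distance — each with exactly one
regulator silenced, the other two on — while the progenitor is still
stable; shortly after, the progenitor destabilizes, a subcritical symmetry
breaking, and noise picks one of three fates. The subcritical (jump-like)
regime matters: in supercritical parameter sets the branches emerge
continuously and cells track weakly stable states the whole way, so the
inferred largest eigenvalue approaches but never crosses zero. Branch
ground truth is the silenced regulator; the fast ramp
($a: 0 \to 1.2$ over $t \in [20, 60]$) with low noise ($\sigma = 0.025$)
produces a delayed, decisive escape whose inferred profile is genuinely
positive inside the transition on all three branches.

### What the simulations do and do not emulate

The generators produce continuous abundances with multiplicative
intrinsic noise along asynchronous transitions, sampled as (trajectory,
time) snapshot cells — capturing the mixture-of-stages structure of real
time-course data. They do not emulate technical dropout, mRNA capture
inefficiency, discreteness of UMI counts, cell-cycle covariates, or
pseudotime estimation error (the ordering is true simulation time). A
passing benchmark therefore shows the inference machinery is sound on
clean dynamics of the assumed model class, not that any particular real
data set satisfies those assumptions. One property of real data the clean
benchmarks provably cannot reproduce: with a single unstable direction,
the positive-eigenvalue count is one regardless of model dimension, so
the dimension-normalized positive fraction differs exactly twofold
between 5- and 10-gene models. In real data, where the number of marginal
eigenvalues tends to scale with the gene count, that normalization is what
makes profiles of different dimensionality comparable.

## Numerical choices

* Deterministic integration: `deSolve::ode` (lsoda) at tolerance $10^{-8}$.
* Locating the eigenvalue zero crossing of a ramped run: the crossing
  parameter converges to the true fold like (ramp rate)$^{2/3}$ — the
  classic slow-passage scaling — so the packaged protocol is two-stage: a
  coarse full-range ramp brackets the fold, then a slow ramp over a
  narrow bracket refines it (measured error $\sim 5\times10^{-4}$ in ramp
  units against the continuation oracle).
* Stochastic integration: fixed-step Euler–Maruyama, $dt = 0.01$ by
  default; runaway magnitudes (circuits are bounded by their
  production/degradation balance) raise an error suggesting a smaller
  step.
* Window enumeration: `floor((N - width)/increment) + 1` full windows; a
  trailing partial window is dropped.
* Gene selection ties are broken alphabetically; cell-ordering ties by
  cell id; both make reruns bit-identical under one seed.
* Degenerate regressors: see the per-window exclusion rule above.
* Quantiles (edge pruning, IQR) use R's default type-7 rule.

## Known limitations

* The model is linear in the window; strongly nonlinear regulation within
  a single window is averaged into effective linear coefficients.
* The estimator slightly underestimates positive eigenvalues at sharp
  transitions: unspliced counts lag the regressors, which biases inferred
  coefficients downward while cells accelerate away from an unstable
  state. Spikes are therefore conservative in amplitude.
* A constant, shared splicing rate is assumed; genes with atypical
  splicing kinetics will distort their rows of the interaction matrix.
* Pseudotime quality is inherited, not checked: a poor ordering mixes
  stages within windows and flattens the profile.
* Reading counts requires the MTX + CSV layout documented in
  `read_splicing_counts()`; HDF5-backed formats are not read.

## Problem sizes used in the shipped analyses

The packaged benchmark analyses use 4 000 cells for the toggle switch
(100 trajectories × 40 sampling times; windows of 400 cells advancing by
100), 7 200 cells for the EMT circuit (100 × 72; windows of 600 by 150),
and 7 200 cells for the trifurcating circuit (150 × 48; per-branch
windows of 320 by 80), with 10 subsampling iterations per window
throughout. These sizes give stable profiles with visible error bars
while keeping a full rerun of every analysis in the order of minutes on
one CPU.
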