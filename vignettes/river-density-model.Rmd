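---
title: "Modelling a riparian species' density with a river-anchored Markov random field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a riparian species' density with a river-anchored Markov random field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverMRF)
```

## The problem

riverMRF estimates a year-average density surface for a species that is
attracted to a river, in the regime where field data are extremely sparse: a
handful of individuals recorded on a short river transect and a few off-river
survey parcels over a whole field year. The motivating case is a
near-threatened spikethumb frog population near the Tacaná volcano
(Chiapas/Guatemala border): 17 individuals on a 75 m transect over 10 trips,
and 3 individuals on five 5 m parcels. Counts this sparse cannot support a
per-cell occupancy or point-process fit; realizations of sparse point
processes also seed artificial clusters once neighbour interactions are
introduced. The model therefore works with *densities* rather than counts.

## The model

The study rectangle is a lattice of square cells. Cells covering the river
form the set $R$; the remaining cells split into 4-connected regions
$\Lambda^1, \dots, \Lambda^k$ separated by the river. A configuration assigns
each off-river cell a density $\omega_t \in [0, K]$, where the cap

$$K = \frac{\text{river count}}{\text{transect cells} \times \text{trips}}$$

is the observed year-average per-cell density on the river (0.113 for the
case study), where density is assumed maximal. River cells are frozen at the
boundary value $K$: the river is data, not state.

Configurations are weighted by a Gibbs measure $\pi(\omega) \propto
e^{-H(\omega)/T}$ with Hamiltonian $H = H_0 + V_g$:

* the spreading term $H_0 = \sum_{t_1 \sim t_2} (\omega_{t_1} -
  \omega_{t_2})^2$, summed once over each unordered pair of 4-adjacent cells,
  plus one term $(\omega_t - K)^2$ for every incidence of a cell with an
  adjacent river cell. $H_0$ is minimized by constant fields: left alone, the
  population spreads.
* the potential well $V_g = g \sum_t d_t^2\, \omega_t$, where $d_t$ is the
  river distance of cell $t$. It penalizes density far from the river with
  strength $g$ (the coupling constant), modelling attraction to water. The
  quadratic shape is a deliberate one-parameter choice — the data cannot
  support a richer well.

Because $H$ only couples 4-neighbours and the river row of values is fixed,
the regions are conditionally independent given the river: the full measure
factorizes over regions, and every computation here (energies, chains,
calibration) runs per region. This is checked to $10^{-12}$ relative
precision in the test suite.

### The river distance

$d_t = M_t + A_t$ decomposes into the minimal absolute column offset $M_t$ to
any river cell, plus the minimal absolute row offset $A_t$ to a river cell in
a column achieving that minimum. Distances are in *cell units*, not meters;
only the product $g\,d^2$ is identifiable, so the coupling absorbs the
physical scale. When several river cells achieve the same column offset, the
one with the smallest row offset (then the smallest row index) is the
nominal minimizer; the resulting $d$ does not depend on the tie-break.
$d = 0$ exactly on the river and $d \ge 1$ elsewhere.

## Sampling

The measure is sampled by a single-site Metropolis chain (`run_chain()`). One
*sweep* visits every region cell once in a fixed *layered ordering*: layer 0
is all river-adjacent cells, layer $\ell + 1$ the unvisited neighbours of
earlier layers, row-major within a layer. At each cell a proposal is drawn
uniformly on $[0, K]$; it is accepted outright when it lowers $H$, otherwise
with probability $e^{-\Delta H / T}$. The layered ordering matters: within a
single sweep, fresh boundary information propagates inward layer by layer
(a Gauss–Seidel front), which is what makes short annealing schedules
workable.

Implementation notes:

* $\Delta H$ is computed from the cell's at most four neighbour terms and its
  potential term, in O(1) (`delta_energy()` is the reference R
  implementation; the compiled sweep loop repeats the same arithmetic).
* The per-sweep energy trace is recomputed in full extended precision at the
  end of every sweep rather than accumulated incrementally, so traces are
  exact and never drift negative.
* All randomness comes from R's generator (proposal first, acceptance draw
  only when needed), so a seed makes a chain bit-reproducible.
* `tail_average` accumulates a running mean of the last end-of-sweep states —
  the estimate of the per-cell expected density — without storing the chain
  history. End-of-sweep states (rather than every single-site state) are
  averaged; at stationarity the two estimators agree and the former is
  cheaper.

### Temperatures, and why there are two

$T$ sets how sharply the measure concentrates on low-energy states. Three
regimes matter in practice:

* $T$ large: the chain mixes but the measure is diffuse — tail averages sit
  far from the minimizer, with large Monte-Carlo noise.
* $T$ very small: almost every proposal is rejected (the acceptance window
  around the local optimum has width $\sim \sqrt{T}$ out of the full $[0,K]$
  proposal range), and relaxation from a cold start becomes diffusively slow.
* In between, a single temperature still pays an *entropic deficit*: because
  values are capped at $K$, equilibrium fluctuations around the free-case
  minimizer $\omega \equiv K$ are one-sided and the mean sits
  $O(\sqrt{T})$ below it.

The production recipe (`two_stage_chain()`, `fit_density_map()`) therefore
runs one chain at $T_1$ from the zero state, then warm-starts a second chain
at $T_2 < T_1$ from its tail average and reports the second tail average.
Stage 1 does the large-scale relaxation quickly; stage 2 removes most of the
entropic deficit. One temperature drop proved sufficient; the schedule is not
iterated further.

At desk scale (regions of a few hundred cells, used throughout the tests and
examples) the package defaults to $T_1 = 10^{-5}$, $T_2 = T_1/100$ and
$10^4$–$10^5$ sweeps per stage; with these choices the free-case chain ends
within 3% of the exact minimizer $\omega \equiv K$ on every seed tried, and a
full two-stage fit takes seconds. The case-study preset
(`tacana_preset()`) documents the values calibrated on the original
full-scale geometry ($T_1 = 4.75 \times 10^{-6}$, $T_2 = 2 \times 10^{-8}$,
$\hat g = 3.25\times 10^{-7}$, $10^6$ sweeps); they are shipped as reference
data, not defaults, because the original river raster is not published and
those magnitudes are specific to its 13715-cell region.

## Calibration

`compute_K()` fixes the cap from the transect counts. The temperature
$T_1$ is selected by `select_T1()` in the free case ($g = 0$), where the
minimizer is known exactly (constant $K$, energy 0): each candidate runs a
chain from zero and the candidate with the smallest tail-average energy wins.

The coupling $\hat g$ is then matched to the off-river data
(`estimate_g()`): the observed parcels carry an expected year-average count
(3 individuals / 10 trips = 0.3 for the case study), and the model's
counterpart is the tail-average density summed over the parcel cells. Since
stronger attraction strips density from the parcels, the parcel expectation
is non-increasing in $g$ (checked at run time, within a Monte-Carlo
allowance); the match is found by doubling $g$ from a geometry-scaled start
until the expectation first falls below the target, then bisecting. Each
evaluation is a full two-stage chain on a fixed seed. In the low-temperature
regime the evaluation map $g \mapsto$ expectation is smooth and nearly
noise-free — the Hamiltonian is convex, so the chain output hugs the unique
constrained minimizer — which is what makes bracketing + bisection reliable.
The default matching tolerance is 0.01 expected individuals (absolute),
configurable.

A genuinely unreachable target — larger than the free-case expectation —
raises an error: attraction can only *reduce* off-river density, so such
data would falsify the model rather than calibrate it.

## From densities to maps and simulated observations

The fitted surface $\hat\omega$ supports three renderings:

* **Heat map** (`heatmap_bins()`): seven rainbow bins, constant on
  $((s/7)K, ((s+1)/7)K]$ for $s = 0..6$, red through violet with increasing
  intensity. A density of exactly 0 falls outside every half-open interval
  and is assigned bin 0 by convention (it must render at the lowest
  intensity). River cells are drawn black.
* **Whole-year realization** (`year_counts()`): independent Poisson draws
  with mean $\text{trips} \times \hat\omega$ per cell — what a full field
  year could have recorded.
* **Single-trip realization** (`trip_presence()`): independent Bernoulli
  draws with success $\hat\omega$ (valid since $K < 1$) — what one average
  trip could have seen.

Realizations are drawn only on off-river cells: river cells carry the fixed
boundary density already summarized by $K$, and their observed individuals
are field data, not simulation targets. Dot plots jitter count markers
uniformly within the cell square; the placement within a cell carries no
information.

## The synthetic geometry generator

The original river raster exists only as published figures, so
`make_river()` generates stand-in geometries: a random monotone lattice path
crossing the grid top-to-bottom, dilated to the requested width, kept
4-connected (diagonal steps insert the intermediate cell), optionally forked
once. A width-1 band splits the grid into exactly two regions; a fork
encloses a middle region (three, occasionally four, components).
`planted_scenario()` additionally plants parcels in the largest region and
runs the production chain at a known $g^\ast$, producing a ground-truth
surface whose parcel expectation can be fed back to `estimate_g()` — the
parameter-recovery loop used by the acceptance tests.

What these geometries emulate: a connected, roughly one-cell-wide river that
separates the grid, with realistic distance fields and region shapes. What
they do not emulate: the meandering, variable-width hydrology of the real
river, terrain effects, or the specific 13715-cell region of the case study.
Passing tests therefore certify the *machinery* — energies, decoupling,
sampling, calibration — on geometries of the same kind, not the published
full-scale map values, which additionally depend on the unpublished raster.

## Numerical choices and degenerate inputs

* Grid coordinates are 0-based from the north-west corner; UTM conversion
  uses nearest-integer rounding of the anchored offsets, the convention that
  reproduces the published parcel table exactly.
* Full-grid energies are accumulated in extended precision (R's long-double
  `sum()` and a long-double accumulator in the compiled loop); at desk scale
  the energy is a sum of ~$10^3$–$10^5$ terms of magnitude up to $K^2$,
  while meaningful differences can be many orders smaller.
* Region numbering is deterministic (decreasing size, ties by first
  row-major cell) so that "region 1" is stable across runs and platforms.
* Degenerate inputs have defined behaviour: an all-river mask yields zero
  regions; a single-cell region is a legal chain domain (independent draws
  filtered by Metropolis); a region with no river-adjacent cell is rejected,
  because the model requires a boundary; a transect length that is not a
  whole number of cells rounds down with a warning.
* `estimate_g()` stops bisecting when the bracket is narrower than
  `rtol` times $g$ and reports the closer endpoint; with the default
  low-temperature evaluation this resolution is far below the Monte-Carlo
  scale of the problem.

## Known limitations

* The quadratic well is an assumption, not a fit; richer potentials would
  need more off-river data than the motivating survey provides.
* $\hat g$ is a point estimate matched to a single aggregated count; no
  uncertainty is attached to it.
* Calibration uses the single data-bearing region, and the fitted coupling
  is applied to all regions when producing the full map.
* The two-temperature schedule is empirical. It is validated against the
  known free-case minimizer and by parameter recovery on synthetic
  geometries, not by a convergence theorem; logarithmic annealing schedules
  with guarantees are impractical at these problem sizes.
* Observation realizations are independent across cells; no within-cell
  point process or detection-error model is implied.
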