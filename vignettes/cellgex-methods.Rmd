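---
title: "cellgex: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellgex: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cellgex simulates time-course transcriptomics data whose ground truth is a
mechanistic model of a growing cell population rather than a purely
statistical recipe.  Two layers are coupled loosely: a cell layer (an
off-lattice, cell-center Monte Carlo model of growth, division and
mechanical interaction) and an expression layer (pathway activities read
off the cell states, mapped to per-gene means and pushed through a
platform-specific error model).  The expression layer only consumes the
recorded trajectory, so either side can be swapped or re-run
independently.

## The cell model

Each cell is a disk in the plane with a continuous center coordinate and a
radius; a mitotic cell is a two-disk dumbbell.  Units: length in resting
cell radii (`r0 = 1` for a size-1 type), time in hours, energy in kT.

**Interaction.** Disk pairs at center distance $d$ with radius sum $s$
contribute

$$E(d) \;=\; \begin{cases}
\varepsilon_{\mathrm{rep}}\,\big((s-d)/s\big)^2 & d < s \\[2pt]
-\varepsilon_{\mathrm{adh}} & s \le d < s + w \\[2pt]
0 & \text{otherwise,}
\end{cases}$$

a quadratic overlap penalty plus a square adhesion well of width $w$.
The population energy is the sum over unordered pairs (dumbbells
contribute both disks).

**Updating.** One sweep performs $N$ trials ($N$ = population size).  Each
trial picks a uniformly random cell and one kind uniformly among the kinds
currently legal for it: *migration* (uniform direction, length uniform on
$[0, \texttt{max\_migration}]$), *growth* (only when the cell's schedule
is due), or, in mitosis, *deformation* (widening the dumbbell).  Trials
are accepted with the Metropolis probability $\min(1, e^{-\Delta E})$,
with $\Delta E$ computed incrementally over affected pairs (a spatial hash
grid makes this O(1) per trial; the recorded trajectory stores both the
incrementally tracked and the recomputed total energy, and the test suite
requires them to agree to $10^{-8}$).

**Cell cycle.** Cycle lengths are drawn at birth from a type-specific
normal distribution truncated below at $\max(2\,t_{\mathrm{mit}}, 1)$
hours.  Interphase growth follows an area-linear schedule that doubles the
resting area over (cycle length − mitosis duration) hours: at wall-clock
age $t$ the target area is $\pi r_0^2 (1 + t/T_{\mathrm{inter}})$, and a
growth trial (when due) proposes a catch-up to the current target.
Because acceptance is energetic, crowded cells fall behind their schedule
— this is the contact-inhibition mechanism, not a bolt-on rule.  Phases
are a deterministic function of the area ratio $a = (r/r_0)^2$: G1 on
$[1, 1.3)$, S on $[1.3, 1.7)$, G2 on $[1.7, 2)$, and M once $a$ reaches 2,
when the disk becomes a dumbbell whose separation is scheduled from 0 to
$2 r_0$ over the mitosis duration.  Division happens unconditionally when
the mitosis deadline passes (overlapping daughters relax by migration);
the daughters are resting-radius disks tangent along the stored axis, each
with a fresh cycle draw.  S-entry, M-entry and division events are logged
with timestamps.

**Seeding.** The initial population is dart-thrown uniformly, without
overlap, into a disk whose area is the total resting cell area divided by
the requested density — so the realized initial area fraction equals the
`density` argument exactly.  Each founder starts at a uniformly random
point of interphase (with the matching radius and a consistent negative
nominal birth time), otherwise the first division wave would be
artificially synchronous.  The optional circular boundary is a hard wall
at the seeding-disk radius: trials pushing any disk outside are rejected.

### Mechanics constants

Two constants were re-derived against their stated purpose — sparse
growth unimpeded, dense growth stalls — after the originally intended
values failed it empirically:

* `epsilon_rep = 2000`.  With a quadratic penalty, one scheduled growth
  increment changes overlap only infinitesimally, so the per-step
  $\Delta E$ at a weak repulsion scale (order 10) is ~0.03 kT even in a
  jammed bounded domain, and Metropolis lets the population climb the
  energy hill indefinitely (a 168 h bounded run reached ~7× the domain
  capacity with mean local density 0.97).  At 2000 the same run stalls
  with local density plateauing near 0.75 and the per-cell division rate
  dropping roughly tenfold between the first and last quarter; behavior
  is insensitive over [2000, 10000].
* `max_migration = 0.5`.  At 0.25 a sparse clonal cluster cannot relax as
  fast as its cells grow, adding a ~0.45 h systematic latency to division
  intervals; at 0.5 the latency vanishes while dense runs still stall.

Other defaults: `mc_steps_per_hour = 10`, `epsilon_adh = 0.1`,
`adhesion_range = 0.3`, `mitosis_duration = 1` h, local-density
neighborhood factor 3.  All are exposed in `model_params()` and the JSON
config.

### Division-interval statistics

Two systematic effects matter when validating realized division intervals
against the configured cycle distribution:

1. *Inspection bias.* In an exponentially growing population observed
   over a finite window, divisions of fast-cycling lineages are
   over-represented; the naive mean is biased low by roughly
   $\sigma^2 \ln 2 / T$ (about −0.9 h for a 12 ± 4 h type).  Restricting
   to a birth cohort early enough that essentially every member divides
   inside the window removes the bias, because cycle lengths are drawn
   i.i.d. at birth.  `division_intervals(..., max_birth =)` implements
   this; the acceptance machinery uses `hours − (mean + 6 sd + mitosis)`.
2. *Scheduler latency.* A cell finishes its area doubling at the first
   accepted growth trial past the schedule end.  Growth-accepted events
   arrive at ~0.5 per sweep (one expected pick per sweep, kind chosen
   between migration and growth), so the expected wait is ~2 sweeps, plus
   half a sweep of division granularity: ~2.5 / `mc_steps_per_hour` h
   (0.25 h at defaults).  The acceptance test adds this derived offset to
   the truncated-normal oracle moments; the acceptance *report* publishes
   the raw measured values.

## Pathways and calibration

A pathway is a gene set plus an activity rule mapping (trajectory, cell,
time) to $P \in [0, 1]$.  Built-ins: S/M phase-transition (binary, 1 when
the cell's latest phase entry lies in a 1 h window before the query time —
"at the current time point" needs a finite window in continuous time),
contact inhibition (the cell's local density: the covered fraction of the
annulus between its radius and 3× its radius, computed on a deterministic
equal-area polar quadrature grid, 16 radial × 64 angular points — accurate
to ~0.01 against a Monte Carlo area oracle), growth rate (accepted growth
area per hour over the last recording interval relative to the type's
unimpeded schedule, clamped to [0, 1]; 0 in mitosis by convention), and
binary cell-type identity.

Calibration fixes each gene's expression range.  From a distribution:
gene means are exponential with mean `lambda` (λ parameterizes the *mean*,
recorded as a dialect choice), range widths are |Normal(0, `stddev`)|, and
`gmin = max(0, m − w/2)`, `gmax = m + w/2`.  From a reference matrix: the
5th/95th percentiles of the gene's row (robust to outliers, rather than
min/max).

## Expression and error models

For pathway $k$ with activity $P_k$, a gene $i$ annotated to $k$ takes the
interpolated value $P_k\,G^{\max}_{ik} + (1-P_k)\,G^{\min}_{ik}$; genes in
several pathways combine their per-pathway values with a configurable
rule, arithmetic mean by default.  In bulk mode the $P_k$ of the $N$
sampled cells are averaged first (one column per sample time); in
single-cell mode each sampled cell keeps its own activities (one column
per cell).  The interpolation is checked against a brute-force oracle to
$10^{-12}$ on randomized instances.

Calibrated means are treated as *linear-scale* abundances for the count
platforms: relative abundance $a_{ij} = g_{ij} / \sum_i g_{ij}$.  (Reading
the same numbers as log2 would put a 2^100-scale dynamic range through the
library-size normalization and degenerate the counts to a single expressed
gene; the calibration defaults only make sense on a linear scale.)

* **Microarray**: i.i.d. Normal(0, `microarray_sd`²) noise added to the
  mean matrix, read as log-style intensities.
* **Bulk RNA-seq**: counts ~ NB(mean `library_size`·a, dispersion φ),
  variance μ + φμ²; a single dispersion rather than a fitted
  mean-variance trend.
* **Single-cell RNA-seq**: per-cell library sizes log-normal (sd on the
  log10 scale), NB counts as above, then independent dropout with the
  logistic probability $\pi = 1/(1 + e^{\texttt{shape}\,(g -
  \texttt{midpoint})})$, decreasing in expression, midpoint defaulting to
  the median calibrated mean.  Batch effects and mean-variance trends are
  deliberately out of scope.

Noise defaults (`microarray_sd = 0.25`, `library_size = 1e6`,
`nb_dispersion = 0.1`, `dropout_shape = 1`, single-cell libraries
10⁴ ± 0.2 log10) are package inventions — the upstream description leaves
them unspecified — and are all exposed in configuration.

## Reproducibility

One user seed drives everything through named sub-streams (model,
calibration, sampling, noise), so e.g. the noise layer can be re-run
without re-simulating cells.  The same (config, seed) pair yields
byte-identical outputs; the CLI test re-runs a full pipeline and compares
files.  Configs are JSON (validated against a schema, unknown keys
rejected; the effective config with defaults resolved is written next to
the outputs).  Trajectories serialize to versioned JSON Lines; bulk
matrices to TSV; single-cell counts to a Matrix Market triplet.

## Packaged scenarios

* `bulk_microarray`: one 24 ± 4 h cell type, 100 founders, bounded domain
  at initial density 0.05, 168 h — long enough for growth to stall — with
  S-entry, M-entry and contact-inhibition pathways of 50 genes each
  (150 genes total) sampled every 4 h into 43 microarray columns.
* `singlecell_twotype`: types A (12 ± 4 h) and B (36 ± 4 h) in equal
  proportion, unbounded, 48 h; binary identity pathways on disjoint
  50-gene sets plus shared transition pathways; single-cell counts with
  NB noise and dropout.
* `growth_confounded`: two identical types plus a growth-rate pathway;
  emitted twice from one trajectory and one sampling — once with three
  disjoint gene sets, once with the growth pathway annotated to the union
  of both identity sets — so the two datasets differ only in annotation
  overlap.  Intended as input for factorization-method benchmarks.

Scenario sizes (gene counts beyond the stated 150 total, initial cell
numbers, densities, noise levels) are desk-scale package defaults, all
overridable.

## What a green test establishes — and what it does not

The generator emulates: mechanically interacting proliferating cells,
density-dependent growth arrest, desynchronized cycles, heterogeneous cell
types, pathway-driven expression with known activities, and
platform-appropriate noise including single-cell dropout.  It does not
emulate: cell death, 3-D geometry, nutrient fields, regulatory-network
dynamics, batch effects, UMI artifacts, gene-length bias, or realistic
pathway overlap structure.  Default simulations separate signals far more
cleanly than real data, so benchmark accuracy on them is an upper bound
for the cell/pathway recovery tasks — methods should additionally be
stressed with overlapping gene sets and noisier settings.

## Numerical notes

* Truncated-normal draws use the inverse-CDF construction (identical in R
  and in the C++ engine, given the shared RNG).
* The local-density quadrature is midpoint-rule on an equal-area polar
  grid; resolution is configurable and the default was chosen to meet the
  0.01 oracle tolerance.
* Degenerate inputs: `cycle_sd = 0` yields the mean exactly; `hours = 0`
  records only the seed snapshot and samples once at t = 0; a population
  smaller than `n_cells` is sampled whole, with a warning; seeding
  densities too high to dart-throw fail with a clear error (the packing
  limit is well below the jamming density, around 0.55).
* Mitotic cells enter the energy sum as two disks; the energy jump at the
  disk-to-dumbbell transition is accounted for in the incremental total.
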