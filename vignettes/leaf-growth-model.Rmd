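---
title: "A cell-based model of symplastic leaf epidermis growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-based model of symplastic leaf epidermis growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symplast)
```

## The model

`symplast` simulates the unidirectional growth of a monocot leaf epidermis
as a quasi-one-dimensional tissue of cell files. Each cell is described by
three lengths (all in μm):

* the **visible length** $l$ — what a microscopist would measure;
* the **relaxed length** $l_r$ — the wall length in the unstressed state;
* the **isosmotic length** $l_i$ — the length at which the cell would be
  isotonic with its surroundings; because the protoplast composition is
  assumed constant, $l_i$ is proportional to dry biomass and serves as the
  model's biomass variable.

From these, both pressures are explicit state functions:

$$P_{osm} = \alpha\,\frac{l_i - l}{l}, \qquad
  P_{turg} = \beta\,\frac{l - l_r}{l_r},$$

with $\alpha$ the osmotic-pressure coefficient (the Van't Hoff factor
$c^{out}RT$ collapsed into one constant, 10 bar by default) and $\beta$ the
turgor coefficient (wall elasticity and geometry collapsed into 100 bar).
Water influx drives visible growth at the specific rate

$$\frac{\dot l}{l} = r\,L_w\,(P_{osm} - P_{turg}),$$

a Lockhart/Ortega-type law in which $rL_w$ (4 μm × 40 per-μm h⁻¹ bar⁻¹ =
160 h⁻¹ bar⁻¹) converts the pressure imbalance into a relative growth
rate. (Two unit readings of $L_w$ circulate — per-μm h⁻¹ bar⁻¹ and
μm h⁻¹ bar⁻¹; the package adopts the one that makes $rL_w$ a specific rate
per bar, which is what the growth law requires.) The wall yields
irreversibly only above the turgor threshold $P_c$:

$$\dot l_r = \begin{cases} 0 & P_{turg} \le P_c\\
  \eta\,\dot l_i\,(P_{turg}-P_c)^3 & P_{turg} > P_c,\end{cases}$$

so $l_r$ is non-decreasing, and wall growth is slaved to biomass growth
with proportionality $\eta$ (0.15). Biomass itself follows an imposed
piecewise-linear schedule: slope $a_1$ from birth until $l_i$ reaches the
critical value $l_i^{max}$, slope $a_2 > a_1$ for the elongation duration
$t^{elong}$, then constant.

Because $rL_w(\alpha+\beta) \approx 1.8\times 10^4\,h^{-1}$, the visible
length relaxes toward the pressure balance within seconds. An isolated
cell therefore grows in quasi-equilibrium: both pressures settle at a
common value $\bar P$ that solves the self-consistency condition
$\eta(\bar P - P_c)^3 = \left[(1+\bar P/\alpha)(1+\bar P/\beta)\right]^{-1}$
(steady ratios of the three lengths), giving $\bar P \approx 3.7$ bar for
the default parameters — the plateau seen in the single-cell experiment.

## Symplastic coupling through fragments

Cell files cannot slide past one another. The leaf axis is partitioned
into transverse **fragments**: the union of all cell boundaries across all
$N$ files cuts the axis into segments $\lambda_k$, each contained in
exactly one cell per file. A fragment grows at its length times the mean
of the free specific growth rates of its $N$ containing cells, and a
cell's visible length is the sum of its member fragments. This is the
entire tissue mechanics: a cell whose autonomous drive exceeds the local
file-average is held back (compressed — its osmotic pressure climbs),
while a slower neighbour is stretched (its turgor climbs until cubic wall
yielding matches the imposed strain). Division inserts a new transverse
wall leaf-wide by splitting the single affected fragment.

## Zonation, division, and the life of a cell

The growth zone is stationary relative to the leaf base (a morphogen
gradient is assumed but not modelled; the division-zone boundary is simply
a fixed position): cells whose midpoint lies within $L_{DZ}$ = 3.3 mm
divide when $l_i \ge l_i^{max}$, splitting all three lengths in the
proportion $d/(1-d)$ with $d$ drawn from a normal distribution (mean 0.5,
sd 0.1) truncated to (0.1, 0.9) by rejection sampling (equivalent to
inverse-CDF truncation). Beyond $L_{DZ}$ a cell keeps growing at $a_1$
(transition zone) until it reaches $l_i^{max}$, then elongates at $a_2$
for $t^{elong}$ = 71.09 h (elongation zone). Elongation ends at
$t^{elong}$ or when the midpoint leaves the $L_{GZ}$ = 23.8 mm growth
zone, whichever comes first; a cell pushed out of the growth zone stops
growing regardless of phase. Zone state is monotone
(DZ → TZ → EZ → mature); a cell's position is its midpoint, which matches
the interval-averaged profiles used throughout.

## The inverse problem and the internal lengths

Experiments measure visible lengths, but the schedule acts on the
*internal* isosmotic length. The package therefore recovers
$a_1, a_2, l_i^0, l_i^{max}$ from three visible landmarks (initial length
14.74 μm, end-of-division length 29.48 μm at 24.7 h, end-of-elongation
length 197.2 μm at 95.79 h): the isotonic newborn state pins
$l_i^0 = l^0$; $a_1$ is root-found so the replayed cell hits the division
landmark, with $l_i^{max} = l_i^0 + a_1 t^{div}$ by the definition of the
schedule's switch point; $a_2$ is then root-found against the elongation
landmark. This yields $a_1^\* \approx 1.035$, $a_2^\* \approx 3.23$ μm/h
and $l_i^{max} \approx 40.3$ μm. Tissue simulations use this
$l_i^0/l_i^{max}$ pair with the reference fitted rates $a_1 = 0.69$,
$a_2 = 5.04$ μm/h.

## Numerical scheme

The stiff visible-length relaxation makes naive explicit stepping at
useful step sizes unstable. Each step (default $dt = 0.01$ h) advances,
in order: biomass lengths (exact, schedule slope), wall lengths (explicit,
from pre-step turgor), then every fragment with a linearized-implicit
(one-Newton-step backward Euler) update

$$\lambda_k \leftarrow \lambda_k\left(1 +
  \frac{dt\,\bar g_k}{1 + dt\,\bar\Gamma_k}\right),$$

where $\bar g_k$ averages the member cells' free rates *evaluated at the
updated $l_i, l_r$* (this is what lets the scheme track the quasi-static
manifold) and $\bar\Gamma_k$ averages their relaxation rates
$rL_w(\alpha l_i/l + \beta l/l_r)$. The update is unconditionally stable,
reduces to explicit Euler when $dt\,\bar\Gamma \ll 1$, makes a homogeneous
tissue reproduce the isolated-cell integrator exactly, and was verified
against a reference stiff solver (`deSolve::lsoda` at rtol $10^{-11}$) on
heterogeneous two-file systems (agreement to four decimals over 20 h).
All rates in a step are computed from a frozen pre-step state (a Jacobi
sweep), so file order cannot bias the result. Visible lengths are
*reconstituted* as member-fragment sums after every step, so the partition
identity holds by construction; halving $dt$ changes final lengths by
under 0.1%. Divisions are processed base-to-tip, file by file; the new
wall splits one fragment leaf-wide, and all sums ($l_i$, $l$, $l_r$,
$\sum\lambda_k$) are conserved to machine precision. A readable pure-R
reference implementation of the same step is kept alongside the compiled
engine and the test suite asserts bit-level agreement of whole runs.

## Initial state, stop rule, and other free choices

The description of the original experiments leaves several quantities
unstated; the package fixes them once, as follows.

* **Newborn/seed mechanical state**: isotonic ($l = l_i$) with the wall
  prestressed exactly to the yield threshold,
  $l_r = l\,\beta/(\beta+P_c)$ — deterministic, and within a short
  recorded transient the cell reaches the quasi-equilibrium regime.
* **Initial tissue**: each file is seeded with
  $\lceil L_{DZ}/\bar l_i \rceil$ cells ($\bar l_i$ the mean of
  $l_i^0$ and $l_i^{max}$), isosmotic lengths drawn uniformly on
  $(l_i^0, l_i^{max})$ so divisions desynchronize, visible lengths
  rescaled per file so every file spans exactly $L_{DZ}$.
* **Stop rule**: leaf length $\ge 1.4\,L_{GZ}$ (the growth zone plus a 40%
  mature margin), configurable; exceeding `max_time` without reaching it
  is an error.
* **Interval scheme**: 0.5 mm intervals to 4 mm, 1.0 mm to 10 mm, 2.0 mm
  beyond — the 0.5/1.0/2.0 pattern with breakpoints chosen once.
* **Cost weights**: $k_i \propto i$ normalized to sum to one
  (scale-free); intervals empty in either profile are dropped and the
  weights renormalized.
* **η-selection objective**: the time-*integral* of
  $|P_{turg}-P_{osm}|$ over one cycle (the pointwise maximum is the other
  natural reading; the integral is smoother).
* **Pressure recording**: at whole hours of each cell's life, into
  150-vectors (osmotic block then turgor block, zero after death), the
  horizon being 75 h; clustering uses Euclidean distance on these vectors
  with seeded restarts, k = 10, clusters relabelled by mean lifespan —
  cluster *identities* are not comparable across runs, only the
  short/medium/long-lifespan structure.

## What the synthetic-data generator does and does not emulate

`generate_synthetic_profile()` stands in for a digitized experimental
cell-length profile: it runs the simulator at chosen $(a_1, a_2)$,
interval-averages the final snapshot, and optionally adds Gaussian noise
to the interval means. It reproduces the *format* and the
simulator-implied profile shape, not real measurement error structure
(digitization bias, per-interval cell counts of a single real leaf,
between-leaf variability). Passing the parameter-recovery tests therefore
shows the fitting machinery is self-consistent — the cost surface
identifies the generating rates when the search grid contains them and
the stochastic division history is shared — not that rates recovered from
a real profile carry 5% accuracy. Because division histories respond
discontinuously to parameter changes, the cost is only piecewise-smooth;
the recovery tests run at reduced file counts with a fixed seed, and
fitting real data should use more files (the cost is a mean over many
cells and smooths accordingly).

## Problem sizes used in the tests

The suite runs the full pipeline at reduced scale: tissue checks use 2–6
files on short leaves; the end-to-end checks use a 20-file leaf with
the full 3.3/23.8 mm zonation (the per-cell statistics and profile shapes
are file-count invariant, and counts scale with file number); the
acceptance script runs the full 100-file configuration. These sizes are
the package's choice of desk-scale experiments.

## Known limitations

* The quasi-1D "brickwork" cannot represent shear between files, wall
  anisotropy, or 2D cell rearrangement; fragment coupling assumes
  absolutely rigid shared walls.
* With the default $rL_w$, pressure imbalances relax in seconds, so
  sustained large differences between $P_{osm}$ and $P_{turg}$ in one
  cell cannot occur; extreme turgor requires a cell whose wall growth is
  frozen while neighbours stretch it, which the zonation timescales make
  rare. Interval-mean pressure profiles consequently show modest
  transition-zone structure (single-cell osmotic pressures do spike well
  above the plateau in compressed elongating cells).
* The morphogen gradient behind the stationary zonation is abstracted to
  a fixed boundary position.
* The η-selection criterion barely discriminates in the quasi-equilibrium
  regime: every admissible η yields near-equal pressures, so the
  integrated deviation is nearly flat in η (see the objective curve
  attached to `estimate_eta()`'s result).

## A worked example

```{r example, eval = FALSE}
inv <- solve_inverse_problem()
inv
sch <- wheat_schedule(inverse = inv)          # a1 = 0.69, a2 = 5.04
sim <- run_simulation(n_files = 20, schedule = sch, seed = 1)
summary(sim)
plot(axial_pressure_profile(sim))
plot(sim_length_profile(sim))
cl <- cluster_pressure_profiles(pressure_profile_matrix(sim), k = 10,
                                seed = 1)
cl
```
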