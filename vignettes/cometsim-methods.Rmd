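---
title: "Modelling motor-driven cargo accumulation at growing microtubule ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor-driven cargo accumulation at growing microtubule ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometsim)
```

## The model

`cometsim` simulates plus-end directed molecular motors (a kinesin such as
Tea2) carrying a multivalent cargo (a CLIP-170 homologue such as Tip1) on a
growing microtubule, to ask under which conditions cargo accumulates
super-linearly at the growing end — the hallmark of non-stoichiometric
"comet" formation by plus-end tracking proteins.

The microtubule is a one-dimensional lattice of sites of length
$a = 8.4\,$nm (one tubulin heterodimer). Site 1 is the minus-end; the lattice
grows by appending empty sites at the plus-end at rate $\gamma$ (sites/s) and
never shrinks. The dynamics is a totally asymmetric simple exclusion process
with Langmuir kinetics (TASEP/LK), extended by cargo and by three scenario
mechanisms:

* **Motors.** Attach at any empty site at rate $\omega_a$, detach at rate
  $\omega_d$, and hop one site towards the plus-end at rate $p$ when the
  target site is empty (exclusion: one motor per site). The attachment rate
  is proportional to motor concentration,
  $\omega_a = \kappa_a \, c_{\mathrm{motor}}$.
* **Open plus-boundary.** A motor on the terminal site steps off the lattice
  at its hop rate (carrying its cargo stack with it). Its *detachment* rate
  remains $\omega_d$ — there is no end-specific retention, so the growing
  end by itself is not a trap. Without this open boundary, exclusion alone
  piles motors up behind the tip in every scenario, which is not the
  behaviour the model is built to dissect (end accumulation should require
  an end-specific mechanism).
* **Cargo.** A bound motor binds one cargo at rate $k_c^{\mathrm{on}}$ and
  loses it at $k_c^{\mathrm{off}}$; additional layers adsorb on the exposed
  top of an existing stack at $k_m^{\mathrm{on}}$ and desorb from the top at
  $k_m^{\mathrm{off}}$ (a LIFO stack; a detaching motor removes its whole
  stack). Multi-layer stacking is what allows more cargo than motors.
* **GTP cap** (`enable_cap`). Freshly added sites are GTP and hydrolyse
  site-autonomously in two exponential steps, GTP $\to$ GDP-Pi $\to$ GDP, at
  rates $k_{h1}, k_{h2}$. Motors hop (and walk off the end) at the reduced
  rate $p_{\mathrm{slow}}$ when the *destination* site is GTP or GDP-Pi.
  Random (non-vectorial) hydrolysis plus steady growth makes the stationary
  GTP fraction at distance $x$ sites behind the tip exactly
  $e^{-k_{h1} x/\gamma}$, which the engine tests verify by fitting.
* **Cargo trains** (`enable_trains`). Maximal runs of adjacent cargo-bearing
  motors move as rigid units: the run advances one site, at the hop rate of
  its leading motor's destination, when the leading plus-neighbour is empty.
  Cargo-free motors always hop individually.
* **Cluster stabilization** (`enable_stabilization`). A cargo-bearing motor
  adjacent to at least one other cargo-bearing motor detaches at
  $\omega_d / s$ — a dwell time enhanced $s$-fold inside cargo clusters.

Simulation is an exact continuous-time Gillespie algorithm. The compiled
engine aggregates events of equal rate into classes (attachment, the two
detachment classes, fast/slow hops, cargo transitions, the two hydrolysis
steps, terminal walk-off, growth), so each event costs O(1) work; a pure-R
stepper over the exported `propensity_catalogue()` serves as the
small-system reference implementation and is cross-checked against both the
compiled engine and brute-force master-equation solutions in the tests.

## Parameters and defaults

| Parameter | Default | Units | Meaning / rationale |
|---|---|---|---|
| `a` | 8.4 | nm | tubulin dimer; 24 sites $\approx$ 200 nm tip region |
| `L0` | 1000 | sites | published system size ($8.4\,\mu$m) |
| `p` | 20 | 1/s | one motor traverses 1,000 sites in $\approx 50$ s ($0.17\,\mu$m/s) |
| `p_slow` | `p`/3 | 1/s | order of the slowdown observed on GTP-analogue lattices |
| `kappa_a` | $1.32\times 10^{-4}$ | 1/(nM·s) | 100 nM $\Rightarrow$ Langmuir occupancy 0.05 (LD phase) |
| `omega_d` | 0.25 | 1/s | 4 s dwell time |
| `gamma` | 3 | sites/s | $\approx 1.5\,\mu$m/min growth |
| `k_h1`, `k_h2` | 0.35 | 1/s | GTP+GDP-Pi zone spans $\sim$100–200 nm behind the tip |
| `k_c_on`, `k_c_off` | 1 | 1/s | half of the motors carry cargo (fast first layer) |
| `k_m_on`, `k_m_off` | 0.5 | 1/s | balanced multi-layer exchange |
| `s` | 3 | – | three-fold dwell-time increase in clusters |

All rates are configurable (YAML/JSON config files mirror the field names).
The defaults put the lattice in the low-density (LD) phase — bulk density set
by Langmuir kinetics, not jamming — which `validate_model_params()` checks
and warns about. With motor turnover, the stationary fraction of motors
carrying a first cargo layer is
$k_c^{\mathrm{on}} / (k_c^{\mathrm{on}} + k_c^{\mathrm{off}} + \omega_d)$
(attachment renews the population cargo-free); the familiar detailed-balance
ratio $k_c^{\mathrm{on}}/(k_c^{\mathrm{on}}+k_c^{\mathrm{off}})$ is its slow
turnover limit. The test suite asserts both forms in their regimes.

## Scenarios and observables

`scenario_flags()` enumerates the five mechanism combinations that are
compared on matched seeds: `cap`, `trains`, `trains_cap`, `stabilized`
(trains + stabilization: stabilization acts on cargo *clusters*, which are
the trains) and `stabilized_cap`. "Independent cargo" means neither trains
nor stabilization.

Snapshots (motor occupancy, cargo stack heights, nucleotide states) are
recorded after equilibration and summarised by `tip_aligned_profile()`,
which aligns the last $W$ sites of every snapshot at the tip. Two windows
summarise a profile: the **tip window**, 24 sites $=\mathrm{round}(200/8.4)$
($\sim 200$ nm), and the **lattice window**, 300–600 sites from the tip —
far from the tip and from the minus-end; the exact extents are a declared
convention. `concentration_sweep()` re-runs the model across motor
concentrations (20–180 nM by default, seeds `base + index`) and
`nonlinearity_index()` divides the tip fold-change by the lattice
fold-change between two concentrations: 1 means the end signal follows the
lattice signal stoichiometrically, $>1$ means super-linear end accumulation.
(As an experimental illustration of the same construction, an end signal
rising fourfold while the motor signal doubles gives an index of 2.)

The model reproduces the expected phenomenology, verified by the acceptance
tests: a cap with slowdown jams motors at the fast-to-slow transition
(profile peak a few to a few tens of sites behind the tip, tip/lattice ratio
$\ge 1.5$); trains or stabilization alone give ratios near 1; stabilization
raises lattice occupancy; and only stabilized clusters combined with the cap
produce a nonlinearity index clearly above 1, with the independent-cargo
index near 1. At the desk-scale schedule the index estimate carries a
sampling error of roughly 0.1–0.15 (its denominator is the small tip
occupancy at 20 nM), which is why `scripts/acceptance.R` samples the sweeps
more densely than the scenario runs.

## Schedules and problem sizes

The published protocol equilibrates for $10^5$ s and records $10^4$
snapshots at the single-motor traversal time (~50 s); that schedule is
available (`run_schedule(1e5, 1e4)`). The package default, used throughout
the tests, is a desk-scale schedule: **2,000 s equilibration, 500 snapshots**
(20 s apart in the scenario comparisons; `run_schedule()`'s default interval
is the traversal time `L0/p`). Snapshots 20 s apart are mildly correlated at
the tip, which the tests absorb by batch-means standard errors. A full
scenario run at these settings executes roughly $10^9$ reactions (the
lattice grows to $\sim 40{,}000$ sites over the sampled interval) in about
half a minute.

Equilibration is the parameter to be most careful with: cargo-clustering
scenarios equilibrate slowest. Block-mean diagnostics over the sampled
interval show no residual drift at 2,000 s for the default rates, but
heavier clustering (large `s`, slow cargo exchange) warrants longer
equilibration.

## Image analysis conventions

The microscopy-side pipeline mirrors the standard workflow for kymograph
comet data and droplet colocalization assays:

* `subtract_background()` is the classical rolling-ball estimate: grey-level
  opening with a ball structuring element (default radius 50 px),
  implemented in compiled code. Intensities are internally rescaled so the
  image's dynamic range spans the ball radius — the behaviour of the
  classical implementation on raw camera counts — making the result
  invariant to normalization and to additive offsets.
* `bin_and_align()` sorts profiles into microtubule-length bins of
  $\pm 0.64\,\mu$m and aligns each bin by integer-pixel shifts (search range
  $\pm 20$ px) minimising the s.d. of the pointwise difference to a
  reference profile drawn with the run's seed. Sub-pixel alignment is
  deliberately not attempted. The s.d. objective discriminates single-pixel
  shifts only where the profile has sharp features (the comet peak); at
  noise levels of ~10% of the *peak* it cannot, and the tests therefore
  quantify recovery at noise of 10% of the lattice plateau.
* Comet "end" and "lattice" regions, defined manually in interactive
  practice, are declared config intervals here (defaults: end = final
  1 $\mu$m before the tip, lattice = 2–6 $\mu$m from the tip), measured from
  the plus-end so profiles of different lengths are comparable.
  `condition_ratio()` divides each high-condition profile's region mean by
  the across-profile low-condition average.
* `detect_condensates()` thresholds (default 0.05) the background-subtracted,
  \[0,1\]-normalized tag channel, labels connected components and reports
  binary centroids, second-moment ellipse axes and mean intensities —
  the regionprops workflow. Border-touching components are kept.
  `client_recruitment()` averages the client channel inside each mask.
* `trace_velocities()` fits one least-squares slope per trace and summarises
  by median and s.d./$\sqrt{N}$. Trace detection and the manual exclusion of
  crossing or merging traces are upstream of this package; traces enter as
  tables.

## Synthetic data: what it does and does not emulate

The generators provide every input the analysis needs, with ground truth
serialized alongside: comet-shaped profiles (shallow seed rise, plateau,
exponential end peak), kymographs rendered from simulation snapshots
(motor channel $\propto$ motor count, cargo channel $\propto$ total stack
height — the cargo-versus-motor two-colour logic), two-channel condensate
images (non-overlapping disks, client = recruitment factor × tag), and
linear traces with a lognormal speed distribution (median 0.23 $\mu$m/s,
spread chosen so that 148 traces give a standard error of the mean of
0.06 $\mu$m/s). Imaging constants default to typical TIRF values
(0.107 $\mu$m pixels, 1 s frames, 0.3 $\mu$m PSF FWHM) and are configurable.

Emulated: Gaussian PSF blur, flat background, Poisson or Gaussian noise,
diffraction-limited disk condensates, positional noise on traces. Not
emulated: EMCCD gain statistics, photobleaching, chromatic offsets between
channels, drift, out-of-focus light, and curved or crossing microtubules.
Passing round-trips on these synthetic data therefore validate the
*procedures* (binning, alignment, segmentation, ratio and velocity
estimators) — they do not certify performance on raw experimental movies,
where registration and trace curation dominate the error budget.

## Numerical choices and degenerate inputs

* Snapshots record the piecewise-constant state at scheduled times (the
  state before the first event at or after each time).
* Event selection uses per-class aggregation; within a class the member is
  chosen uniformly from the selection residual, avoiding a second RNG draw.
  The compiled engine's RNG (xoshiro256++) is seeded from R's RNG, so
  `set.seed()`/`pars$seed` fully determines a trajectory.
* Ties in alignment shifts resolve to the smallest |shift|; the identity
  alignment is therefore a fixed point (idempotency).
* An empty propensity catalogue (all rates zero) is an absorbing state and
  raises an error rather than looping forever; schedules with zero samples
  are refused; a profile window wider than the shortest snapshot names the
  offending snapshot.
* `p = 0` requires an explicit `sample_interval` (the traversal-time default
  is undefined).
* Hop-off-the-end, like hops, uses the slow rate when the cap scenario is on
  and the terminal site is not yet hydrolysed to GDP.

## Known limitations

* The lattice only grows; catastrophe/shrinkage and rescue are out of scope,
  as are diffusive motor states, 2D/3D protofilament geometry and explicit
  simulation of the autonomous end-binding protein (its end-recognition is
  subsumed in the cap's effect on motors).
* The published parameter table is not reproduced; defaults are chosen to
  reproduce the *regime* (LD phase, cap extent, traversal time), not
  particular unpublished values, and every rate is configurable.
* The nonlinearity index at desk-scale sampling is a noisy estimator;
  quantitative comparisons between close scenarios need the published-scale
  schedule or repeated seeds.
* Train hops move a rigid unit at the leading motor's destination rate;
  alternative collective-rate conventions would change cargo flux
  quantitatively but not the scenario ordering tested here.
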