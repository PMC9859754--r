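# cometsim

Stochastic simulation and image analysis of motor-driven cargo accumulation
at growing microtubule plus-ends.

Plus-end tracking proteins form bright "comets" at growing microtubule ends.
When a kinesin motor (e.g. Tea2) delivers a multivalent cargo (e.g. Tip1),
the cargo signal at the end can grow *faster than proportionally* with motor
concentration — more cargo than motors, a non-stoichiometric accumulation.
`cometsim` is for biophysicists who want to dissect which mechanisms can
produce that behaviour, and to test the quantitative image-analysis
procedures used to measure it, entirely on synthetic data with known ground
truth.

## The model

A microtubule is a growing 1D lattice of 8.4 nm sites. Motors obey a totally
asymmetric simple exclusion process with Langmuir kinetics (TASEP/LK) in the
low-density phase: attachment at rate ω_a = κ_a·c (proportional to motor
concentration), detachment at ω_d, hopping towards the plus-end at p under
exclusion, and walk-off at the open plus-boundary. Cargo binds bound motors
(k_c_on/k_c_off) and stacks into multiple layers (k_m_on/k_m_off). Three
switchable mechanisms probe end accumulation:

* **GTP cap** — new sites are GTP and hydrolyse in two exponential steps
  (GTP → GDP-Pi → GDP at k_h1, k_h2); motors hop at a reduced rate p_slow
  into not-yet-hydrolysed sites, so the GTP fraction decays as
  exp(−k_h1·x/γ) behind the tip and a traffic jam forms at the fast→slow
  transition.
* **Cargo trains** — maximal runs of adjacent cargo-bearing motors step
  coherently as rigid units.
* **Cluster stabilization** — cargo-bearing motors adjacent to another
  cargo-bearing motor detach at ω_d/s (dwell time enhanced s-fold).

Simulation is exact (Gillespie direct method, compiled class-aggregated
engine; ~10⁹ reactions per scenario run in about half a minute). Observables
are tip-aligned density profiles, tip (24 sites ≈ 200 nm) versus
mid-lattice (300–600 sites) occupations, motor-concentration sweeps, and a
**nonlinearity index** — the tip fold-change divided by the lattice
fold-change between two concentrations (1 = stoichiometric, >1 =
super-linear end accumulation).

The imaging side re-implements the measurement pipeline: rolling-ball
background subtraction, comet intensity-profile binning (±0.64 µm) /
alignment / averaging, between-condition intensity ratios, condensate
segmentation with client-recruitment quantification, and trace velocity
statistics — plus generators for comet profiles, kymographs, two-channel
condensate images and motile traces, each with serialized ground truth.

## Worked example

The strongest scenario — GTP cap plus stabilized cargo trains — at a 100 nM
motor concentration, desk-scale schedule:

```r
library(cometsim)
pars <- model_params(c_motor = 100, enable_cap = TRUE, enable_trains = TRUE,
                     enable_stabilization = TRUE, seed = 11)
ser <- run_simulation(pars, run_schedule(t_equilibrate = 2000,
                                         n_samples = 500,
                                         sample_interval = 20))
ser
#> snapshot_series: 500 snapshots, t = 2000.0 .. 11980.0 s
#>   lattice 1000 -> 37151 sites; final motors: 2147; events: 2.42e+08

prof <- tip_aligned_profile(ser, 601)
region_occupation(prof, tip_window(pars))      # cargo per site, last 200 nm
#> [1] 0.2568333
region_occupation(prof, lattice_window(pars))  # cargo per site, mid-lattice
#> [1] 0.08551495
```

The tip carries three times the cargo density of the lattice (ratio 3.00) —
whereas the same model with trains or stabilization but *no* cap gives a
ratio near 1, and a concentration sweep
(`concentration_sweep(pars, c(20, 60, 120, 180), ...)` followed by
`nonlinearity_index(sw, 20, 180)`) shows super-linear end accumulation only
for this scenario.

On the analysis side, a synthetic trace experiment at the published sample
size:

```r
tv <- trace_velocities(synth_traces(148, noise_sd = 0.05, seed = 7)$traces)
sprintf("median %.3f um/s, SEM %.3f um/s (N = %d)",
        tv$median_velocity, tv$sem, tv$n)
#> [1] "median 0.301 um/s, SEM 0.057 um/s (N = 148)"
```

which recovers the generator's realized median within a few percent.

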