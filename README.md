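# clumpshare

Reaction–diffusion modelling of cooperative sucrose digestion in
budding yeast, plus the plate-assay statistics that go with such
experiments.

Yeast digests sucrose *outside* the cell: wall-retained invertase
splits each sucrose into glucose + fructose, and the cell then imports
the monosaccharides. Most of the liberated sugar diffuses away, making
it a public good — and making the local cell arrangement matter. This
package simulates a microtiter well as a spherically symmetric volume
and compares the glucose intake of

* an **isolated cell** (alone, or one of *n* uniformly dispersed cells,
  each in a zero-flux subvolume), with
* the **central cell of a clump**, whose *n − 1* neighbours form a
  mean-field shell of packed cellular mass around it.

The model couples Michaelis–Menten hydrolysis (Km = 11 mM, Vmax =
3.6×10⁸ glucose molecules s⁻¹ cell⁻¹ at full induction), saturable
hexose import, glucose-regulated invertase expression (induced by low
glucose, repressed above ~1 mM — a positive feedback loop), and radial
diffusion of both sugars solved with a conservative implicit
finite-volume scheme (one tridiagonal solve per species per time
step). A cell is classified as able to proliferate when its glucose
intake reaches 1.5×10⁶ molecules/s, the measured minimum for slowly
dividing cells.

For the wet-lab side of such experiments the package implements
adjusted Wald (Agresti–Coull) binomial confidence intervals for
well-growth fractions, the competition statistic
ln(producer/non-producer) with one-sample Student-t intervals,
OD→cell-count calibration with the ×6.4 clump correction, and
synthetic-data generators (Bernoulli plate outcomes; exponential
competition growth with a 0.35% producer cost and binomial counting
noise) for testing the whole pipeline without instrument data.

## Worked example

```r
library(clumpshare)
params <- kinetic_params()

clump <- build_geometry("clump", n_cells = 30, params = params)
well  <- build_geometry("dispersed", n_cells = 30, params = params)

r_clump  <- run_simulation(clump, params, sucrose_mM = 8, duration_h = 30)
r_single <- run_simulation(well,  params, sucrose_mM = 8, duration_h = 30)
r_clump
#> Simulation: clump scenario, 30 cell(s), 8 mM sucrose, 30 h
#>   final intake       : 4.757e+06 glucose molecules/s
#>   equilibrium intake : 4.75e+06 glucose molecules/s
#>   wall glucose       : 0.1638 mM
#>   mass balance       : sucrose 2.87e-12, glucose 4.72e-13 (relative)
r_single
#> Simulation: dispersed scenario, 30 cell(s), 8 mM sucrose, 30 h
#>   final intake       : 5.402e+05 glucose molecules/s
#>   equilibrium intake : not converged (still rising)
#>   wall glucose       : 0.01807 mM
#>   mass balance       : sucrose 8.92e-12, glucose 1.64e-12 (relative)

classify_growth(r_clump, params)   # TRUE  — above 1.5e6 molecules/s
classify_growth(r_single, params)  # FALSE — below the threshold
```

The clump's central cell collects ~9× more glucose than an equally
provisioned single cell: its wall glucose (0.16 mM vs 0.018 mM) is fed
by all 30 cells' hydrolysis, and only the clump crosses the
proliferation threshold — clumps can grow at sucrose concentrations
where single cells cannot.

The statistics work on tidy per-well tables:

```r
adjusted_wald_ci(12, 24)
#>   estimate     lower     upper
#> 1      0.5 0.3142743 0.6857257

competition_advantage(gen_competition(competition_scenario(seed = 1)))
#> Competition log-ratio ln(producer/non-producer): -0.0880
#>   95% CI (t, df = 23): [-0.0903, -0.0857]
#>   wells used: 24, excluded (zero count): 0
```

The −0.088 log-ratio is the analytic expectation for a 0.35%
growth-rate cost over 72 h at rate 0.35 h⁻¹ (−cost × rate × time),
recovered from the synthetic counts.

Other entry points: `sweep_clump_size()` (clump-size optimum),
`reproduce_figure()` (standard scenario sets written as CSV bundles
with JSON run manifests), `load_config()` / `write_default_config()`
(flat JSON run configuration). See the vignette
`vignettes/clumpshare-methods.Rmd` for the model, its assumptions and
the parameter choices.

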