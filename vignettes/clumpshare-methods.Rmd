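---
title: "Modelling cooperative sucrose digestion in yeast clumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative sucrose digestion in yeast clumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clumpshare)
```

## The model

Budding yeast digests sucrose externally: invertase, secreted and
retained in the cell wall, hydrolyses each sucrose into one glucose and
one fructose, and the cell then imports the monosaccharides with
saturable hexose transporters. Because hydrolysis happens outside the
membrane, most of the liberated sugar diffuses away — it is a public
good. `clumpshare` asks how much of that public good a cell recaptures
when it sits alone in a microtiter well versus at the center of a
multicellular clump.

The well is modelled as a sphere of liquid (default 150 µl) with the
tracked cell at the origin and spherically symmetric fields $S(r,t)$
(sucrose) and $G(r,t)$ (glucose, standing in for both hexoses) in mM.
Each cell carries an induction level $e \in [0,1]$, the fraction of its
maximal invertase capacity. The local kinetics are:

* **Hydrolysis** (per cell): $v_h = e\,V_h\,S/(K_h + S)$ with the
  enzyme-assay values $K_h = 11$ mM and $V_h = 3.6\times10^8$ glucose
  molecules s$^{-1}$ cell$^{-1}$ at full induction. One glucose (and one
  untracked fructose) is released per sucrose.
* **Import** (per cell): $v_i = V_i\,G/(K_i + G)$. Glucose and fructose
  are taken up identically, so only glucose is tracked; total
  monosaccharide intake is twice the reported glucose intake.
* **Regulation**: the invertase promoter has basal activity $a_0 = 0.1$
  at zero glucose, is induced by low glucose, peaks (activity 1) inside
  the window 0.25–1 mM, and is repressed above it. Induction relaxes
  toward the promoter activity with time constant $\tau = 3600$ s:
  $\dot e = (a(G) - e)/\tau$. The relaxation is symmetric by default,
  so repression can lower enzyme capacity on the $\tau$ timescale; a
  ratcheting variant (`decay = FALSE`) never lowers it. In
  `constitutive` mode $a \equiv 1$, the control used to show that the
  clump advantage does not require this feedback loop.

Both fields obey radial diffusion, $\partial_t C = D r^{-2}\partial_r
(r^2 \partial_r C)$, with zero flux at the cell surface and the outer
wall, $D_{suc} = 520$ and $D_{glc} = 600$ µm² s$^{-1}$ (small sugars in
water at 30 °C).

Three geometries (`build_geometry()`):

* **isolated** — one cell in the full well;
* **dispersed** — each of $n$ uniformly spread cells is simulated in a
  zero-flux Wigner–Seitz subvolume $V/n$;
* **clump** — the tracked cell is wrapped in a mean-field shell of
  packed cellular mass holding the other $n-1$ cells at volume fraction
  $\phi = 0.64$ (random close packing of 2.5 µm cells). Shell cells act
  as volumetric sources/sinks at the local concentrations; the shell is
  treated as reactive liquid for transport (sugars move through the
  porous wall/periplasm space essentially unhindered on these scales;
  applying a porosity factor to shell transport makes it impossible to
  reconcile the isolated and clump intake scales, see "Choices and
  calibration").

## Numerics

The solver is a conservative finite-volume discretisation on a
log-spaced radial grid (default 300 nodes from the cell surface at
2.5 µm to the outer wall), stepped implicitly. Each step (default
$dt = 1$ s) follows the loop: measure the wall concentrations, update
induction, hydrolyse, import, diffuse. The reaction sinks are
linearised at the measured concentrations and folded into the implicit
diffusion solve — one tridiagonal system per species per step — so the
update is unconditionally stable, keeps fields nonnegative without
clamping, and makes the molecule bookkeeping exact: every run closes
its sucrose and glucose balances to ~$10^{-12}$ relative (asserted at
$10^{-6}$ in the tests).

Two details deserve emphasis:

* **Time weighting.** The standalone `diffusion_step()` defaults to
  Crank–Nicolson ($\theta = 1/2$), which is second-order and exactly
  conservative. The coupled driver defaults to backward Euler
  ($\theta = 1$): the innermost grid cell relaxes on ~10 µs timescales,
  and any splitting of the strong surface reactions from a
  Crank–Nicolson diffusion step rings at such nodes (amplification
  factor → −1). Because the reaction–diffusion steady state of the
  discrete equations does not depend on $dt$, the equilibrium intakes
  reported are unaffected by the first-order time accuracy; halving
  $dt$ and doubling the grid changes them by well under 1%.
* **Equilibrium detection.** A run is declared converged when the
  recorded intake changes by less than 1% (relative) across the final
  10% of the run; the equilibrium intake is the mean over that window.
  Clump runs converge within hours; isolated-cell runs keep rising
  slowly (the well keeps accumulating glucose) and report their
  final-time intake instead.

## Choices and calibration

Default parameters are in `kinetic_params()`. The measured quantities
(hydrolysis $K_h$, $V_h$; the promoter window; the ~1–2×10⁶
molecules s$^{-1}$ minimum intake for proliferation, default threshold
1.5×10⁶) are fixed. The remaining defaults are model choices:

* **Hexose transport** $K_i = 5$ mM, $V_i = 1.5\times10^8$
  molecules s$^{-1}$ cell$^{-1}$ — a low-affinity, high-capacity
  transporter with low-glucose slope $V_i/K_i = 3\times10^7$
  molecules s$^{-1}$ mM$^{-1}$, so a cell at tens of µM glucose takes
  up ~1–2×10⁶ molecules s$^{-1}$, matching chemostat measurements of
  slowly growing cells. The slope is tightly constrained: the
  simulated wall glucose of an isolated cell in 8 mM sucrose after
  30 h is ~0.019 mM while the clump center sits at ~0.17 mM, and the
  corresponding intakes must differ by roughly the same factor —
  forcing near-linearity of the import law over that range. Keeping
  $K_i$ in the mM range (rather than a high-affinity fit with the same
  slope) leaves the transporter unsaturated at interior-clump glucose
  levels, which is what lets large clumps consume glucose in transit.
* **Promoter shape**: $a(G) = a_0 + (1-a_0)\,f(G)/f^\*$ with
  $f = \frac{G}{G + K_{ind}}\cdot\frac{K_{rep}^4}{K_{rep}^4 + G^4}$,
  $K_{ind} = 0.5$ µM and $K_{rep} = 2$ mM. Induction saturates at
  micromolar glucose (so cells in the faint glucose cloud of an
  isolated producer stay induced) and repression is sharp above ~1 mM.
  The curve's maximum falls at ~0.29 mM, inside the required window.
* **Initial induction** $e(0) = 1$: assay cells are pregrown in 1 mM
  glucose precisely to enter the well fully induced.
* **Clump bookkeeping**: "a clump of $n$ cells" is one resolved
  central cell plus $n-1$ shell cells; a clump of one is exactly the
  isolated scenario.

## What the simulations show

With defaults, the central clump cell in 8 mM sucrose equilibrates at
~4.7×10⁶ glucose molecules s$^{-1}$ — above the proliferation
threshold — while a dispersed single cell reaches only ~5×10⁵ after
30 h, below it; the ratio is ~9. At 2 and 32 mM the pairs are
~1.7×10⁶ / 1.9×10⁵ and ~8.3×10⁶ / 9.6×10⁵. The ordering holds in
constitutive mode as well: recapture of neighbours' monosaccharides
alone, without the expression feedback, already favours clumps.

The clump-size sweep (8 mM, 8 h) rises steeply up to thousands of
cells and has an interior maximum: the default sweep
(`default_sweep_sizes()`, up to 3×10⁴ cells) peaks at a clump radius of
~60–90 µm (~1–3×10⁴ cells), beyond which the central cell starves.
The position of this optimum is set by two lengths: the sucrose
penetration depth of packed cell mass,
$\ell_S = \sqrt{D_{suc} K_h/(n_c V_h)} \approx 31$ µm (fixed by the
measured hydrolysis kinetics and the packing density $n_c$), and the
glucose screening length $\ell_G = \sqrt{D_{glc}(K_i+G)/(n_c V_i)}
\approx 40$ µm (fixed by the import slope). The optimum radius scales
with their combination, so it cannot be moved inward by an order of
magnitude without a several-fold steeper import law — which the
isolated/clump intake calibration above excludes. This tension is a
real property of the model family, not a numerical artifact; we report
the sweep as computed.

## The plate-assay statistics

`adjusted_wald_ci()` implements the Agresti–Coull interval
$\tilde p = (x + z^2/2)/(n + z^2)$, half-width
$z\sqrt{\tilde p(1-\tilde p)/(n+z^2)}$, clipped to [0, 1], with $z$
the exact normal quantile (1.959964… at 95%). It is the appropriate
interval for the small well counts of plate assays (24 wells per
condition); exact enumeration puts its coverage above 0.92 for
$n = 24$ across $p$ = 0.1–0.9. `growth_fraction_summary()` pools
replicate plates within a condition before forming the interval.

`competition_advantage()` summarises two-genotype competitions by the
per-well statistic $\ln(N_{producer}/N_{nonproducer})$, which equals
the growth-rate difference times elapsed time for equal inocula, with
a one-sample Student-t interval across wells. Wells where either
genotype was not observed have an undefined log-ratio; they are
excluded and reported (the exclusion rule is ours — with 10⁵-cell
counting depths zeros essentially never occur in practice).
`od_to_cells()` converts OD595 readings by monotone piecewise-linear
interpolation of a measured standard curve, times 6.4 (the mean cells
per particle) for clumpy cultures counted as particles.

## Synthetic data

`gen_plate()` draws independent Bernoulli growth outcomes per well at
condition-specific probabilities (24 wells per condition by default);
`growth_probability()` links simulated intake to those probabilities
with a logistic in log-intake centered on the growth threshold, steep
enough to be near-deterministic away from the threshold while allowing
the partial growth fractions seen at marginal sugar concentrations.
`gen_competition()` grows producer and non-producer populations
exponentially from equal inocula (60 + 60 cells, 72 h), the producer
paying a relative rate cost (default 0.35%, the measured cost of
forced invertase expression), then subsamples each well binomially at
the counting depth (default 10⁵ cells; counting the whole well is a
noise-free census). Both generators are deterministic under their
scenario seed.

These generators reproduce the statistical structure the estimators
assume — independent wells, binomial counting noise, known effect
sizes — and nothing else: no spatial interaction between wells, no
plate effects, no instrument gating artifacts. Tests built on them
therefore validate the estimators and the pipeline plumbing, not the
biology of real plates.

## Problem sizes used in the checks

The test-suite and acceptance runs use the study's own scales: 150 µl
wells, 30 cells, 2–32 mM sucrose, 30 h simulations on 300-node grids
with $dt = 1$ s; the clump-size sweep covers 17 log-spaced sizes from
1 to 10⁴ cells at 8 h; statistical calibrations use 24-well plates and
300–500 replicate generations.

## Limitations

* The mean-field shell has no cell-scale granularity; sub-clump-scale
  heterogeneity and clump geometry effects are out of reach.
* No growth, division or clump fragmentation during a run: the model
  predicts whether proliferation can start, not its dynamics.
* Fructose is folded into the glucose field by the symmetric-uptake
  assumption; transporter competition between the two hexoses is not
  modelled.
* The optimum clump size is sensitive to the import law in packed
  cell mass, which is the least-constrained part of the
  parameterisation (see "Choices and calibration").
* Convection is absent; shaken-culture conditions can only be
  addressed by the assay statistics, not the simulation.
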