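---
title: "Thermodynamically consistent kinetics of serine-integrase recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically consistent kinetics of serine-integrase recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrec)
```

## The system and the modelling question

Serine integrases such as the ϕC31 enzyme recombine a phage attachment site
(*attP*) with a bacterial one (*attB*), producing the hybrid sites *attL*
and *attR*. The striking property of these enzymes is directionality: with
integrase alone, attP × attB recombination is efficient while the reverse
attL × attR reaction is undetectable, yet adding the recombination
directionality factor (RDF) reverses the preference. No external free-energy
source (e.g. ATP) is consumed, and for linear DNA the substrate and product
molecules are essentially isoenergetic, so the directionality cannot come
from the DNA itself. It must come from the protein–DNA complexes that form
along the way — and, because every elementary step is reversible, any
explanation must respect the conservation of energy around the reaction
cycle.

`intrec` implements mass-action kinetic models of this system as reversible
reaction networks, with that thermodynamic constraint built in rather than
checked after the fact.

## Reaction scheme

Two pathways connect the substrate and product plasmids (pPB carries
attP + attB in inverted repeat; pLR carries attL + attR):

* **−RDF pathway** (attP × attB): integrase dimers (`int2`, formed in
  solution with dissociation constant `K_ii`) bind the two att sites
  sequentially (`b1`, per-site association constant, statistical factor 2
  for the first site), the two bound dimers pair into a synapse (`s1`),
  strand exchange occurs as a single condensed reversible step (`r1`), the
  product synapse relaxes into a kinetically stable conformation (`mod`),
  and the stable synapse dissociates (`s2`, desynapsis) to the
  integrase-bound product, which can release its dimers (`b2`).
* **+RDF pathway** (attL × attR): integrase dimers load two RDF monomers in
  solution (`K_ir` per site) to form `int2rdf2`, which drives the mirror
  pathway `b3 → s3 → r2 → modr → s4 → b4`.

Two further features are required by the titration phenomenology:

* **Unproductive RDF complexes.** The half-loaded `int2rdf1` also binds att
  sites, and only plasmids whose two sites both carry `int2rdf2` (four RDF
  monomers in the eventual synapse) can proceed through `s3`/`r2`; likewise
  only plasmids with two bare `int2` dimers proceed through `s1`/`r1`.
  Mixed occupancy is a dead end. This reproduces the sharp dependence of the
  +RDF reaction on the RDF:integrase ratio, saturating at 1:1.
* **Tetramer self-inhibition.** At high integrase a second dimer can join an
  occupied attP/attB site (association constant `K_inh`), making the site
  synapsis-incompetent and causing the observed mild decline of the 3-h
  yield at high integrase. It is restricted to attP/attB sites by default
  (toggleable via `tetramer_inhibition`).

Model variants: `MODEL0_PLASMID` omits the `mod`/`modr` steps and their
stable synapses — it is retained because its failure is informative (see
below). `MODEL1_PLASMID` is the full scheme. `MODEL1_LINEAR` adapts Model 1
to intermolecular recombination of short linear attP/attB fragments:
binding is per fragment, synapsis is bimolecular (`K_s1` in 1/nM), and the
strand-exchange/modification rate constants are lower, reflecting the loss
of the supercoiled plasmid's intramolecular advantage. Only the −RDF
pathway is modelled for linear substrates. Antiparallel (exchange-
incompetent) synapse alignments are not distinct species; their effect is
absorbed into the effective rate of `r1`.

## Energy conservation as a construction rule

Both pathways start and end on free DNA of equal free energy while binding
and releasing the same protein complexes, so the product of equilibrium
constants along each pathway must equal 1 (Wegscheider's condition):

* −RDF: `K_b1² · K_s1 · K_r1 · K_mod · K_s2 / K_b2² = 1`
* +RDF: `K_b3² · K_s3 · K_r2 · K_modr · K_s4 / K_b4² = 1`

`wegscheider_residuals()` reports the absolute log-space deviation of each
product; `close_parameters()` makes both vanish exactly by solving for one
derived constant per pathway. Conventions that matter:

* **`K_s2` and `K_s4` are desynapsis constants** (stable product synapse →
  desynapsed complex), the direction their pathway traverses them. With
  this convention closure gives `K_s2 ∝ 1/K_r1`: doubling `K_r1` *halves*
  the derived `K_s2`. Flipping this convention silently breaks closure, so
  it is asserted in tests.
* **The derived constants default to `K_s2`/`K_s4`** because they belong to
  the least directly observable steps and because perturbation analyses
  compensate through them, making `compensated_perturbation()` (e.g.
  "double `K_r1`, re-close through `K_s2`") a one-liner.
* **Statistical factors (×2/×1) cancel** around each pathway and are
  excluded from the closure bookkeeping; the network builder applies them
  to rate constants, not to the per-site equilibrium constants.

`energy_landscape()` expresses the same constraint as a per-step ΔG =
RT·ln(Γ/K) profile at reference concentrations (10 nM DNA-containing
species, 200 nM unbound protein complexes — both `int2` and `int2rdf2`;
temperature defaults to 303.15 K, the 30 °C incubation temperature, and is
configurable since ΔG scales linearly in T). A closed set always has zero
cumulative ΔG over each pathway.

## Why Model 1: kinetic trapping

With energy conservation enforced, a model cannot slow the "forbidden"
attL × attR (−RDF) reaction by simply detuning one rate constant: lowering
a reverse rate forces the forward rate down with it (the equilibrium
constant is fixed by closure), slowing both directions. Model 0 therefore
equilibrates from both substrate directions within 3 h — reproduced by
`default_parameters("MODEL0_PLASMID")` in the test suite — which
contradicts the observed asymmetry; matching the product-favouring
equilibrium in Model 0 additionally forces integrase to bind attL/attR far
more tightly than attP/attB, against measured affinities.

Model 1 resolves this with the stable product synapses `LR_int_s2` and
`PB_intrdf_s2`: the unfavourable dissociation of product complexes is split
over two moderately unfavourable steps (`s2` then `b2`), so attL/attR
binding need only be about twice as strong as attP/attB (`K_b2 = 2·K_b1`
here), and the interconversion `s2`/`s4` is made very slow in *both*
directions, which closure permits. Starting from pLR without RDF, the DNA
is quickly sequestered into the synapsis-blocked `LR_int` complex and
creeps toward equilibrium over days, while the same parameters let the
pPB-start reaction finish in tens of minutes. Directionality is kinetic
trapping, not thermodynamic bias.

## Parameters and calibration

Concentrations are in nM (all protein concentrations as monomer), time in
seconds; bimolecular constants in 1/(nM·s), per-site association constants
`K_b*` in 1/nM, solution dissociation constants `K_ii`, `K_ir` in nM.

The reference values shipped by `default_parameters()` were calibrated by
this package against the reported outcomes of the defining in vitro
experiments (10 nM supercoiled plasmid, 400 nM integrase, 800 nM RDF for
the +RDF arm, 30 °C): the 30-min and equilibrium extents of both permitted
reactions, the 1-h extents of both suppressed reactions, the equilibrium
yields after compensated two-fold perturbations of `K_r1`/`K_r2`, and the
3-h extent of the linear-fragment reaction. The calibration proceeded from
a closed-form design of the equilibrium composition (the detailed-balanced
equilibrium is a partition function over species weights) followed by
one-dimensional numerical solves on the full network, in this order:

1. `K_r1` → −RDF equilibrium yield; `K_r2` → +RDF equilibrium yield;
2. `kf_r1 = kf_mod` → 30-min −RDF kinetics; `kf_r2 = kf_modr` → 30-min
   +RDF kinetics;
3. `kf_s4` → 1-h suppressed +RDF extent; `kf_s2` sets the (much slower)
   suppressed −RDF extent;
4. linear variant: `K_s1` and `kf_r1 = kf_mod` → 3-h extent.

Binding affinities (`K_b1 = 0.1 /nM`, i.e. a 10 nM per-site dissociation
constant, with `K_b2 = 2·K_b1`) and association rates (0.01 1/(nM·s) =
1e7 1/(M·s)) were fixed at typical protein–DNA values and not tuned; `K_ii`
= 10 nM and `K_ir` = 5 nM keep solution assembly saturated at the working
concentrations, as the titration data require. This reconstruction has 28
free constants (13 equilibrium constants of which `K_s2`/`K_s4` are
closure-derived, and 15 forward rates); the robustness scan perturbs all of
them.

## Simulation and numerics

* **Integrator.** The networks are stiff (second-scale binding against
  day-scale desynapsis), so `simulate_network()` uses `deSolve` with an
  analytic Jacobian; `lsoda` for time courses and BDF for the long-horizon
  equilibrium runs. Defaults rtol = 1e-8, atol = 1e-12 nM; the headline
  readouts move by well under 0.1 percentage point when tightened tenfold.
  The right-hand side is evaluated without concentration clipping — mass
  action is smooth through zero and clipping destroys the Jacobian
  consistency the stiff solver depends on; trajectories are floored at 0
  afterwards, with a hard error below −1e-9 nM.
* **Requested times are exact.** "30 min" readouts are dense-output
  interpolation points, not nearest samples.
* **Equilibrium.** `equilibrium_composition()` integrates to 1e8 s (beyond
  the slowest relaxation) and then polishes `rhs = 0` by Gauss–Newton in
  log-concentration space with the conservation laws appended as equations
  (rows equilibrated, since flux magnitudes span ~15 orders). The polished
  state is verified to max |d[x]/dt| < 1e-10 nM/s and, these networks being
  detailed-balanced, to near-zero net flux through every individual step
  (~1e-14 nM/s in practice). Zero-total conservation laws (the attL/attR
  pairing balance of the linear variant) are kept in the system — dropping
  them leaves a rank-deficient Newton step.
* **Solution protein assembly is evolved kinetically,** not
  pre-equilibrated: at the working concentrations dimerization and RDF
  loading relax within seconds, so the distinction is immaterial to the
  readouts, and a kinetic start keeps the initial condition elementary
  (all protein monomeric, all DNA bare).
* **Fitting.** `fit_parameters()` works on log-parameters with
  Levenberg–Marquardt, re-deriving `K_s2`/`K_s4` at every evaluation so no
  candidate violates closure. The finite-difference step is set to ~1e-3 on
  the log scale (`epsfcn`), safely above the ODE solver noise floor —
  with the library default the Jacobian is dominated by integration noise
  and the optimizer stalls at the starting point. Association rates are
  bounded to 1e-6–1 1/(nM·s) (1e3–1e9 1/(M·s)).
* **Robustness.** `robustness_scan()` perturbs each free constant two-fold
  in both directions. By default each perturbed set is re-closed through
  `K_s2`/`K_s4`, keeping the thermodynamics valid; `reclose = FALSE` applies
  the raw perturbation in diagnostic mode. The re-closure mode is the one
  that keeps every maximal-yield change below 33% in the shipped
  configuration (25% at worst, led by `K_r2`); "maximal yield" is the
  maximum of the product fraction over a 3-h time course of each permitted
  reaction.

## The synthetic-data generator

`default_design()` reproduces the shape of the calibration dataset: two
triplicate time-course arms (16 points each, 2–180 min) for the permitted
reactions plus 3-h endpoint titrations — a 12-point two-fold integrase
dilution series from 800 nM for pPB, and the same series crossed with
RDF:integrase ratios 0.25–2 for pLR — 92 cells in total at 10 nM plasmid.
The exact split between time-course and endpoint cells, and the grid
values, are documented package defaults (the original axes are not printed
as numbers); the total of 92 and the triplicate structure are as reported.
`generate_dataset()` adds Gaussian replicate noise on the fraction scale
(sd 0.03 by default, an assumption motivated by the small triplicate error
bars of such gel-quantitation data), truncated to [0, 1], and is
byte-reproducible from its seed.

What passing parameter-recovery tests on these data do **not** show: the
generator has no gel-quantitation artefacts (band-size correction,
background subtraction), no pipetting covariance between replicates, no
substrate-batch effects, and its noise is homoscedastic. Recovery results
therefore demonstrate the identifiability and correctness of the machinery,
not that 92 real gel measurements determine all 28 constants — profile
directions such as jointly rescaling `K_mod` and the derived `K_s2` are
nearly flat and are only pinned by the thermodynamic constraint and the
fixed-affinity choices above.

## Problem sizes used by the tests

The test suite runs complete but deliberately small instances: fitting
tests free two constants against a 10-cell noise-free design; the
chi-square check of the objective pools 60 replicated blocks of an 8-point
arm through a single simulation; the full 92-cell dataset is generated once.
The full 28-parameter robustness scan (112 perturbed simulations) runs in
the acceptance checks. These sizes are the package's choices for a
convenient default test run; all operations scale to the full design.

## Known limitations

* DNA topology is ignored: no supercoiling energetics, knotting, or
  topology-dependent binding. The directionality phenomenon does not
  require them, but absolute rates for supercoiled substrates absorb these
  effects into effective constants.
* Integrase inactivation is not modelled; the underlying experiments
  showed substrate DNA protects integrase activity over the reaction
  timescale.
* The stable product "synapse" `LR_int_s2` is one of two structures the
  data cannot distinguish (a true synapse vs. a slow-converting non-synapsed
  conformation); the model encodes the synapse reading.
* No stochastic (SSA) simulation and no Bayesian uncertainty
  quantification; fits are local least squares with multi-start.
* The linear variant covers the −RDF reaction only.
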