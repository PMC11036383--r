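---
title: "Mechanistic model of integrated filtration and cake washing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic model of integrated filtration and cake washing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cakewash)
```

# The isolation problem

After crystallization, an active pharmaceutical ingredient (API) arrives as a
suspension of crystals in an impure mother liquor. Isolation removes that
liquor in two coupled steps: dead-end **filtration** builds a cake on the
filter medium and stops at *dryland* (the point at which no free liquid
remains above the cake, leaving the pores saturated with mother liquor), and
**washing** pushes wash solvent through the cake to displace or dilute the
dissolved API and impurities still held in the pores. The purity of the dried
product and the amount of solvent consumed are both set by how these two
steps are operated, so a mechanistic model of the pair — not of either step
alone — is what process designers need.

`cakewash` implements that pair: a constant-pressure Darcy/Carman–Kozeny
filtration model integrated to dryland, three washing mechanisms, parameter
estimation from filtrate volume–time data, and design-space tools. Two
bench-scale case studies (mefenamic acid, "MFA", and paracetamol, "PCM",
each with several crystallization/wash solvent pairs and dissolved
impurities) ship as ready-made scenarios.

# Filtration model

Constant-pressure dead-end filtration obeys Darcy's law with resistances in
series:

$$\frac{dV}{dt} = \frac{\Delta P\, A^2}{\mu\,(\alpha\, w\, V + R_m A)}$$

with $V$ the cumulative filtrate volume (m³), $\Delta P$ the driving
pressure (Pa), $A$ the filter area (m²), $\mu$ the filtrate viscosity
(Pa·s), $R_m$ the medium resistance (1/m), $w$ the dry solids deposited per
unit filtrate volume (kg/m³), and $\alpha$ the specific cake resistance
(m/kg) from Carman–Kozeny theory:

$$\alpha = \frac{180\,(1-\varepsilon)}{\rho_s\, \psi^2\, x^2\, \varepsilon^3}$$

where $\varepsilon$ is cake porosity, $\psi$ particle sphericity, $x$ the
mean particle size and $\rho_s$ the crystal density. Compressible cakes
follow the power law $\alpha(\Delta P) = \alpha_{ref}\,(\Delta P / \Delta
P_{ref})^n$ with compressibility index $n$ ($n<1$ low/moderately
compressible, $n>1$ highly compressible). The Carman–Kozeny value is
interpreted as $\alpha_{ref}$ at the reference pressure, 1 bar by default
(the reference pressure is a modelling convention, not a measurable, and is
configurable per scenario).

Because all solids are assumed to deposit (no fines passage, no dissolution),
the dryland end point is known in closed form: $V_{end} = V_{liq,0} -
\varepsilon/(1-\varepsilon)\, V_{solid}$, and $w = m_{solid}/V_{end}$ is
solved self-consistently with it. `simulate_filtration()` integrates the ODE
with `deSolve::lsoda` and stops by event detection on the free liquid height
(absolute tolerance $10^{-6}$ m); the terminal sample is then extended to the
exact dryland point using the analytic solution of the same ODE,

$$t(V) = \frac{\mu}{A\,\Delta P}\left(\frac{\alpha w V^2}{2A} + R_m V\right),$$

so that mass balances close to machine precision rather than to the event
tolerance. The same analytic solution backs the fast predictions inside the
estimation objective; the test suite checks integrator and closed form
against each other to 0.1%.

`darcy_fit()` implements the classical linearization: regressing $t/V$ on
$V$ gives $\alpha$ from the slope and $R_m$ from the intercept. Negative
fitted intercepts — which occur on the bench when the suspension pre-settles
before the pressure is applied — are reported verbatim with a warning flag;
the forward simulator refuses negative $R_m$.

# Washing mechanisms

Washing starts from the saturated dryland cake. Three mechanisms are
provided, selectable per stage:

* **Piston displacement** (`displacement`): ideal plug flow. The first
  $\min(W, 1)$ pore volumes of filtrate carry pure mother liquor, any excess
  carries wash liquid; the residual mother-liquor fraction is
  $\max(0, 1-W)$. $W$ is the *wash ratio*: wash volume per cake void volume.
* **Axial-dispersion washout** (`dispersion`): the one-dimensional
  convection–dispersion solution for a uniformly saturated cake,

  $$\frac{c}{c_0} = \tfrac12\,\mathrm{erfc}\!\Big[(W-1)\sqrt{\tfrac{Pe}{4W}}\Big]
    - \tfrac12\,e^{Pe}\,\mathrm{erfc}\!\Big[(W+1)\sqrt{\tfrac{Pe}{4W}}\Big]$$

  with $Pe$ the Peclet number (convective over dispersive transport). This
  form conserves mass exactly ($\int_0^\infty c/c_0\, dW = 1$), stays within
  $[0,1]$, and converges to the displacement step as $Pe \to \infty$. The
  $e^{Pe}$ term is evaluated in log space (via the Gaussian log tail), so
  $Pe = 10^6$ is handled without overflow. Washing curves generated by this
  mechanism show the three classical regimes — constant-rate, intermediate,
  and diffusion — which `segment_wash_curve()` labels at configurable
  thresholds (0.95/0.05 of the initial exit concentration by default).
* **Well-mixed semibatch dilution** (`well_mixed`): an MSMPR-style surrogate
  for strong back-mixing. In `accumulate` mode the aliquot joins the pore
  liquor with *no outflow*: concentrations dilute as $c = c_0 V_0/(V_0 +
  V_{wash})$ and the retained liquid grows beyond the pore volume — this is
  the semibatch hold-up behavior that over-predicts retained liquid after a
  wash, and it is the mode that mimics the original case-study simulations.
  In `feed_and_bleed` mode the hold-up is constant and the washout is the
  CSTR solution $c = c_f + (c_0 - c_f)e^{-W}$.

In a multi-stage program, any excess hold-up left by an accumulate stage is
deliquored back to the pore volume (withdrawn as filtrate at the mixed
composition) before the next aliquot is charged — on the bench each wash is
filtered off before the next is poured. This makes successive accumulate
stages follow the dilution product $\prod_i V_0/(V_0+V_i)$, so splitting a
fixed solvent total into more aliquots strictly improves purity under
accumulate, whereas feed-and-bleed washing depends only on the total wash
ratio and is exactly split-invariant. That split-invariance is the mechanism
behind the observation that one large aliquot and several small ones give
the same final purity in an instant-mixing model; models that resolve
partial back-mixing would break it.

All stage bookkeeping is done in species masses, so species and total mass
balances close to machine precision for every mechanism (asserted at 1e-8
relative in the tests, across all 18 fixture scenarios).

## Choice of Peclet number

The case studies report no measured dispersion, so `peclet` is a per-stage
scenario parameter with default **10** — mid-range dispersion that produces
a washing curve with all three regimes clearly present. Users with
breakthrough data should fit it; predictions in the intermediate regime are
sensitive to it, while the $W \lesssim 0.5$ and $W \gg 1$ limits are not.

# Parameter estimation

`estimate_parameters()` fits any subset of (sphericity $\psi$, porosity
$\varepsilon$, medium resistance $R_m$, compressibility index $n$) to
filtrate volume–time observations by bounded local search (`nlminb`, $R_m$
on a log10 scale, optional multi-start) on the normalized least-squares
objective $\sum_{exp}\sum_t ((V_{sim}-V_{obs})/\max|V_{obs}|)^2$.

Two identifiability facts shape the implementation:

* Runs stop at dryland, so the largest observed volume is itself an
  observation of the dryland end point and enters the objective as a
  terminal residual. Without it, porosity is only one-sidedly identified:
  any porosity whose predicted plateau exceeds the observed one fits the
  pre-dryland curve exactly.
* $n$ rescales $\alpha$ identically at a single driving force, so
  single-pressure designs cannot identify it. The estimator detects this,
  pins $n = 0$, and raises a `compressibility_unidentifiable` flag — the
  same behavior as the zero-compressibility rows in the case-study tables.
  A two-pressure design restores identifiability; the tests recover all four
  parameters to within 1% from noise-free two-pressure data.

# Physical properties and fixtures

The case-study sources specify compositions, masses, geometry and the
calibrated cake parameters, but no solvent or solid physical properties.
The package therefore ships a literature defaults table
(`species_table()`, 25 °C values): e.g. MFA crystal density 1300 kg/m³, PCM
1293 kg/m³, solvent densities and viscosities from standard handbooks.
Dissolved solutes are assigned their crystal density and a nominal 1 mPa·s
viscosity contribution. Every value is overridable per scenario
(`with_species()`). Mixture rules are deliberately simple: mass-weighted
specific volumes for density, log-linear mixing for viscosity. The
diglyme–water synthesis liquor (89:11 w/w) is carried as a single
pseudo-solvent species, since the models never resolve the two components.

Solid densities and solvent densities propagate into the two quantities the
case studies print — cake void volume and retained liquor mass — so they are
the assumptions to revisit first when absolute retained-mass predictions
matter. Viscosities only set the filtration time scale.

The 18 fixtures (`make_scenario("mfa_expt1")` … `"pcm_expt9"`) transcribe
the experiment tables: per-experiment driving force, wash ratio and wash
count, suspension compositions, particle summaries, and the calibrated
(sphericity, porosity, medium resistance, compressibility) of the matching
solvent pair. PCM suspensions keep the 65 g total charge with the solid load
varying per experiment. First-wash compositions use the anti-solvent-safe
crystallization/wash mixtures (10:90 v/v for MFA; the screened fractions for
PCM), converted to mass fractions via component densities.

# Synthetic data

`generate_filtration_observations()` forward-simulates a scenario and adds
multiplicative Gaussian noise to the volume grid;
`generate_wash_observations()` does the same for per-stage filtrate
compositions (renormalizing so compositions still sum to one). Both are
bit-reproducible from `(scenario, noise_sd, seed)`. They emulate what the
bench instruments record — cumulative volumes and stage filtrate
compositions — with independent relative noise. They do **not** emulate
pre-settling before pressurization, operator error in spotting dryland,
cake cracking or channeling, partial back-mixing above the cake, or
dissolution of the solid during washing; passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to those bench artifacts.

# Design-space tools

`sweep_design_space()` evaluates the filtration+washing pipeline over grids
of wash volumes, wash counts or Peclet numbers (filtration is computed once
per sweep). The reported response is the final-cake impurity concentration
in kg per m³ of retained liquor, under which the feed-and-bleed sweep is
exactly $c_0 e^{-V/V_{void}}$.

`knee_volume()` operationalizes the qualitative "no meaningful further
removal" point: the smallest grid volume at which the marginal impurity
reduction per mL falls below 5% (configurable) of the initial marginal
reduction, anchored at the stored unwashed baseline. For an exponential
response this lands at $V^\ast \ln 20 \approx 3 V^\ast$ — about three cake
void volumes — within the grid spacing.

`optimize_wash_plan()` searches per-stage volumes on a grid (exhaustive
enumeration: responses are cheap and landscapes tie exactly under
split-invariant mechanisms, where gradient methods would dither). Ties are
broken toward fewer stages, then larger first aliquots.

# Numerical choices

* ODE integration: `lsoda`, `rtol = 1e-10`, `atol = 1e-16`; dryland event
  tolerance $10^{-6}$ m of free liquid height, terminal sample extended to
  the exact end point (above).
* Dispersion washout: evaluated with the Gaussian log-tail for the
  $e^{Pe}\,\mathrm{erfc}$ term; removed fractions by adaptive quadrature
  (`stats::integrate`, rel. tol. $10^{-12}$), and stage bookkeeping is
  written so mass balances close exactly regardless of quadrature error.
* Compositions must sum to 1 within $10^{-9}$ everywhere; configs are
  written with 15 significant digits so round-trips preserve that.
* Compressibility labels: $n<1$ low/moderate, $n\ge1$ high, $n>100$ extreme
  (the high/extreme border is not sharply defined in the literature).
* Degenerate inputs: zero-volume wash stages are exact identities; flat
  sweep responses return the smallest grid volume with a `degenerate` knee
  flag; all-equal pressures in `fit_compressibility()` return $n=0$ with an
  unidentifiable flag.
* Test problem sizes: 50-point filtrate grids, 40-point sweeps, 50-replicate
  noise studies — small enough to run the whole suite in well under a
  minute while exercising every code path.

# Known limitations

* No variable-pressure or centrifugal filtration, medium blinding, fines
  migration, cake cracking, or sequential two-layer cake build-up (the PCM
  two-dose protocol is approximated as a single batch with combined
  masses).
* No de-saturation/deliquoring physics beyond the bookkeeping drain between
  accumulate stages, and no drying.
* No dissolution or growth of the solid during washing (so anti-solvent
  precipitation is out of scope; the mixed first-wash compositions in the
  fixtures exist to honor the bench protocol, not to model the effect).
* Washing mechanisms are volume-driven; stage durations are reporting
  metadata only.
* Instant mixing in the well-mixed modes: partial or null back-mixing
  between a charged aliquot and the free liquid is not modeled, which is
  precisely why feed-and-bleed predicts identical purity for any split of a
  fixed wash total.
* In `feed_and_bleed` mode the hold-up volume is held constant while
  composition changes, so the implied liquor density drifts slightly within
  a stage; balances are kept exact in mass terms.

# A worked pass through the MFA case

```{r example, eval = FALSE}
sc <- make_scenario("mfa_expt2")
res <- simulate_filtration(sc)
glance(res)

cake <- dryland_state(res)
wash <- run_wash_program(cake, sc$wash_program)
wash$stage_summary

sw <- sweep_design_space(sc, list(wash1_volume_ml = 1:40),
                         mechanism = "well_mixed", mode = "feed_and_bleed")
knee_volume(sw)
autoplot(sw)
```
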