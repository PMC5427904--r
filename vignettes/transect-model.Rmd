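---
title: "Modelling picophytoplankton and chlorophyll on a vertical transect plane"
author: "phytodcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling picophytoplankton and chlorophyll on a vertical transect plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`phytodcm` simulates four picophytoplankton populations — *Synechococcus*,
the high-light and low-light *Prochlorococcus* ecotypes, and the
picoeukaryote assemblage — together with phosphate on a two-dimensional
vertical plane spanned by a ship transect (x, in m from the north-western
end) and depth (z, in m, positive downward). The water column is an
oligotrophic mid-summer one: strongly stratified, nutrient-starved at the
surface, with opposing vertical gradients of light and phosphate that carve
out, for each population, a *production layer* in which gross growth exceeds
losses. The observable consequence is a deep chlorophyll maximum (DCM).

Each abundance field $b_i(x,z,t)$ (cells m$^{-3}$) obeys an
advection–diffusion–reaction equation

$$\partial_t b_i = b_i\,\big(\min\{f_{I_i}(I), f_{R_i}(R)\} - m_i\big)
 + \partial_z(D_v \partial_z b_i) + \partial_x(D_h \partial_x b_i)
 - \partial_x(v_h b_i) - \partial_z(v_i b_i),$$

and phosphate $R(x,z,t)$ (mmol P m$^{-3}$) obeys

$$\partial_t R = -\sum_i \tfrac{b_i}{Y_i}\min\{f_{I_i}, f_{R_i}\}
 + \partial_z(D_v \partial_z R) + \partial_x(D_h \partial_x R)
 - \partial_x(v_h R) + \sum_i \varepsilon_i m_i \tfrac{b_i}{Y_i}.$$

Growth is Liebig co-limitation: the gross rate is the smaller of two
Michaelis–Menten terms, $f_I = r I/(I + K_I)$ for light and
$f_R = r R/(R + K_R)$ for phosphate, and $m_i$ lumps respiration, death and
grazing. Uptake removes $1/Y_i$ mmol P per new cell; a fraction
$\varepsilon_i$ of the phosphorus in dying cells is remineralised locally.
Light follows Lambert–Beer with self-shading,

$$I(x,z) = I_{in}(x)\exp\Big(-\int_0^z \big[\textstyle\sum_i a_i\,
\mathrm{chl}_i + a_{bg}\big]\,dZ\Big),$$

so the chlorophyll field feeds back on its own light supply. Active
movement is a taxis rule: cells swim down ($+v^s$) where
$\partial G/\partial z > 0$, up ($-v^s$) where it is negative, and stay put
where the net growth rate $G$ is vertically flat (a deadband of
$10^{-12}\,\mathrm{h^{-1} m^{-1}}$ regularises the sign switch).

Boundaries: the ecosystem is closed for biomass (zero total normal flux on
the surface, the bottom of each bathymetric step, and both lateral walls).
Phosphate has zero surface flux, and Dirichlet values taken from the
observed profiles on the bottom of every staircase step and on the two
lateral walls; the vertical step walls themselves are treated as solid
(no-flux) for both variables, since no condition is prescribed there.

## Environment estimation

The static environment comes from per-station hydrographic profiles.
Vertical turbulent diffusivity is a Richardson-number closure
(Pacanowski–Philander): $Ri = N^2/(\partial u/\partial z)^2$ with
$N^2 = (g/\rho_0)\,\partial \rho/\partial z$, then
$\nu = \nu_0/(1+\alpha Ri)^n + \nu_b$ and
$D_v = \nu/(1+\alpha Ri) + \kappa_b$. The defaults are the classic
constants ($\nu_0 = 10^{-2}$ m²/s, $\alpha = 5$, $n = 2$,
$\nu_b = 10^{-4}$, $\kappa_b = 10^{-5}$); all are configurable because
published applications differ in them. Zero shear receives $Ri = 10^6$ so
that $D_v \to \kappa_b$ instead of dividing by zero. Horizontal
diffusivity is piecewise-constant in x (default 100 m²/s within the
coastal fifths of the transect, 10 m²/s offshore, in the range estimated
for shelf seas). Station fields (density, velocity, phosphate) are
interpolated linearly in z then in x, with constant extension beyond the
sampled range; a station lacking a measurement is treated as carrying its
nearest neighbour's values.

## Numerics

The solver is method-of-lines: centred second-order differences for both
diffusion terms (face diffusivities are arithmetic means), flux-form
upwind-biased advection for the current and taxis terms, and forward Euler
in time with the classic Δx = 5 km, Δz = 2 m, Δt = 0.05 h defaults.

The advective face reconstruction is the κ = 1/3 third-order upwind-biased
stencil wrapped in the Koren flux limiter. On smooth monotone data the
limited faces coincide with the unlimited third-order values — the
truncation-error convergence study in the test suite measures order ≈ 3.0 —
but at sharp fronts the limiter keeps the scheme monotone. This matters
here for two structural reasons: the taxis velocity switches sign
discontinuously across a biomass maximum, focusing cells into a layer one
or two cells thick, and the data-derived horizontal current does not vanish
at the closed lateral walls, so biomass piles up against them in an
unresolvable boundary layer. With the unlimited stencil both situations
produce undershoots; clipping those to zero would act as a spurious source
(created biomass dies, is remineralised, and regrows — a positive feedback
that we observed inflating stocks without bound). With the limiter the
transported fields stay non-negative at CFL ≤ 1/2 and the clipped-mass
diagnostic stays at zero in well-resolved runs. Where the wide stencil
would leave the wet region the faces fall back to first-order upwind.

Remaining positivity clipping (from the stiff uptake term during bloom
transients) is logged in `state$clipped_mass` so tests can assert it is
negligible. The automatic time step honours the diffusive
(≤ 0.25 Δz²/D) and advective (≤ 0.5 Δz/|v|) limits with a 0.8 safety
factor, and multi-population runs cap it at 0.1 h because the nutrient
turnover time $R/(\sum b_i \mathrm{invY}_i f)$ shrinks as blooms build up —
an explicit-scheme constraint that is invisible to the transport CFL.

Steady state is declared when the relative L1 change of all prognostic
fields per 100 h falls below $10^{-6}$ (configurable), or at
$t_{max} = 2\cdot10^4$ h.

Discrete conservation is exact by construction: all transport is assembled
from face fluxes, and closed faces carry zero flux, so closed-boundary sums
telescope. The test suite verifies drift at machine precision over 1000
steps, and total phosphorus invariance when $\varepsilon_i = 1$.

## Chlorophyll conversion and diagnostics

Steady abundances convert to chlorophyll a (or divinyl chlorophyll a for
*Prochlorococcus*) via cellular pigment contents: fixed
1.18 fg cell$^{-1}$ for *Synechococcus* and piecewise-linear
photoacclimation curves (content rising with depth) for the other groups.
The default curves are placeholders in the literature range
(0.4–1.2 fg for HL *Prochlorococcus*, 0.8–2 fg for LL, 25–60 fg for
picoeukaryotes); users supply their own tables for real applications. The
modelled picophytoplankton carry only part of the total chlorophyll; the
nano/micro fraction is added per station as 20% of the station's depth-mean
fluorescence chlorophyll within the upper-layer water mass (MAW, default
lower boundary 100 m), interpolated linearly along the transect and spread
uniformly over the MAW depth range. Taking 20% of the *profile mean*
(rather than of each point) is a choice; the alternative would make the
added term depth-dependent, contradicting its "uniform over the layer"
role.

Model profiles are scored against station fluorescence profiles with the
Pearson chi-square $\chi^2 = \sum_k (o_k - e_k)^2/e_k$, using the model
values as the expected-value denominator (the source literature does not
state the denominator; this choice is recorded in every `fit_report`).
Points where the interpolated model falls below $10^{-9}$ are excluded and
counted. Model comparison uses the chi-square form of the Akaike score
($\sum\chi^2 + 2k$) and Cohen's $w = \sqrt{\chi^2/N}$ with $N$ the summed
expected values — both normalisations are stated in the output because
conventions vary.

DCM metrics: magnitude is the raw profile maximum; the depth is refined by
a parabola through the three points around the maximum; the width is the
full width at half maximum above the deep background (the value at the
profile's deepest point), since no standard width definition exists for
DCMs. Profiles whose maximum sits at the surface or the bottom are flagged
as having no DCM rather than erroring.

## Calibration

The *reduced* model lets each station carry its own half-saturation
constants; the *full* model uses one global set. Initial values invert the
production-layer boundaries: requiring $G = 0$ at a prescribed lower
(light-set) boundary gives $K_I = I(z_{bot})(r-m)/m$, and at the upper
(nutrient-set) boundary $K_R = R(z_{top})(r-m)/m$. By default the
boundaries are taken from the half-maximum edges of the observed DCM.
Refinement is a deterministic coordinate descent over log-spaced
multiplicative candidate grids (factors $2^{-1}\dots2^{1}$ in half-octave
steps), each candidate scored by running a single-column simulator of that
station to steady state and evaluating the reduced chi-square; candidates
whose peak abundances leave configured plausibility intervals are rejected
and the rejection flagged. Accepted moves never increase the chi-square.
A deterministic grid search was chosen over stochastic optimisers for exact
reproducibility; the half-octave grid bounds the achievable accuracy at
about 6% per parameter, well inside the ~25% recovery accuracy that the
noise level supports.

The column simulator is the calibration's scale-down: one x-node, the
station's own Pacanowski–Philander diffusivity profile, bottom-only
phosphate Dirichlet, Δz = 4 m and a 4000 h horizon. Full-transect
simulations are reserved for the final scoring in `fit_reduced_and_full()`.

## The synthetic scenario generator

No public dataset accompanies the study design this package addresses, so
`scenario_config()`/`generate_hydrology()` fabricate a complete seeded
survey: 12 stations over 550 km, a staircase bathymetry of seven
rectangles capped at a 200 m model floor (the biologically active upper
layer — resolving a 3000 m column at 2 m spacing would spend the entire
budget below the euphotic zone), sigmoidal pycnoclines (weaker and
shallower near the coasts, mimicking coastal mixing), surface-intensified
along-transect jets stronger near both coasts, phosphate rising through a
nutricline near 110 m from 0.02 to ~0.4 mmol m$^{-3}$, and
fluorescence-like profiles with a single Gaussian DCM tied to the
nutricline. Observation sampling applies multiplicative lognormal noise
(σ = 5% by default). Everything is deterministic per seed, and the
generator restores the caller's RNG state.

What the generator does *not* emulate: zonal (out-of-plane) currents and
their transport, internal waves and tidal aliasing in the profiles,
photoacclimation dynamics (chl:cell responds to light history),
diatom/dinoflagellate blooms near the coasts, and correlated instrument
error. Passing tests therefore demonstrate internal consistency of the
method — conservation, convergence, recovery of known parameters,
structural DCM behaviour — not skill against real cruise data.

The default community parameters are literature-plausible for
Mediterranean summer picophytoplankton but non-canonical (the constants
used in the source study are not published in its main text): growth rates
0.042–0.055 h$^{-1}$, losses 0.008–0.012 h$^{-1}$, light half-saturations
ordered 35 (Syn) > 25 (Pro HL) > 12 (picoeuk) > 4 (Pro LL)
µmol photons m$^{-2}$ s$^{-1}$ so the ecotypes stack with depth, phosphate
half-saturations 0.015–0.035 mmol m$^{-3}$, phosphorus quotas of roughly
1–3 fg P per cyanobacterial cell and ~60 fg per picoeukaryote cell, and
50% phosphorus recycling. An early parameterisation with several-fold
smaller quotas produced standing stocks exceeding the water column's
phosphorus inventory; the present values give DCM magnitudes of a few
tenths of µg dm$^{-3}$, matching what summer oligotrophic fluorescence
profiles show.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run deliberately coarsened
configurations chosen as the smallest that still exhibit the physics:
conservation on a 40 × 50 staircase for 1000 steps; single 60-node columns
for the equilibrium and DCM studies (Δt = 0.2–1 h there, since the
single-population biology is non-stiff); calibration on Δz = 4 m columns
with a 4000 h horizon; and the full pipeline at Δx = 25 km, Δz = 4 m,
integrated 2500–5000 h, by which time the DCM structure is established.
The Δx = 5 km, Δz = 2 m, Δt = 0.05 h defaults remain in place for real
use.

## Known limitations

* Forward Euler limits the time step through both transport and the stiff
  uptake term; very strong mixed layers (unstratified PP diffusivities of
  ~10$^{-2}$ m² s$^{-1}$) force Δt well below the printed default at
  Δz = 2 m. `cfl_check()` refuses such runs rather than integrating them
  unstably.
* The 2D plane cannot represent zonal transport; where real currents cross
  the transect the model's lateral pile-up against closed walls is a known
  artefact, mitigated but not removed by the limiter.
* The velocity field is treated as static and is not divergence-free in
  the plane, so advection can locally create apparent convergence of
  nutrients; this is inherited from using measured along-transect
  velocities alone.
* Calibration explores a log-grid around its initialisation; a truth far
  outside the grid's reach (beyond ~an octave per sweep times `max_iter`)
  is not found. The infeasibility and constraint flags report this rather
  than hiding it.
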