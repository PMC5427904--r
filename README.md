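# phytodcm

Picophytoplankton community dynamics and chlorophyll distribution on a
vertical transect plane of an oligotrophic sea.

## What it is for

In stratified, nutrient-poor waters (the summer Mediterranean being the
type case), light decreases downward and phosphate increases downward, and
phytoplankton concentrate in a subsurface layer — the deep chlorophyll
maximum (DCM) — where both resources are just sufficient. `phytodcm` is for
researchers who want to reproduce, on a two-dimensional x–z plane spanned
by a ship transect, the observed chlorophyll a and divinyl chlorophyll a
distribution from first principles: four picophytoplankton populations
(*Synechococcus*, high- and low-light *Prochlorococcus* ecotypes,
picoeukaryotes) competing for light and phosphate in a measured physical
environment, with the model output scored station by station against
fluorescence profiles.

The model couples, for each population `i`, an
advection–diffusion–reaction equation

    ∂b_i/∂t = b_i (min{f_I(I), f_R(R)} − m_i)
            + ∂z(D_v ∂z b_i) + ∂x(D_h ∂x b_i)
            − ∂x(v_h b_i) − ∂z(v_i b_i)

to a phosphate equation with Michaelis–Menten uptake and partial recycling,
and to a Lambert–Beer light field with chlorophyll self-shading. `v_i` is a
growth-gradient taxis (cells swim toward higher net growth at fixed speed).
Biomass boundaries are closed; phosphate is pinned to observed values at
the bottom and the lateral walls. The spatial domain is a staircase of
rectangular subdomains approximating the bathymetry; the solver is an
explicit method-of-lines scheme (centred diffusion, flux-limited
third-order upwind advection, forward Euler at Δx = 5 km, Δz = 2 m,
Δt = 0.05 h by default).

Around the solver sit the pieces a full study needs: Pacanowski–Philander
vertical diffusivity estimated from density/velocity profiles,
abundance-to-chlorophyll conversion with per-population cellular pigment
contents plus the nano/micro-phytoplankton fraction, DCM and upper-layer
(MAW) diagnostics, Pearson χ² goodness-of-fit with AIC/Cohen's-w model
comparison, and an iterative station-wise calibration of the half-saturation
constants (a "reduced" model with per-station constants vs a "full" model
with global ones). A seeded synthetic-scenario generator emulates a
12-station, 550 km summer transect survey so the whole pipeline runs
without any field data.

## Worked example: a deep chlorophyll maximum in one column

A single stratified column with light from above and a weak phosphate
source below develops a sustained interior chlorophyll maximum:

```r
library(phytodcm)

grid <- build_grid(domain_geometry(
  data.frame(x_start = 0, x_end = 1000, z_bottom = 100), dx = 1000, dz = 2))
pop <- population_params("Picoeukaryotes", r = 0.06, m = 0.02, K_I = 3,
                         K_R = 0.025, invY = 1e-13, eps = 0.5, a = 0.016,
                         v_s = 0, content = 30)
pops <- structure(list(Picoeukaryotes = pop), class = "plankton_community")
env <- structure(list(
  D_v = matrix(1e-5, 1, grid$nz), D_h = 1, v_h = matrix(0, 1, grid$nz),
  I_in = 600, a_bg = 0.07, R_in_bottom = 0.04,
  R_in_west = rep(0, grid$nz), R_in_east = rep(0, grid$nz),
  R_init = matrix(0.02, 1, grid$nz), nutrient_bc = "bottom"),
  class = "env_fields")

run <- integrate_to_steady(init_state(grid, b0 = 1e8, env = env, n_pops = 1),
                           env, pops, grid,
                           solver_settings(dt = 1, t_max = 2e4, steady_tol = 1e-7))
chl <- abundance_to_chl(run$state$b[[1]], pop$content, grid)
profile <- extract_profile(chl, grid, x_station = 500)
dcm <- dcm_metrics(profile)
cat(sprintf("DCM: %.3f ug/dm^3 at %.1f m, FWHM %.1f m\n",
            dcm$magnitude, dcm$depth, dcm$width))
R_peak <- run$state$R[1, which.max(profile$value)]
cat(sprintf("phosphate at the peak: %.4f mmol/m^3 (f_R = %.4f 1/h vs m = %.3f)\n",
            R_peak, michaelis_menten(pop$r, pop$K_R, R_peak), pop$m))
```

```
DCM: 0.125 ug/dm^3 at 81.9 m, FWHM 10.6 m
phosphate at the peak: 0.0142 mmol/m^3 (f_R = 0.0217 1/h vs m = 0.020)
```

The peak sits at 82 m — between the depth where light no longer pays for
maintenance and the depth the phosphate flux reaches — and the local
phosphate sits where uptake balances losses to within 10% (`f_R ≈ m`),
the structural signature of a nutrient-limited DCM at equilibrium.

The full transect workflow is one call chain:

```r
cfg  <- scenario_config(seed = 1, dx = 25000, dz = 4)   # coarsened demo grid
make_scenario(cfg, "demo_scenario")
scen <- read_scenario("demo_scenario")
out  <- run_transect_pipeline(scen, settings = solver_settings(t_max = 5000,
                                                               steady_tol = 1e-5))
out$stats$dcm        # per-station DCM magnitude/depth/width
out$stats$maw        # upper-layer mean chlorophyll and phosphate
out$stats$fits       # per-station chi-square reports
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/phytodcm.R` (`synth`, `simulate`, `stats` subcommands).

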