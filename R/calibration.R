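#' Production-layer initialisation of half-saturation constants
#'
#' Given the depths of the upper (nutrient-set) and lower (light-set)
#' boundaries of a population's production layer, half-saturation constants
#' are chosen so that the net growth rate vanishes exactly there: inverting
#' f_I(I) = m at z_bottom gives K_I = I(z_bottom) (r - m)/m, and inverting
#' f_R(R) = m at z_top gives K_R = R(z_top) (r - m)/m.
#'
#' @param I_profile data frame `depth`, `value`: irradiance profile.
#' @param R_profile data frame `depth`, `value`: phosphate profile.
#' @param r,m maximum growth and loss rates, 1/h (r > m).
#' @param z_top,z_bottom production-layer boundary depths, m.
#' @return list `K_I`, `K_R`.
#' @export
ryabov_initial_K <- function(I_profile, R_profile, r, m, z_top, z_bottom) {
  if (r <= m) stop("need r > m")
  I_zb <- stats::approx(I_profile$depth, I_profile$value, xout = z_bottom, rule = 2)$y
  R_zt <- stats::approx(R_profile$depth, R_profile$value, xout = z_top, rule = 2)$y
  if (I_zb <= 0) stop("irradiance must be positive at the lower boundary")
  if (R_zt <= 0) stop("phosphate must be positive at the upper boundary")
  list(K_I = I_zb * (r - m) / m, K_R = R_zt * (r - m) / m)
}

#' Calibration specification
#'
#' @param free named list of free parameters; each element
#'   `list(pop = <population name>, what = "K_I"|"K_R")`.
#' @param bounds named list of `c(lower, upper)` per free parameter.
#' @param abundance_constraints named list per population of allowed peak
#'   abundance intervals `c(lower, upper)` in cells/m^3 (NULL = none).
#' @param factors multiplicative candidate grid per coordinate sweep
#'   (log-spaced around the current value).
#' @param max_iter maximum coordinate-descent sweeps.
#' @param improve_tol relative chi-square improvement below which the
#'   descent stops.
#' @export
calibration_spec <- function(free, bounds = NULL, abundance_constraints = NULL,
                             factors = 2^seq(-1, 1, by = 0.5),
                             max_iter = 6L, improve_tol = 1e-3) {
  if (!length(free)) stop("no free parameters")
  if (!is.null(bounds))
    for (b in bounds) if (b[1L] <= 0 || b[2L] <= b[1L]) stop("bounds must be positive and ordered")
  list(free = free, bounds = bounds,
       abundance_constraints = abundance_constraints,
       factors = sort(unique(c(1, factors))), max_iter = max_iter,
       improve_tol = improve_tol)
}

apply_K <- function(pops, free, K) {
  for (nm in names(free)) {
    f <- free[[nm]]
    pops[[f$pop]][[f$what]] <- K[[nm]]
  }
  pops
}

#' Single-column simulator for one station
#'
#' Builds a one-column model of the station's water column (its own
#' Pacanowski-Philander diffusivity profile, surface irradiance and bottom
#' phosphate value; lateral transport absent) and returns a closure mapping
#' a named vector of half-saturation values to the steady total chlorophyll
#' profile and per-population peak abundances. This is the coarse harness
#' used inside the calibration loop; full-transect scoring stays 2D.
#'
#' @param station one element of a [hydro_profiles()].
#' @param pops `plankton_community` (subset to the populations of interest
#'   for speed, if desired).
#' @param free free-parameter map as in [calibration_spec()].
#' @param config an [environment_config()].
#' @param dz vertical spacing, m.
#' @param max_depth cap on the modelled column depth, m.
#' @param b0 initial uniform abundance, cells/m^3.
#' @param settings [solver_settings()]; dt is replaced by a stable step.
#' @return function(K) -> list `profile` (data frame depth/value of total
#'   chlorophyll), `peaks` (named vector, cells/m^3), `state`.
#' @export
make_column_simulator <- function(station, pops, free,
                                  config = environment_config(),
                                  dz = 4, max_depth = 200, b0 = 1e8,
                                  settings = solver_settings(t_max = 6000,
                                                             steady_tol = 1e-5)) {
  depth <- min(max(station$depth), max_depth)
  geo <- domain_geometry(data.frame(x_start = 0, x_end = 1000, z_bottom = depth),
                         dx = 1000, dz = dz)
  grid <- build_grid(geo)
  pp <- config$pp
  ri <- richardson_number(station$depth, station$density, station$u,
                          rho0 = config$rho0, g = config$g, ri_cap = config$ri_cap)
  dv <- pacanowski_philander(ri, pp$nu0, pp$alpha, pp$n, pp$nu_b, pp$kappa_b)
  D_v <- matrix(stats::approx(station$depth, dv, xout = grid$z_nodes, rule = 2)$y,
                1L, grid$nz)
  R_prof <- stats::approx(station$depth, station$phosphate,
                          xout = grid$z_nodes, rule = 2)$y
  env <- structure(list(
    D_v = D_v, D_h = 1, v_h = matrix(0, 1L, grid$nz), I_in = station$I_in,
    a_bg = config$a_bg, R_in_bottom = R_prof[grid$nz],
    R_in_west = R_prof, R_in_east = R_prof,
    R_init = matrix(R_prof, 1L, grid$nz), nutrient_bc = "bottom"),
    class = "env_fields")
  settings$dt <- suggest_dt(env, pops, grid, dt_max = 1)
  force(free)
  function(K) {
    p <- apply_K(pops, free, as.list(K))
    st0 <- init_state(grid, b0 = b0, env = env, n_pops = length(p))
    run <- integrate_to_steady(st0, env, p, grid, settings)
    chl <- lapply(seq_along(p), function(i)
      abundance_to_chl(run$state$b[[i]], p[[i]]$content, grid))
    total <- Reduce(`+`, chl)
    peaks <- vapply(run$state$b, max, numeric(1))
    names(peaks) <- names(p)
    list(profile = data.frame(depth = grid$z_nodes, value = total[1L, ]),
         peaks = peaks, state = run$state, converged = run$converged)
  }
}

#' Calibrate half-saturation constants at one station
#'
#' Deterministic coordinate descent over log-spaced multiplicative candidate
#' grids around the initial values. Each candidate is scored by running the
#' supplied simulator to steady state and computing the reduced chi-square
#' of the modelled chlorophyll profile against the station observations;
#' candidates whose peak abundances leave the allowed intervals are
#' rejected. Accepted moves never increase the chi-square.
#'
#' @param observed data frame `depth`, `value`: observed chlorophyll.
#' @param simulate_fn closure from [make_column_simulator()] (or compatible).
#' @param init named numeric vector of initial values for the free
#'   parameters.
#' @param spec a [calibration_spec()].
#' @return list `K` (named vector), `fit` (`fit_report`), `init_fit`,
#'   `n_evals`, `constraint_active`, `trace` (chi2_red per accepted sweep).
#' @export
calibrate_station <- function(observed, simulate_fn, init, spec) {
  free <- spec$free
  stopifnot(all(names(free) %in% names(init)))
  n_free <- length(free)
  feasible <- function(sim) {
    ac <- spec$abundance_constraints
    if (is.null(ac)) return(TRUE)
    for (nm in names(ac)) {
      if (!nm %in% names(sim$peaks)) next
      if (sim$peaks[[nm]] < ac[[nm]][1L] || sim$peaks[[nm]] > ac[[nm]][2L])
        return(FALSE)
    }
    TRUE
  }
  score <- function(sim) chi_square(sim$profile, observed, n_free)$chi2_red
  n_evals <- 0L
  evaluate <- function(K) {
    n_evals <<- n_evals + 1L
    sim <- simulate_fn(K)
    list(sim = sim, ok = feasible(sim), chi2_red = score(sim))
  }
  K <- init[names(free)]
  cur <- evaluate(K)
  if (!cur$ok)
    stop("infeasible starting point: peak abundances violate the allowed intervals")
  init_fit <- chi_square(cur$sim$profile, observed, n_free,
                         station_id = "init")
  constraint_active <- FALSE
  trace <- cur$chi2_red
  for (iter in seq_len(spec$max_iter)) {
    improved <- FALSE
    for (nm in names(free)) {
      cand <- K[[nm]] * spec$factors
      if (!is.null(spec$bounds) && nm %in% names(spec$bounds))
        cand <- pmin(pmax(cand, spec$bounds[[nm]][1L]), spec$bounds[[nm]][2L])
      cand <- setdiff(unique(cand), K[[nm]])
      best <- cur
      bestK <- K
      for (v in cand) {
        Kc <- K; Kc[[nm]] <- v
        ev <- evaluate(Kc)
        if (!ev$ok) {
          if (ev$chi2_red < best$chi2_red) constraint_active <- TRUE
          next
        }
        if (ev$chi2_red < best$chi2_red) { best <- ev; bestK <- Kc }
      }
      if (best$chi2_red < cur$chi2_red * (1 - spec$improve_tol)) {
        cur <- best; K <- bestK; improved <- TRUE
      }
    }
    trace <- c(trace, cur$chi2_red)
    if (!improved) break
  }
  fit <- chi_square(cur$sim$profile, observed, n_free, station_id = "final")
  list(K = K, fit = fit, init_fit = init_fit, n_evals = n_evals,
       constraint_active = constraint_active, trace = trace)
}

# default production-layer boundaries from an observed chlorophyll profile:
# the DCM's half-maximum edges, falling back to the upper/lower quartile
# depths when no interior maximum exists.
production_layer_from_obs <- function(observed) {
  m <- dcm_metrics(observed)
  if (m$has_dcm && is.finite(m$width) && m$width > 0)
    list(z_top = max(min(observed$depth), m$depth - m$width / 2),
         z_bottom = min(max(observed$depth), m$depth + m$width / 2))
  else
    list(z_top = stats::quantile(observed$depth, 0.25, names = FALSE),
         z_bottom = stats::quantile(observed$depth, 0.75, names = FALSE))
}

#' Fit the reduced (station-wise K) and full (global K) model variants
#'
#' For each station, half-saturation constants are initialised from the
#' production layer implied by the observed chlorophyll profile (half-
#' maximum edges of the DCM) and refined by [calibrate_station()] on that
#' station's column simulator (reduced model). The full model calibrates a
#' single global K set against the pooled chi-square over all stations.
#' Both variants are compared with [model_selection_stats()].
#'
#' @param stations a [hydro_profiles()] (>= 2 stations).
#' @param pops `plankton_community`.
#' @param spec [calibration_spec()].
#' @param config [environment_config()].
#' @param ... passed to [make_column_simulator()].
#' @return list `reduced` (per-station results), `full` (global K and
#'   per-station fits), `stats` (model-selection bundle), `K_table`
#'   (data frame of per-station K values for the reduced model).
#' @export
fit_reduced_and_full <- function(stations, pops, spec,
                                 config = environment_config(), ...) {
  if (length(stations) < 2L) stop("need >= 2 stations")
  sims <- lapply(stations, make_column_simulator, pops = pops,
                 free = spec$free, config = config, ...)
  obs_list <- lapply(stations, function(s)
    data.frame(depth = s$depth, value = s$chl))
  inits <- lapply(seq_along(stations), function(i) {
    s <- stations[[i]]; obs <- obs_list[[i]]
    layer <- production_layer_from_obs(obs)
    Iprof <- data.frame(depth = s$depth,
                        value = s$I_in * exp(-config$a_bg * s$depth))
    Rprof <- data.frame(depth = s$depth, value = pmax(s$phosphate, 1e-6))
    K <- numeric(0)
    for (nm in names(spec$free)) {
      f <- spec$free[[nm]]
      p <- pops[[f$pop]]
      ry <- ryabov_initial_K(Iprof, Rprof, p$r, p$m,
                             layer$z_top, layer$z_bottom)
      K[[nm]] <- if (f$what == "K_I") ry$K_I else ry$K_R
    }
    K
  })
  reduced <- lapply(seq_along(stations), function(i) {
    res <- calibrate_station(obs_list[[i]], sims[[i]], inits[[i]], spec)
    res$fit$station_id <- stations[[i]]$station_id
    res
  })
  names(reduced) <- vapply(stations, `[[`, character(1), "station_id")

  # full model: one global K scored on the pooled chi-square
  pooled_sim <- function(K) {
    runs <- lapply(sims, function(f) f(K))
    profile <- do.call(rbind, lapply(seq_along(runs), function(i) {
      p <- runs[[i]]$profile
      p$depth <- p$depth + (i - 1L) * 1e6    # disjoint depth blocks per station
      p
    }))
    peaks <- Reduce(pmax, lapply(runs, `[[`, "peaks"))
    list(profile = profile, peaks = peaks, runs = runs)
  }
  pooled_obs <- do.call(rbind, lapply(seq_along(obs_list), function(i) {
    o <- obs_list[[i]]; o$depth <- o$depth + (i - 1L) * 1e6; o
  }))
  init_full <- inits[[which.min(vapply(seq_along(reduced), function(i)
    reduced[[i]]$fit$chi2_red, numeric(1)))]]
  full_res <- calibrate_station(pooled_obs, pooled_sim, init_full, spec)
  final_runs <- pooled_sim(full_res$K)$runs
  full_fits <- lapply(seq_along(stations), function(i)
    chi_square(final_runs[[i]]$profile, obs_list[[i]], length(spec$free),
               station_id = stations[[i]]$station_id))
  red_fits <- lapply(reduced, `[[`, "fit")
  stats <- model_selection_stats(red_fits, full_fits,
                                 k_reduced = length(spec$free) * length(stations),
                                 k_full = length(spec$free))
  K_table <- do.call(rbind, lapply(names(reduced), function(id)
    data.frame(station_id = id, t(reduced[[id]]$K))))
  list(reduced = reduced,
       full = list(K = full_res$K, fits = full_fits),
       stats = stats, K_table = K_table)
}
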