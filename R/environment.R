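#' Bundle per-station hydrographic profiles
#'
#' @param stations list; each element a list with `station_id`, `x` (m along
#'   the transect), `I_in` (surface irradiance, umol photons m^-2 s^-1) and
#'   depth series `depth` (m, strictly increasing), `density` (kg m^-3),
#'   `u` (m s^-1, along-transect), `phosphate` (mmol P m^-3) and `chl`
#'   (fluorescence-derived chlorophyll, ug dm^-3).
#' @return object of class `hydro_profiles` (the validated station list).
#' @export
hydro_profiles <- function(stations) {
  if (length(stations) < 1L) stop("need at least one station")
  xs <- vapply(stations, function(s) s$x, numeric(1))
  if (is.unsorted(xs, strictly = TRUE)) stop("station_x must be strictly increasing")
  for (s in stations) {
    need <- c("station_id", "x", "I_in", "depth", "density", "u", "phosphate", "chl")
    miss <- setdiff(need, names(s))
    if (length(miss)) stop("station ", s$station_id, ": missing fields ", paste(miss, collapse = ", "))
    if (is.unsorted(s$depth, strictly = TRUE))
      stop("station ", s$station_id, ": depths must be strictly increasing")
    n <- length(s$depth)
    for (f in c("density", "u", "phosphate", "chl"))
      if (length(s[[f]]) != n) stop("station ", s$station_id, ": length mismatch in ", f)
    if (any(diff(s$density) < -0.5))
      stop("station ", s$station_id, ": density strongly decreasing with depth (unstable profile)")
  }
  structure(stations, class = "hydro_profiles")
}

#' Gradient Richardson number from a density/velocity profile
#'
#' Ri(z) = N^2 / (du/dz)^2 with N^2 = (g/rho0) drho/dz (z positive downward,
#' so drho/dz >= 0 is stable). Derivatives use centred differences with
#' one-sided differences at the ends; negative N^2 is clipped to zero and
#' zero-shear points receive the cap value.
#'
#' @param depth depths in m, strictly increasing, length >= 3.
#' @param density potential density, kg m^-3.
#' @param u along-transect velocity, m s^-1.
#' @param rho0 reference density (kg m^-3).
#' @param g gravity (m s^-2).
#' @param ri_cap Ri assigned where the shear vanishes (default 1e6).
#' @return numeric vector of Ri, same length as `depth`.
#' @export
richardson_number <- function(depth, density, u, rho0 = 1025, g = 9.81, ri_cap = 1e6) {
  n <- length(depth)
  if (n < 3L) stop("need at least 3 depth levels")
  if (is.unsorted(depth, strictly = TRUE)) stop("depths must be strictly increasing")
  if (length(density) != n || length(u) != n) stop("series must share the depth axis")
  ddz <- function(f) {
    d <- numeric(n)
    d[1L] <- (f[2L] - f[1L]) / (depth[2L] - depth[1L])
    d[n]  <- (f[n] - f[n - 1L]) / (depth[n] - depth[n - 1L])
    if (n > 2L) {
      k <- 2:(n - 1L)
      d[k] <- (f[k + 1L] - f[k - 1L]) / (depth[k + 1L] - depth[k - 1L])
    }
    d
  }
  n2 <- pmax(0, (g / rho0) * ddz(density))
  shear2 <- ddz(u)^2
  ri <- ifelse(shear2 == 0, ri_cap, n2 / shear2)
  pmin(ri, ri_cap)
}

#' Pacanowski-Philander vertical turbulent diffusivity
#'
#' Classic Richardson-number closure: nu = nu0/(1 + alpha Ri)^n + nu_b and
#' D_v = nu/(1 + alpha Ri) + kappa_b. Monotonically non-increasing in Ri;
#' tends to `nu0 + nu_b + kappa_b` in unstratified water and to `kappa_b`
#' under strong stratification.
#'
#' @param ri Richardson numbers (>= 0).
#' @param nu0,alpha,n,nu_b,kappa_b closure constants (defaults 0.01 m^2/s, 5,
#'   2, 1e-4 m^2/s, 1e-5 m^2/s).
#' @return vertical diffusivity, m^2 s^-1.
#' @export
pacanowski_philander <- function(ri, nu0 = 0.01, alpha = 5, n = 2,
                                 nu_b = 1e-4, kappa_b = 1e-5) {
  if (any(ri < 0)) stop("negative Richardson number: clip before calling")
  nu <- nu0 / (1 + alpha * ri)^n + nu_b
  nu / (1 + alpha * ri) + kappa_b
}

#' Interpolate station profiles onto the transect grid
#'
#' Linear in z within each station (nearest-value extension beyond the
#' sampled depths), then linear in x between stations with constant
#' extrapolation beyond the first/last station. Station values are
#' reproduced exactly at their own x/z nodes.
#'
#' @param profiles a [hydro_profiles()] object with >= 2 stations.
#' @param grid a [build_grid()] grid.
#' @param field_name one of `"density"`, `"u"`, `"phosphate"`, `"chl"`, or a
#'   per-station derived series passed via `values` (list of vectors aligned
#'   with each station's depths).
#' @param values optional list of per-station depth series overriding
#'   `field_name` lookup (used e.g. for derived diffusivity profiles).
#' @return nx by nz matrix (defined on all nodes; mask downstream).
#' @export
interpolate_to_grid <- function(profiles, grid, field_name, values = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 stations to interpolate")
  if (is.null(values)) {
    if (!field_name %in% c("density", "u", "phosphate", "chl"))
      stop("unknown field_name: ", field_name)
    values <- lapply(profiles, `[[`, field_name)
  }
  xs <- vapply(profiles, `[[`, numeric(1), "x")
  # per-station values on the grid z axis
  onz <- vapply(seq_along(profiles), function(i) {
    stats::approx(profiles[[i]]$depth, values[[i]], xout = grid$z_nodes, rule = 2)$y
  }, numeric(grid$nz))
  onz <- matrix(onz, nrow = grid$nz)            # nz x nstation
  out <- vapply(seq_len(grid$nz), function(k) {
    stats::approx(xs, onz[k, ], xout = grid$x_nodes, rule = 2)$y
  }, numeric(grid$nx))
  matrix(out, nrow = grid$nx)                   # nx x nz
}

#' Default environment configuration
#'
#' @param dh_segments data frame `x_start`, `x_end` (m), `value` (m^2/s):
#'   piecewise-constant horizontal diffusivity (coastal-enhanced by default).
#' @param a_bg background turbidity, 1/m.
#' @param pp list of Pacanowski-Philander constants.
#' @param rho0,g,ri_cap Richardson-number parameters.
#' @param nutrient_bc `"dirichlet"` (bottom and lateral phosphate pinned to
#'   observed values) or `"closed"` (test harness variant).
#' @export
environment_config <- function(dh_segments = NULL, a_bg = 0.045,
                               pp = list(nu0 = 0.01, alpha = 5, n = 2,
                                         nu_b = 1e-4, kappa_b = 1e-5),
                               rho0 = 1025, g = 9.81, ri_cap = 1e6,
                               nutrient_bc = "dirichlet") {
  list(dh_segments = dh_segments, a_bg = a_bg, pp = pp,
       rho0 = rho0, g = g, ri_cap = ri_cap, nutrient_bc = nutrient_bc)
}

#' Assemble the static environmental fields
#'
#' Computes per-station Richardson numbers and Pacanowski-Philander vertical
#' diffusivities, interpolates them (and the current velocity) onto the grid,
#' looks up the piecewise-constant horizontal diffusivity, interpolates
#' surface irradiance per x node, and samples boundary phosphate values at
#' the bottom of each column and along both lateral boundaries.
#'
#' @param profiles a [hydro_profiles()] with >= 2 stations.
#' @param grid a [build_grid()] grid.
#' @param config an [environment_config()].
#' @return object of class `env_fields`: `D_v` (nx x nz, m^2/s), `D_h` (per
#'   x node, m^2/s), `v_h` (nx x nz, m/s), `I_in` (per x node), `a_bg`,
#'   `R_in_bottom` (per x node), `R_in_west`/`R_in_east` (per z node),
#'   `R_init` (interpolated phosphate field), `nutrient_bc`.
#' @export
assemble_environment <- function(profiles, grid, config = environment_config()) {
  if (!inherits(profiles, "hydro_profiles")) profiles <- hydro_profiles(profiles)
  pp <- config$pp
  dv_prof <- lapply(profiles, function(s) {
    ri <- richardson_number(s$depth, s$density, s$u,
                            rho0 = config$rho0, g = config$g, ri_cap = config$ri_cap)
    pacanowski_philander(ri, pp$nu0, pp$alpha, pp$n, pp$nu_b, pp$kappa_b)
  })
  D_v <- interpolate_to_grid(profiles, grid, values = dv_prof)
  v_h <- interpolate_to_grid(profiles, grid, "u")
  R_init <- interpolate_to_grid(profiles, grid, "phosphate")

  if (is.null(config$dh_segments)) {
    x_l <- grid$geometry$x_l
    config$dh_segments <- data.frame(
      x_start = c(0, 0.2 * x_l, 0.8 * x_l),
      x_end   = c(0.2 * x_l, 0.8 * x_l, x_l),
      value   = c(100, 10, 100))
  }
  seg <- config$dh_segments
  D_h <- vapply(grid$x_nodes, function(x) {
    j <- which(x >= seg$x_start - 1e-9 & x <= seg$x_end + 1e-9)[1L]
    if (is.na(j)) stop("D_h segments do not cover x = ", x)
    seg$value[j]
  }, numeric(1))
  if (any(D_h <= 0)) stop("D_h must be positive")

  xs <- vapply(profiles, `[[`, numeric(1), "x")
  I_in <- stats::approx(xs, vapply(profiles, `[[`, numeric(1), "I_in"),
                        xout = grid$x_nodes, rule = 2)$y

  kb <- grid$nwet
  R_in_bottom <- R_init[cbind(seq_len(grid$nx), kb)]
  R_in_west <- R_init[1L, ]
  R_in_east <- R_init[grid$nx, ]

  env <- list(D_v = D_v, D_h = D_h, v_h = v_h, I_in = I_in, a_bg = config$a_bg,
              R_in_bottom = R_in_bottom, R_in_west = R_in_west,
              R_in_east = R_in_east, R_init = R_init,
              nutrient_bc = config$nutrient_bc)
  class(env) <- "env_fields"
  validate_env_fields(env, grid)
  env
}

validate_env_fields <- function(env, grid) {
  w <- grid$wet
  if (any(!is.finite(env$D_v[w])) || any(env$D_v[w] <= 0)) stop("D_v must be finite and positive")
  if (any(!is.finite(env$D_h)) || any(env$D_h <= 0)) stop("D_h must be finite and positive")
  if (any(!is.finite(env$v_h[w]))) stop("v_h must be finite")
  if (any(env$R_in_bottom < 0) || any(env$R_in_west < 0) || any(env$R_in_east < 0))
    stop("boundary phosphate must be non-negative")
  invisible(env)
}
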