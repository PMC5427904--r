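# run code with a local, restorable RNG state so generators are seeded
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthetic transect scenario configuration
#'
#' Describes a seeded stand-in for a mid-summer oligotrophic transect
#' survey: ~12 stations over ~550 km, strongly stratified water with a
#' pycnocline, surface-intensified along-transect currents stronger near
#' both coasts, phosphate increasing with depth below a nutricline, and
#' fluorescence profiles with a single deep chlorophyll maximum. The
#' modelled water column is capped at `model_floor` (the biologically
#' active upper layer) even where the real bathymetry is far deeper.
#'
#' @param n_stations number of stations (default 12).
#' @param transect_length m (default 550e3).
#' @param dx,dz grid spacings, m (defaults 5000 and 2).
#' @param model_floor modelled depth cap, m (default 200).
#' @param subdomains data frame `x_start`, `x_end`, `z_bottom` (m); default
#'   seven rectangles spanning the transect.
#' @param rho0 surface density, kg/m^3.
#' @param delta_rho pycnocline density contrast, kg/m^3.
#' @param pycnocline_depth,pycnocline_width m.
#' @param current_amp surface current amplitude, m/s.
#' @param current_efold current e-folding depth, m.
#' @param p_surface,p_deep surface and deep phosphate, mmol P/m^3.
#' @param nutricline_depth,nutricline_width m.
#' @param I_in_range surface irradiance range across stations,
#'   umol photons m^-2 s^-1.
#' @param noise_sd multiplicative lognormal observation noise sigma.
#' @param seed integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_stations = 12L, transect_length = 550e3,
                            dx = 5000, dz = 2, model_floor = 200,
                            subdomains = NULL,
                            rho0 = 1026, delta_rho = 2.5,
                            pycnocline_depth = 40, pycnocline_width = 12,
                            current_amp = 0.25, current_efold = 50,
                            p_surface = 0.02, p_deep = 0.40,
                            nutricline_depth = 110, nutricline_width = 15,
                            I_in_range = c(500, 650),
                            noise_sd = 0.05, seed = 1L) {
  stopifnot(n_stations >= 2L, transect_length > 0, model_floor > 0, noise_sd >= 0)
  if (is.null(subdomains)) {
    L <- transect_length
    frac <- c(0, 0.09, 0.27, 0.45, 0.60, 0.78, 0.93, 1)
    depths <- pmin(c(120, 200, 200, 160, 200, 200, 140), model_floor)
    subdomains <- data.frame(x_start = frac[-8] * L, x_end = frac[-1] * L,
                             z_bottom = depths)
    # snap subdomain edges to the grid spacing
    subdomains$x_start <- round(subdomains$x_start / dx) * dx
    subdomains$x_end <- round(subdomains$x_end / dx) * dx
  }
  cfg <- list(n_stations = as.integer(n_stations),
              transect_length = transect_length, dx = dx, dz = dz,
              model_floor = model_floor, subdomains = subdomains,
              rho0 = rho0, delta_rho = delta_rho,
              pycnocline_depth = pycnocline_depth,
              pycnocline_width = pycnocline_width,
              current_amp = current_amp, current_efold = current_efold,
              p_surface = p_surface, p_deep = p_deep,
              nutricline_depth = nutricline_depth,
              nutricline_width = nutricline_width,
              I_in_range = I_in_range, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

station_bottom_depth <- function(cfg, x) {
  sd <- cfg$subdomains
  j <- which(x >= sd$x_start - 1e-9 & x <= sd$x_end + 1e-9)[1L]
  min(sd$z_bottom[j], cfg$model_floor)
}

#' Generate synthetic hydrographic station profiles
#'
#' Deterministic per seed. Density follows a sigmoidal pycnocline (always
#' non-decreasing with depth); the along-transect current is a
#' surface-intensified jet, stronger near both coasts; phosphate rises
#' sigmoidally through the nutricline (oligotrophic surface values); the
#' fluorescence-like chlorophyll profile has a single Gaussian deep
#' maximum over a small background. Stations near the coasts are less
#' stratified (shallower, weaker pycnocline), mimicking coastal mixing.
#'
#' @param cfg a [scenario_config()].
#' @return a [hydro_profiles()] object.
#' @export
generate_hydrology <- function(cfg) {
  with_seed(cfg$seed, {
    L <- cfg$transect_length
    # stations centred on grid columns, spanning the transect
    nx <- max(2L, as.integer(round(L / cfg$dx)))
    j <- unique(round(seq(1L, nx, length.out = cfg$n_stations)))
    xs <- (j - 0.5) * cfg$dx
    stations <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      x <- xs[i]
      s <- x / L                              # 0..1 along the transect
      coast <- (2 * s - 1)^2                  # 1 at the coasts, 0 mid-transect
      depth_max <- station_bottom_depth(cfg, x)
      depth <- seq(1, depth_max - 1, by = cfg$dz)
      strat <- 0.6 + 0.4 * (1 - coast)        # weaker stratification near coasts
      zp <- cfg$pycnocline_depth * (0.8 + 0.4 * (1 - coast)) +
        stats::rnorm(1, 0, 2)
      density <- cfg$rho0 + cfg$delta_rho * strat /
        (1 + exp(-(depth - zp) / cfg$pycnocline_width))
      u0 <- cfg$current_amp * (0.35 + 0.65 * coast) * (1 + stats::rnorm(1, 0, 0.05))
      u <- u0 * exp(-depth / cfg$current_efold)
      zn <- cfg$nutricline_depth * (0.8 + 0.4 * (1 - coast)) + stats::rnorm(1, 0, 3)
      phosphate <- cfg$p_surface + (cfg$p_deep * (0.8 + 0.4 * coast) - cfg$p_surface) /
        (1 + exp(-(depth - zn) / cfg$nutricline_width))
      z_dcm <- min(0.85 * zn, 0.7 * depth_max) + stats::rnorm(1, 0, 3)
      A <- 0.30 + 0.15 * coast + abs(stats::rnorm(1, 0, 0.03))
      chl <- 0.05 + A * exp(-(depth - z_dcm)^2 / (2 * 18^2))
      chl <- chl * exp(stats::rnorm(length(chl), 0, cfg$noise_sd / 2))
      I_in <- cfg$I_in_range[1L] +
        diff(cfg$I_in_range) * (0.5 + 0.5 * sin(pi * s)) + stats::rnorm(1, 0, 10)
      stations[[i]] <- list(station_id = sprintf("M%02d", i), x = x, I_in = I_in,
                            depth = depth, density = density, u = u,
                            phosphate = phosphate, chl = chl)
    }
    hydro_profiles(stations)
  })
}

#' Sample noisy station observations from a truth run
#'
#' Extracts the truth total-chlorophyll and phosphate profiles at each
#' station's x, on the model z axis, and applies multiplicative lognormal
#' noise exp(sigma Z), floored at zero.
#'
#' @param cfg a [scenario_config()] (supplies the seed and noise sigma).
#' @param truth list with `chl_total` and `R` fields plus `grid` (e.g. from
#'   a completed simulation).
#' @param stations the [hydro_profiles()] defining station positions.
#' @param sigma noise level; defaults to `cfg$noise_sd`.
#' @return list per station: `station_id`, `x`, `chl` and `phosphate`
#'   data frames (`depth`, `value`).
#' @export
generate_observations <- function(cfg, truth, stations, sigma = cfg$noise_sd) {
  if (is.null(truth$chl_total) || is.null(truth$R) || is.null(truth$grid))
    stop("truth must provide chl_total, R and grid")
  with_seed(cfg$seed + 1L, {
    lapply(stations, function(s) {
      chl <- extract_profile(truth$chl_total, truth$grid, s$x)
      ph <- extract_profile(truth$R, truth$grid, s$x)
      if (sigma > 0) {
        chl$value <- pmax(0, chl$value * exp(stats::rnorm(nrow(chl), 0, sigma)))
        ph$value <- pmax(0, ph$value * exp(stats::rnorm(nrow(ph), 0, sigma)))
      }
      list(station_id = s$station_id, x = s$x, chl = chl, phosphate = ph)
    })
  })
}

#' Write a complete, self-contained scenario bundle
#'
#' Produces a directory with `geometry.csv` (subdomains, km and m),
#' `stations.csv` (index with x_km and surface irradiance), one
#' `station_<id>.csv` profile file per station, `config.yaml` and a
#' `manifest.json` recording the seed and generated parameter values. The
#' bundle is readable back with [read_scenario()].
#'
#' @param cfg a [scenario_config()].
#' @param dir target directory (created if needed).
#' @return invisibly, the directory path.
#' @export
make_scenario <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  profiles <- generate_hydrology(cfg)
  geo <- cfg$subdomains
  utils::write.csv(data.frame(x_start_km = geo$x_start / 1000,
                              x_end_km = geo$x_end / 1000,
                              depth_m = pmin(geo$z_bottom, cfg$model_floor)),
                   file.path(dir, "geometry.csv"), row.names = FALSE)
  idx <- data.frame(station_id = vapply(profiles, `[[`, character(1), "station_id"),
                    x_km = vapply(profiles, `[[`, numeric(1), "x") / 1000,
                    I_in = vapply(profiles, `[[`, numeric(1), "I_in"))
  utils::write.csv(idx, file.path(dir, "stations.csv"), row.names = FALSE)
  for (s in profiles) {
    utils::write.csv(data.frame(depth_m = s$depth, density_kg_m3 = s$density,
                                u_m_s = s$u, phosphate_mmol_m3 = s$phosphate,
                                chl_ug_dm3 = s$chl),
                     file.path(dir, paste0("station_", s$station_id, ".csv")),
                     row.names = FALSE)
  }
  yaml::write_yaml(list(dx_m = cfg$dx, dz_m = cfg$dz,
                        model_floor_m = cfg$model_floor,
                        a_bg = 0.045,
                        maw_depth_m = 100,
                        nano_micro_fraction = 0.20),
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(c(cfg[setdiff(names(cfg), "subdomains")],
                         list(n_files = length(profiles))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
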