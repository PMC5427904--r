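read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in setdiff(required, "station_id")) {
    if (!is.numeric(df[[col]]))
      stop("parse error in ", basename(path), ": non-numeric values in column ", col)
  }
  df
}

#' Read a station-profile bundle
#'
#' Expects the layout written by [make_scenario()]: a `stations.csv` index
#' (`station_id`, `x_km`, `I_in`) and one `station_<id>.csv` per station
#' with columns `depth_m`, `density_kg_m3`, `u_m_s`, `phosphate_mmol_m3`,
#' `chl_ug_dm3`. Units in headers; km converted to m on read.
#'
#' @param dir bundle directory.
#' @return a [hydro_profiles()] object.
#' @export
read_station_profiles <- function(dir) {
  idx <- read_csv_checked(file.path(dir, "stations.csv"),
                          c("station_id", "x_km", "I_in"))
  stations <- lapply(seq_len(nrow(idx)), function(i) {
    f <- file.path(dir, paste0("station_", idx$station_id[i], ".csv"))
    df <- read_csv_checked(f, c("depth_m", "density_kg_m3", "u_m_s",
                                "phosphate_mmol_m3", "chl_ug_dm3"))
    if (is.unsorted(df$depth_m, strictly = TRUE))
      stop("validation error in ", basename(f), ": depths out of order")
    list(station_id = idx$station_id[i], x = idx$x_km[i] * 1000,
         I_in = idx$I_in[i], depth = df$depth_m, density = df$density_kg_m3,
         u = df$u_m_s, phosphate = df$phosphate_mmol_m3, chl = df$chl_ug_dm3)
  })
  hydro_profiles(stations)
}

#' Read a scenario bundle
#'
#' @param dir bundle directory written by [make_scenario()].
#' @return list `geometry` (a [domain_geometry()]), `profiles`
#'   ([hydro_profiles()]), `config` (list from `config.yaml`).
#' @export
read_scenario <- function(dir) {
  geo <- read_csv_checked(file.path(dir, "geometry.csv"),
                          c("x_start_km", "x_end_km", "depth_m"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  geometry <- domain_geometry(
    data.frame(x_start = geo$x_start_km * 1000, x_end = geo$x_end_km * 1000,
               z_bottom = geo$depth_m),
    dx = cfg$dx_m, dz = cfg$dz_m)
  list(geometry = geometry, profiles = read_station_profiles(dir), config = cfg)
}

#' Write gridded model output
#'
#' Self-describing delimited-text export: a long-format `fields.csv` with
#' coordinates `x_m`, `z_m` and one column per variable (abundances,
#' phosphate, irradiance, per-population and total chlorophyll, D_v, v_h),
#' dry nodes stored as NA, plus a `meta.json` with dimensions, spacings and
#' variable units. Round-trips losslessly through [read_gridded_output()].
#'
#' @param state steady `transect_state`.
#' @param chlmap a `chl_map` (or NULL).
#' @param env `env_fields`.
#' @param grid the grid.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_gridded_output <- function(state, chlmap, env, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(m) { m[!grid$wet] <- NA; as.vector(m) }
  df <- data.frame(x_m = rep(grid$x_nodes, times = grid$nz),
                   z_m = rep(grid$z_nodes, each = grid$nx))
  for (i in seq_along(state$b)) df[[paste0("b", i)]] <- flat(state$b[[i]])
  df$R <- flat(state$R)
  if (!is.null(chlmap)) {
    for (nm in names(chlmap$per_pop))
      df[[paste0("chl_", nm)]] <- flat(chlmap$per_pop[[nm]])
    df$chl_total <- flat(chlmap$total)
  }
  df$D_v <- flat(env$D_v)
  df$v_h <- flat(env$v_h)
  utils::write.csv(df, file.path(dir, "fields.csv"), row.names = FALSE)
  meta <- list(nx = grid$nx, nz = grid$nz, dx = grid$dx, dz = grid$dz,
               t_h = state$t,
               units = list(b = "cells/m^3", R = "mmol P/m^3",
                            chl = "ug/dm^3", D_v = "m^2/s", v_h = "m/s",
                            x_m = "m", z_m = "m"),
               n_populations = length(state$b))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read gridded model output back
#'
#' @param dir directory written by [write_gridded_output()].
#' @return list `fields` (named list of nx-by-nz matrices, dry = NA),
#'   `meta`, `x_nodes`, `z_nodes`.
#' @export
read_gridded_output <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "fields.csv"))
  vars <- setdiff(names(df), c("x_m", "z_m"))
  fields <- lapply(vars, function(v) matrix(df[[v]], meta$nx, meta$nz))
  names(fields) <- vars
  list(fields = fields, meta = meta,
       x_nodes = unique(df$x_m), z_nodes = unique(df$z_m))
}

#' Export per-station profile tables
#'
#' @param field nx-by-nz matrix.
#' @param grid the grid.
#' @param stations [hydro_profiles()].
#' @param path CSV file path.
#' @export
write_station_profiles <- function(field, grid, stations, path) {
  rows <- lapply(stations, function(s) {
    p <- extract_profile(field, grid, s$x)
    data.frame(station_id = s$station_id, depth_m = p$depth, value = p$value)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
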