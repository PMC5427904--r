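#' Default cellular pigment-content curves
#'
#' Synechococcus uses a fixed 1.18 fg chl a per cell; the other groups use
#' placeholder piecewise-linear photoacclimation curves (pigment per cell
#' rising with depth), configurable by the user. Values are
#' literature-plausible but non-canonical.
#'
#' @return named list of data frames `depth_m`, `fg_per_cell`.
#' @export
default_conversion_curves <- function() {
  list(
    Synechococcus = data.frame(depth_m = c(0, 200), fg_per_cell = c(1.18, 1.18)),
    Prochlorococcus_HL = data.frame(depth_m = c(0, 120, 200),
                                    fg_per_cell = c(0.4, 1.2, 1.2)),
    Picoeukaryotes = data.frame(depth_m = c(0, 120, 200),
                                fg_per_cell = c(25, 60, 60)),
    Prochlorococcus_LL = data.frame(depth_m = c(0, 150, 200),
                                    fg_per_cell = c(0.8, 2.0, 2.0)))
}

#' Convert an abundance field to a chlorophyll field
#'
#' chl(x, z) = b(x, z) [cells/m^3] x content(z) [fg/cell] x 1e-12
#' = ug/dm^3 (1 fg/m^3 = 1e-12 ug/dm^3).
#'
#' @param b abundance field, cells m^-3 (nx by nz, >= 0).
#' @param curve content curve: data frame `depth_m`, `fg_per_cell`
#'   (piecewise-linear, constant extrapolation) or a single fg/cell value.
#' @param grid the grid.
#' @return chlorophyll field, ug dm^-3.
#' @export
abundance_to_chl <- function(b, curve, grid) {
  if (any(b < 0, na.rm = TRUE)) stop("negative abundance")
  content <- if (is.data.frame(curve))
    stats::approx(curve$depth_m, curve$fg_per_cell, xout = grid$z_nodes, rule = 2)$y
  else rep(curve, grid$nz)
  if (any(content <= 0)) stop("cellular content must be positive")
  b * matrix(content, grid$nx, grid$nz, byrow = TRUE) * 1e-12
}

#' Nano/micro-phytoplankton chlorophyll contribution
#'
#' The modelled picophytoplankton account for only part of the total
#' chlorophyll; the remainder (nano- and micro-phytoplankton, > 3 um) is
#' estimated per station as `fraction` (default 20%) of the station's
#' depth-mean fluorescence chlorophyll within the upper (MAW) layer, then
#' linearly interpolated along x (constant beyond the end stations). The
#' result is applied uniformly over depth within the MAW.
#'
#' @param stations a [hydro_profiles()] (>= 2 stations with `chl`).
#' @param grid the grid.
#' @param fraction fraction of total chlorophyll attributed to larger
#'   phytoplankton (default 0.20).
#' @param maw_depth lower MAW boundary, m (scalar).
#' @return delta_b per x node, ug dm^-3.
#' @export
nano_micro_contribution <- function(stations, grid, fraction = 0.20, maw_depth = 100) {
  if (length(stations) < 2L) stop("need >= 2 stations with fluorescence data")
  per_station <- vapply(stations, function(s) {
    sel <- s$depth <= maw_depth
    if (!any(sel)) sel <- seq_along(s$depth) <= 1L
    if (!length(s$chl)) stop("no fluorescence data at station ", s$station_id)
    fraction * mean(s$chl[sel])
  }, numeric(1))
  xs <- vapply(stations, `[[`, numeric(1), "x")
  stats::approx(xs, per_station, xout = grid$x_nodes, rule = 2)$y
}

#' Total chlorophyll map
#'
#' Sums the per-population chlorophyll a / divinyl chlorophyll a fields and
#' adds the nano/micro contribution uniformly over the MAW layer.
#'
#' @param chl_per_pop list of chlorophyll fields, ug dm^-3.
#' @param delta_b per-x nano/micro contribution (from
#'   [nano_micro_contribution()]), or NULL for none.
#' @param grid the grid.
#' @param maw_depth lower MAW boundary, m.
#' @return object of class `chl_map`: `per_pop` (list), `delta_b`, `total`
#'   (nx by nz), `maw_mask`.
#' @export
total_chl_map <- function(chl_per_pop, delta_b = NULL, grid, maw_depth = 100) {
  total <- Reduce(`+`, chl_per_pop)
  maw_mask <- grid$wet & matrix(grid$z_nodes <= maw_depth, grid$nx, grid$nz, byrow = TRUE)
  if (!is.null(delta_b)) {
    total <- total + matrix(delta_b, grid$nx, grid$nz) * maw_mask
  } else {
    delta_b <- rep(0, grid$nx)
  }
  structure(list(per_pop = chl_per_pop, delta_b = delta_b,
                 total = total * grid$wet, maw_mask = maw_mask,
                 maw_depth = maw_depth),
            class = "chl_map")
}

#' Chlorophyll map from a model state
#'
#' Convenience wrapper: converts each population's steady abundance with its
#' content curve and assembles the total map (optionally with the
#' station-derived nano/micro contribution).
#'
#' @param state a `transect_state`.
#' @param pops `plankton_community` (content curves are taken from each
#'   population's `content`).
#' @param grid the grid.
#' @param stations optional [hydro_profiles()] for the nano/micro term.
#' @param fraction,maw_depth passed to [nano_micro_contribution()].
#' @return a `chl_map`.
#' @export
convert_chl <- function(state, pops, grid, stations = NULL,
                        fraction = 0.20, maw_depth = 100) {
  chl <- lapply(seq_along(pops), function(i)
    abundance_to_chl(state$b[[i]], pops[[i]]$content, grid))
  names(chl) <- names(pops)
  delta_b <- if (!is.null(stations))
    nano_micro_contribution(stations, grid, fraction, maw_depth)
  total_chl_map(chl, delta_b, grid, maw_depth)
}
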