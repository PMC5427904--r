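#' Extract a vertical profile from a gridded field
#'
#' Returns the wet values of the x column nearest to `x_station` (ties break
#' toward smaller x).
#'
#' @param field nx by nz matrix.
#' @param grid the grid.
#' @param x_station position along the transect, m.
#' @return data frame `depth`, `value`.
#' @export
extract_profile <- function(field, grid, x_station) {
  if (x_station < 0 || x_station > grid$geometry$x_l)
    stop("x_station outside the domain")
  d <- abs(grid$x_nodes - x_station)
  j <- which(d <= min(d) + 1e-9)[1L]          # tie toward smaller x
  k <- seq_len(grid$nwet[j])
  data.frame(depth = grid$z_nodes[k], value = field[j, k])
}

#' Pearson chi-square goodness of fit between profiles
#'
#' chi2 = sum_k (obs_k - mod_k)^2 / mod_k over the observed depths, with the
#' model profile linearly interpolated to the observation depths. Points
#' where the interpolated model falls at or below `floor` are excluded and
#' counted. The model values serve as the expected-value denominator
#' (Pearson form).
#'
#' @param model data frame `depth`, `value` (model profile).
#' @param observed data frame `depth`, `value` (observations).
#' @param n_free_params number of free parameters consumed by the fit.
#' @param floor exclusion threshold for near-zero model values.
#' @param station_id optional label.
#' @return object of class `fit_report`: `chi2`, `dof`, `chi2_red`,
#'   `n_points`, `n_excluded`, `expected_total`, `station_id`.
#' @export
chi_square <- function(model, observed, n_free_params = 0, floor = 1e-9,
                       station_id = NA_character_) {
  mod <- stats::approx(model$depth, model$value, xout = observed$depth, rule = 2)$y
  use <- mod > floor & is.finite(observed$value)
  n_used <- sum(use)
  if (n_used <= n_free_params)
    stop("too few usable points (", n_used, ") for ", n_free_params, " free parameters")
  chi2 <- sum((observed$value[use] - mod[use])^2 / mod[use])
  dof <- n_used - n_free_params
  structure(list(chi2 = chi2, dof = dof, chi2_red = chi2 / dof,
                 n_points = n_used, n_excluded = sum(!use),
                 expected_total = sum(mod[use]), station_id = station_id),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit %s: chi2 = %.4g on %d dof (chi2_red = %.4g, %d points, %d excluded)\n",
              x$station_id, x$chi2, x$dof, x$chi2_red, x$n_points, x$n_excluded))
  invisible(x)
}

#' Model-selection statistics for reduced vs full fits
#'
#' A chi-square-based Akaike score AIC = sum(chi2) + 2k is computed for each
#' model variant, and Cohen's effect size w = sqrt(chi2 / N) per station,
#' with N the sum of the expected (model) values used in the fit.
#'
#' @param fit_reduced,fit_full lists of [chi_square()] reports over the same
#'   stations (same order).
#' @param k_reduced,k_full numbers of free parameters of each variant.
#' @return list `AIC_reduced`, `AIC_full`, `cohen_w` (data frame per
#'   station with both variants).
#' @export
model_selection_stats <- function(fit_reduced, fit_full, k_reduced, k_full) {
  ids_r <- unname(vapply(fit_reduced, `[[`, character(1), "station_id"))
  ids_f <- unname(vapply(fit_full, `[[`, character(1), "station_id"))
  if (!identical(ids_r, ids_f)) stop("mismatched stations between fits")
  chi_r <- vapply(fit_reduced, `[[`, numeric(1), "chi2")
  chi_f <- vapply(fit_full, `[[`, numeric(1), "chi2")
  w <- function(fit) sqrt(fit$chi2 / max(fit$expected_total, 1e-300))
  data.frame(station_id = ids_r,
             w_reduced = vapply(fit_reduced, w, numeric(1)),
             w_full = vapply(fit_full, w, numeric(1))) -> cw
  list(AIC_reduced = sum(chi_r) + 2 * k_reduced,
       AIC_full = sum(chi_f) + 2 * k_full,
       cohen_w = cw)
}

#' Deep chlorophyll maximum metrics of a vertical profile
#'
#' Magnitude is the raw profile maximum; depth is refined by a parabola
#' through the three points around the maximum; width is the full width at
#' half maximum above the deep-background level (the profile value at the
#' deepest point), with half-height crossings located by linear
#' interpolation. Profiles whose maximum sits at the first or last depth
#' carry no interior DCM and are flagged rather than treated as an error.
#'
#' @param profile data frame `depth`, `value` (>= 3 points).
#' @return list `has_dcm`, `magnitude`, `depth`, `width` (NA when flagged).
#' @export
dcm_metrics <- function(profile) {
  z <- profile$depth; v <- profile$value
  n <- length(z)
  if (n < 3L) stop("need at least 3 depth points")
  k <- which.max(v)
  no_dcm <- list(has_dcm = FALSE, magnitude = NA_real_, depth = NA_real_,
                 width = NA_real_)
  if (k == 1L || k == n || diff(range(v)) == 0) return(no_dcm)
  magnitude <- v[k]
  # parabolic vertex through the three points around the max
  z3 <- z[(k - 1L):(k + 1L)]; v3 <- v[(k - 1L):(k + 1L)]
  denom <- (z3[1L] - z3[2L]) * (z3[1L] - z3[3L]) * (z3[2L] - z3[3L])
  aa <- (z3[3L] * (v3[2L] - v3[1L]) + z3[2L] * (v3[1L] - v3[3L]) +
           z3[1L] * (v3[3L] - v3[2L])) / denom
  bb <- (z3[3L]^2 * (v3[1L] - v3[2L]) + z3[2L]^2 * (v3[3L] - v3[1L]) +
           z3[1L]^2 * (v3[2L] - v3[3L])) / denom
  depth <- if (aa < 0) -bb / (2 * aa) else z[k]
  background <- v[n]
  half <- background + (magnitude - background) / 2
  cross <- function(idx_before, idx_after) {
    z[idx_before] + (half - v[idx_before]) *
      (z[idx_after] - z[idx_before]) / (v[idx_after] - v[idx_before])
  }
  # shallow-side crossing: last point above the peak with value <= half
  upper <- which(v[seq_len(k)] <= half)
  z_up <- if (length(upper)) cross(max(upper), max(upper) + 1L) else z[1L]
  lower <- which(v[k:n] <= half) + k - 1L
  z_dn <- if (length(lower)) cross(min(lower), min(lower) - 1L) else z[n]
  list(has_dcm = TRUE, magnitude = magnitude, depth = depth,
       width = z_dn - z_up)
}

#' Depth-average over the upper (MAW) layer
#'
#' Arithmetic mean over the wet nodes with z <= maw_depth(x), per column.
#'
#' @param field nx by nz matrix.
#' @param grid the grid.
#' @param maw_depth lower MAW boundary, m; scalar or per x node. Must be
#'   positive and no deeper than the local column depth.
#' @return vector of per-column means.
#' @export
maw_average <- function(field, grid, maw_depth = 100) {
  if (any(maw_depth <= 0)) stop("maw_depth must be positive")
  md <- rep(maw_depth, length.out = grid$nx)
  depth_col <- grid$nwet * grid$dz
  if (any(md > depth_col + 1e-9))
    stop("maw_depth exceeds the water-column depth at some x")
  vapply(seq_len(grid$nx), function(j) {
    k <- which(grid$z_nodes <= md[j] & grid$wet[j, ])
    mean(field[j, k])
  }, numeric(1))
}

#' Station-wise statistics table for a simulation
#'
#' Computes, for each station, the chi-square fit of the modelled total
#' chlorophyll profile against the station's fluorescence profile, DCM
#' metrics of the model profile, and MAW averages of total chlorophyll and
#' phosphate.
#'
#' @param chlmap a `chl_map`.
#' @param state the steady `transect_state` (for phosphate).
#' @param grid the grid.
#' @param stations [hydro_profiles()] with observed `chl`.
#' @param n_free_params free parameters per station fit (0 for a fixed run).
#' @param maw_depth MAW depth, m (clamped per column to the local depth).
#' @return list `fits` (list of `fit_report`), `dcm` (data frame), `maw`
#'   (data frame per station).
#' @export
transect_stats <- function(chlmap, state, grid, stations, n_free_params = 0,
                           maw_depth = 100) {
  md <- pmin(maw_depth, grid$nwet * grid$dz)
  maw_chl <- maw_average(chlmap$total, grid, md)
  maw_R <- maw_average(state$R, grid, md)
  fits <- list(); dcm_rows <- list(); maw_rows <- list()
  for (s in stations) {
    prof <- extract_profile(chlmap$total, grid, s$x)
    obs <- data.frame(depth = s$depth, value = s$chl)
    fits[[s$station_id]] <- chi_square(prof, obs, n_free_params,
                                       station_id = s$station_id)
    m <- dcm_metrics(prof)
    dcm_rows[[s$station_id]] <- data.frame(
      station_id = s$station_id, x = s$x, has_dcm = m$has_dcm,
      magnitude = m$magnitude, depth = m$depth, width = m$width)
    j <- which.min(abs(grid$x_nodes - s$x))
    maw_rows[[s$station_id]] <- data.frame(
      station_id = s$station_id, x = s$x,
      maw_chl = maw_chl[j], maw_phosphate = maw_R[j])
  }
  list(fits = fits,
       dcm = do.call(rbind, dcm_rows),
       maw = do.call(rbind, maw_rows))
}
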