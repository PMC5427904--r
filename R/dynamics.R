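#' Biological parameters of one picophytoplankton population
#'
#' @param name population label.
#' @param r maximum specific growth rate, 1/h (must exceed `m`).
#' @param m specific loss rate (respiration + death + grazing), 1/h.
#' @param K_I light half-saturation, umol photons m^-2 s^-1; scalar or one
#'   value per grid x node (reduced-model form).
#' @param K_R phosphate half-saturation, mmol P m^-3; scalar or per x node.
#' @param invY cellular phosphorus quota (the nutrient content 1/Y), mmol P
#'   per cell.
#' @param eps nutrient recycling coefficient in [0, 1].
#' @param a chlorophyll-normalised absorption, (ug dm^-3)^-1 m^-1.
#' @param v_s swimming/sinking speed magnitude, m/h (>= 0).
#' @param pigment `"chl"` (chlorophyll a) or `"dvchl"` (divinyl chlorophyll a,
#'   the Prochlorococcus marker pigment).
#' @param content cellular pigment content: either a single fg/cell value or
#'   a data frame `depth_m`, `fg_per_cell` (piecewise-linear in depth).
#' @return object of class `population_params`.
#' @export
population_params <- function(name, r, m, K_I, K_R, invY, eps, a, v_s = 0,
                              pigment = c("chl", "dvchl"), content = 1) {
  pigment <- match.arg(pigment)
  if (!(r > m && m > 0)) stop(name, ": need r > m > 0")
  if (any(K_I <= 0) || any(K_R <= 0)) stop(name, ": half-saturations must be positive")
  if (invY <= 0) stop(name, ": invY must be positive")
  if (eps < 0 || eps > 1) stop(name, ": eps must lie in [0, 1]")
  if (v_s < 0) stop(name, ": v_s must be non-negative")
  if (a < 0) stop(name, ": absorption must be non-negative")
  structure(list(name = name, r = r, m = m, K_I = K_I, K_R = K_R, invY = invY,
                 eps = eps, a = a, v_s = v_s, pigment = pigment,
                 content = content),
            class = "population_params")
}

#' Default four-population community
#'
#' Literature-plausible (non-canonical) picophytoplankton parameters for an
#' oligotrophic Mediterranean summer community: Synechococcus and the
#' high-light Prochlorococcus ecotype occupy high-light/high-nutrient niches
#' near the surface and the coasts; picoeukaryotes and the low-light
#' Prochlorococcus ecotype form the deep chlorophyll maximum. Pigment
#' contents: Synechococcus fixed at 1.18 fg chl a per cell; the others use
#' piecewise-linear photoacclimation curves (content rising with depth).
#'
#' @return list of four [population_params()], class `plankton_community`.
#' @export
default_populations <- function() {
  curves <- default_conversion_curves()
  pops <- list(
    population_params("Synechococcus", r = 0.055, m = 0.012, K_I = 35, K_R = 0.035,
                      invY = 2.0e-13, eps = 0.5, a = 0.015, v_s = 0,
                      pigment = "chl", content = curves$Synechococcus),
    population_params("Prochlorococcus_HL", r = 0.050, m = 0.012, K_I = 25, K_R = 0.030,
                      invY = 1.0e-13, eps = 0.5, a = 0.015, v_s = 0,
                      pigment = "dvchl", content = curves$Prochlorococcus_HL),
    population_params("Picoeukaryotes", r = 0.050, m = 0.010, K_I = 12, K_R = 0.022,
                      invY = 2.0e-12, eps = 0.5, a = 0.016, v_s = 0.05,
                      pigment = "chl", content = curves$Picoeukaryotes),
    population_params("Prochlorococcus_LL", r = 0.042, m = 0.008, K_I = 4, K_R = 0.015,
                      invY = 1.0e-13, eps = 0.5, a = 0.015, v_s = 0.05,
                      pigment = "dvchl", content = curves$Prochlorococcus_LL))
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  class(pops) <- "plankton_community"
  pops
}

#' Michaelis-Menten resource limitation
#'
#' @param r maximum rate (1/h), positive.
#' @param K half-saturation constant in resource units, positive.
#' @param s resource level (>= 0); vectorised.
#' @return rate r s / (s + K), in [0, r).
#' @export
michaelis_menten <- function(r, K, s) {
  if (any(r <= 0) || any(K <= 0)) stop("r and K must be positive")
  if (any(s < 0, na.rm = TRUE)) stop("negative resource level")
  r * s / (s + K)
}

# expand a scalar-or-per-x half-saturation into an nx-by-nz matrix
expand_K <- function(K, grid) {
  if (length(K) == 1L) return(matrix(K, grid$nx, grid$nz))
  if (length(K) != grid$nx) stop("per-x half-saturation must have one value per x node")
  matrix(K, grid$nx, grid$nz)
}

#' Net specific growth rate of one population
#'
#' Liebig's law of the minimum over the two Michaelis-Menten limitation
#' terms, minus the specific loss rate: G = min(f_I(I), f_R(R)) - m.
#'
#' @param I irradiance field (nx by nz).
#' @param R phosphate field (nx by nz).
#' @param pop a [population_params()].
#' @param grid the grid (needed when K_I/K_R vary with x).
#' @return list with `G`, and the gross rate `gross = min(f_I, f_R)`.
#' @export
net_growth_rate <- function(I, R, pop, grid) {
  if (!all(dim(I) == dim(R))) stop("I and R must share the grid shape")
  f_I <- michaelis_menten(pop$r, expand_K(pop$K_I, grid), pmax(I, 0))
  f_R <- michaelis_menten(pop$r, expand_K(pop$K_R, grid), pmax(R, 0))
  gross <- pmin(f_I, f_R)
  list(G = gross - pop$m, gross = gross, f_I = f_I, f_R = f_R)
}

#' Lambert-Beer light field with self-shading
#'
#' I(x, z) = I_in(x) exp(-int_0^z [sum_i a_i chl_i + a_bg] dZ), the
#' attenuation integral evaluated by the trapezoidal rule over the
#' node-centred z axis (with a half-cell from the surface to the first node,
#' exact for depth-constant attenuation).
#'
#' @param chl_per_pop list of chlorophyll fields, ug dm^-3 (nx by nz).
#' @param I_in surface irradiance per x node.
#' @param a chlorophyll-normalised absorption per population.
#' @param a_bg background turbidity, 1/m.
#' @param grid the grid.
#' @return irradiance field (nx by nz), same units as `I_in`.
#' @export
light_field <- function(chl_per_pop, I_in, a, a_bg, grid) {
  nx <- grid$nx; nz <- grid$nz; dz <- grid$dz
  A <- matrix(a_bg, nx, nz)
  for (i in seq_along(chl_per_pop)) {
    ci <- chl_per_pop[[i]]
    if (any(ci < 0, na.rm = TRUE)) stop("negative chlorophyll")
    A <- A + a[i] * ci
  }
  half <- 0.5 * dz * A[, 1L]
  if (nz > 1L) {
    inc <- 0.5 * dz * (A[, -nz, drop = FALSE] + A[, -1L, drop = FALSE])
    cs <- inc
    if (nz > 2L) for (k in 2:(nz - 1L)) cs[, k] <- cs[, k - 1L] + inc[, k]
    cum <- cbind(0, cs)
  } else {
    cum <- matrix(0, nx, 1L)
  }
  I <- I_in * exp(-(half + cum))
  I * grid$wet
}

#' Growth-gradient taxis velocity
#'
#' Vertical swimming follows the sign of the vertical gradient of the net
#' growth rate: cells sink (+v_s, downward) where dG/dz > 0, rise (-v_s)
#' where dG/dz < 0, and stay put inside a small deadband around zero. The
#' velocity is forced to zero on surface and bottom nodes so the taxis flux
#' is consistent with the closed biomass boundaries.
#'
#' @param G net growth rate field (nx by nz), 1/h.
#' @param v_s swim speed magnitude, m/h (>= 0).
#' @param grid the grid.
#' @param deadband gradient magnitude treated as zero (1/h per m).
#' @return velocity field, m/h, positive downward.
#' @export
taxis_velocity <- function(G, v_s, grid, deadband = 1e-12) {
  if (v_s < 0) stop("v_s must be non-negative")
  if (v_s == 0) return(matrix(0, grid$nx, grid$nz))
  dG <- ddz_masked(G, grid)
  v <- v_s * ((dG > deadband) - (dG < -deadband))
  # zero on surface and bottom nodes
  v[, 1L] <- 0
  v[cbind(seq_len(grid$nx), grid$nwet)] <- 0
  v * grid$wet
}

#' Initial model state
#'
#' @param grid the grid.
#' @param b0 initial abundance per population (scalar each, cells/m^3), a
#'   uniform low concentration by default.
#' @param R0 initial phosphate: matrix, or NULL to use the interpolated
#'   observed field `env$R_init`.
#' @param env optional `env_fields` supplying `R_init`.
#' @param n_pops number of populations when `b0` is scalar.
#' @return object of class `transect_state` with `b` (list of matrices),
#'   `R`, `t` (h).
#' @export
init_state <- function(grid, b0 = 1e8, R0 = NULL, env = NULL, n_pops = 4L) {
  if (length(b0) == 1L) b0 <- rep(b0, n_pops)
  b <- lapply(b0, function(v) wet_field(grid) + v * grid$wet)
  if (is.null(R0)) {
    if (is.null(env)) stop("supply R0 or env")
    R0 <- env$R_init
  }
  if (length(R0) == 1L) R0 <- matrix(R0, grid$nx, grid$nz)
  structure(list(b = b, R = R0 * grid$wet, t = 0), class = "transect_state")
}

# chlorophyll fields (ug/dm^3) from abundances, given per-z content vectors
chl_fields <- function(b, content_z_list, grid) {
  lapply(seq_along(b), function(i)
    b[[i]] * matrix(content_z_list[[i]], grid$nx, grid$nz, byrow = TRUE) * 1e-12)
}

# evaluate a population's content curve on the grid z axis
content_on_grid <- function(pop, z_nodes) {
  if (is.data.frame(pop$content))
    stats::approx(pop$content$depth_m, pop$content$fg_per_cell,
                  xout = z_nodes, rule = 2)$y
  else rep(pop$content, length(z_nodes))
}

#' Model right-hand side (tendencies of abundances and phosphate)
#'
#' Evaluates, on the staircase grid, the coupled tendencies
#' db_i/dt = b_i G_i + d/dz(D_v db_i/dz) + d/dx(D_h db_i/dx)
#'           - d/dx(v_h b_i) - d/dz(v_i b_i)
#' dR/dt   = -sum_i b_i invY_i min(f_I, f_R)
#'           + d/dz(D_v dR/dz) + d/dx(D_h dR/dx) - d/dx(v_h R)
#'           + sum_i eps_i m_i invY_i b_i
#' with the light field recomputed from the instantaneous chlorophyll.
#' Biomass boundaries are closed (zero total flux through every boundary
#' face); phosphate has zero surface gradient, Dirichlet values on every
#' bottom face of the staircase and on both lateral walls (or fully closed
#' boundaries when `env$nutrient_bc == "closed"`).
#'
#' Diffusion is centred-in-space; advection and taxis use third-order
#' upwind-biased flux reconstruction with first-order fallback where the
#' stencil leaves the wet region.
#'
#' @param state a [init_state()] state.
#' @param env an `env_fields` object.
#' @param pops a `plankton_community`.
#' @param grid the grid.
#' @return list with `db` (list of matrices, cells m^-3 h^-1), `dR`
#'   (mmol P m^-3 h^-1) and diagnostic fields `I`, `G` (list), `chl` (list).
#' @export
rhs <- function(state, env, pops, grid) {
  np <- length(pops)
  for (i in seq_len(np))
    if (any(!is.finite(state$b[[i]][grid$wet])))
      stop("non-finite abundance in population ", i)
  if (any(!is.finite(state$R[grid$wet]))) stop("non-finite phosphate field")

  content <- lapply(pops, content_on_grid, z_nodes = grid$z_nodes)
  chl <- chl_fields(state$b, content, grid)
  a_vec <- vapply(pops, `[[`, numeric(1), "a")
  I <- light_field(chl, env$I_in, a_vec, env$a_bg, grid)

  Dv <- env$D_v * 3600          # m^2/s -> m^2/h
  vh <- env$v_h * 3600          # m/s   -> m/h
  Dh <- env$D_h * 3600

  db <- vector("list", np)
  G_list <- vector("list", np)
  uptake <- matrix(0, grid$nx, grid$nz)
  recycle <- matrix(0, grid$nx, grid$nz)
  for (i in seq_len(np)) {
    p <- pops[[i]]
    gr <- net_growth_rate(I, state$R, p, grid)
    G_list[[i]] <- gr$G * grid$wet
    vi <- taxis_velocity(gr$G, p$v_s, grid)
    bi <- state$b[[i]]
    db[[i]] <- bi * G_list[[i]] +
      mdiff_z(bi, Dv, grid) + mdiff_x(bi, Dh, grid) -
      madv_x(bi, vh, grid) - madv_z(bi, vi, grid)
    uptake <- uptake + bi * p$invY * gr$gross
    recycle <- recycle + p$eps * p$m * p$invY * bi
  }

  # "dirichlet": observed phosphate pinned at bottom and lateral walls;
  # "bottom": bottom only (single-column runs); "closed": conservation harness
  dir_bottom <- env$nutrient_bc %in% c("dirichlet", "bottom")
  dir_lateral <- identical(env$nutrient_bc, "dirichlet")
  dR <- -uptake + recycle +
    mdiff_z(state$R, Dv, grid,
            dirichlet_bottom = if (dir_bottom) env$R_in_bottom) +
    mdiff_x(state$R, Dh, grid,
            dirichlet_west = if (dir_lateral) env$R_in_west,
            dirichlet_east = if (dir_lateral) env$R_in_east) -
    madv_x(state$R, vh, grid,
           lateral = if (dir_lateral) list(R_in_west = env$R_in_west,
                                           R_in_east = env$R_in_east))

  list(db = db, dR = dR * grid$wet, I = I, G = G_list, chl = chl)
}
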