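#' Solver settings
#'
#' @param dt time step, h (default 0.05).
#' @param t_max maximum integration time, h (default 2e4).
#' @param steady_tol relative L1 change of all prognostic fields per 100 h
#'   below which the run is declared stationary (default 1e-6).
#' @param check_every_h interval between convergence checks, h (default 100).
#' @param log_every steps between diagnostic log records (0 = off).
#' @export
solver_settings <- function(dt = 0.05, t_max = 2e4, steady_tol = 1e-6,
                            check_every_h = 100, log_every = 0) {
  stopifnot(dt > 0, t_max > 0, steady_tol > 0, check_every_h > 0)
  list(dt = dt, t_max = t_max, steady_tol = steady_tol,
       check_every_h = check_every_h, log_every = log_every)
}

#' Centred-in-space diffusion operator (1D)
#'
#' Second-order divergence of the diffusive flux on a uniform 1D axis with
#' face diffusivities from arithmetic means of the adjacent nodes:
#' [D_{j+1/2}(f_{j+1}-f_j) - D_{j-1/2}(f_j-f_{j-1})]/ds^2. End faces are
#' closed (no flux). Exact (zero) for a linear field with constant D.
#'
#' @param f field values.
#' @param D diffusivity per node (positive), scalar or vector.
#' @param ds grid spacing.
#' @return tendency vector, same length as `f`.
#' @export
diffuse_centered <- function(f, D, ds) {
  n <- length(f)
  if (length(D) == 1L) D <- rep(D, n)
  if (any(D <= 0)) stop("D must be positive")
  if (n < 2L) return(0 * f)
  Dface <- 0.5 * (D[-n] + D[-1L])
  Fl <- Dface * (f[-1L] - f[-n]) / ds
  (c(Fl, 0) - c(0, Fl)) / ds
}

#' Third-order upwind-biased advection operator (1D)
#'
#' Flux-form divergence d(v f)/ds with kappa = 1/3 upwind-biased face
#' reconstruction chosen by the face velocity sign; first-order upwind
#' fallback where the stencil leaves the domain (closed variant). The
#' periodic variant wraps the stencil and is used for convergence studies.
#'
#' @param f field values.
#' @param v velocity per node (same sign convention as the axis), scalar or
#'   vector.
#' @param ds grid spacing.
#' @param boundary `"closed"` (zero flux through end faces) or `"periodic"`.
#' @return tendency vector d(v f)/ds.
#' @export
advect_upwind3 <- function(f, v, ds, boundary = c("closed", "periodic")) {
  boundary <- match.arg(boundary)
  n <- length(f)
  if (length(v) == 1L) v <- rep(v, n)
  if (length(v) != n) stop("f and v must have the same length")
  if (n < 2L) return(0 * f)
  if (boundary == "periodic") {
    jm <- c(n, seq_len(n - 1L)); jp <- c(seq_len(n - 1L) + 1L, 1L)
    jp2 <- jp[jp]
    vface <- 0.5 * (v + v[jp])
    pos <- vface >= 0
    face <- ifelse(pos, (2 * f[jp] + 5 * f - f[jm]) / 6,
                   (2 * f + 5 * f[jp] - f[jp2]) / 6)
    Fl <- vface * face                   # flux through face j+1/2, j = 1..n
    return((Fl - Fl[c(n, seq_len(n - 1L))]) / ds)
  }
  j <- seq_len(n - 1L)
  vface <- 0.5 * (v[j] + v[j + 1L])
  fj <- f[j]; fjp <- f[j + 1L]
  fm <- c(0, f[seq_len(n - 2L)]); has_m <- c(FALSE, rep(TRUE, n - 2L))
  fp2 <- c(if (n > 2L) f[3:n], 0); has_p2 <- c(rep(TRUE, n - 2L), FALSE)
  pos <- vface >= 0
  face <- ifelse(pos, ifelse(has_m, (2 * fjp + 5 * fj - fm) / 6, fj),
                 ifelse(has_p2, (2 * fj + 5 * fjp - fp2) / 6, fjp))
  Fl <- vface * face
  (c(Fl, 0) - c(0, Fl)) / ds
}

#' Explicit-scheme stability report
#'
#' Conservative bounds for the forward-Euler update: the diffusive number
#' max(D_v dt/dz^2, D_h dt/dx^2) must stay below 0.25 and the advective
#' number max(|v_h| dt/dx, (|v_s|) dt/dz) below 0.5.
#'
#' @param env `env_fields`.
#' @param pops `plankton_community`.
#' @param settings [solver_settings()].
#' @param grid the grid.
#' @return list `diffusive_number`, `advective_number`, `pass`.
#' @export
cfl_check <- function(env, pops, settings, grid) {
  dt_s <- settings$dt * 3600
  w <- grid$wet
  diff_n <- max(max(env$D_v[w]) * dt_s / grid$dz^2,
                max(env$D_h) * dt_s / grid$dx^2)
  vs_max <- max(vapply(pops, `[[`, numeric(1), "v_s")) / 3600  # m/h -> m/s
  adv_n <- max(max(abs(env$v_h[w])) * dt_s / grid$dx,
               vs_max * dt_s / grid$dz)
  list(diffusive_number = diff_n, advective_number = adv_n,
       pass = diff_n <= 0.25 && adv_n <= 0.5)
}

#' Pick a stable time step
#'
#' Largest dt (h) meeting the [cfl_check()] bounds times a safety factor,
#' capped at `dt_max`.
#'
#' @param env,pops,grid as in [cfl_check()].
#' @param safety multiplicative margin (default 0.8).
#' @param dt_max upper cap in h (default 0.5).
#' @export
suggest_dt <- function(env, pops, grid, safety = 0.8, dt_max = 0.5) {
  w <- grid$wet
  lim_diff <- 0.25 / max(max(env$D_v[w]) / grid$dz^2,
                         max(env$D_h) / grid$dx^2)
  vs_max <- max(vapply(pops, `[[`, numeric(1), "v_s")) / 3600
  vmax <- max(max(abs(env$v_h[w])) / grid$dx, vs_max / grid$dz, 1e-30)
  lim_adv <- 0.5 / vmax
  min(safety * min(lim_diff, lim_adv) / 3600, dt_max)
}

#' One forward-Euler step
#'
#' Advances the state by `dt` using [rhs()]; undershoots below zero are
#' clipped to zero and the clipped mass is accumulated in
#' `state$clipped_mass` (cells and mmol P, area-weighted).
#'
#' @param state,env,pops,grid model inputs.
#' @param dt time step, h.
#' @return updated `transect_state`.
#' @export
step <- function(state, env, pops, grid, dt) {
  tend <- rhs(state, env, pops, grid)
  cellA <- grid$dx * grid$dz
  clipped <- if (is.null(state$clipped_mass)) 0 else state$clipped_mass
  for (i in seq_along(state$b)) {
    bn <- state$b[[i]] + dt * tend$db[[i]]
    neg <- bn < 0
    if (any(neg)) {
      clipped <- clipped + sum(-bn[neg]) * cellA
      bn[neg] <- 0
    }
    state$b[[i]] <- bn
  }
  Rn <- state$R + dt * tend$dR
  neg <- Rn < 0
  if (any(neg)) {
    clipped <- clipped + sum(-Rn[neg]) * cellA
    Rn[neg] <- 0
  }
  state$R <- Rn
  state$t <- state$t + dt
  state$clipped_mass <- clipped
  bad <- any(!is.finite(state$R[grid$wet])) ||
    any(vapply(state$b, function(b) any(!is.finite(b[grid$wet])), logical(1)))
  if (bad) stop("numerical blow-up at t = ", signif(state$t, 6), " h")
  state
}

state_norm_l1 <- function(state, grid) {
  w <- grid$wet
  sum(vapply(state$b, function(b) sum(abs(b[w])), numeric(1))) + sum(abs(state$R[w]))
}

state_diff_l1 <- function(s1, s0, grid) {
  w <- grid$wet
  sum(vapply(seq_along(s1$b), function(i) sum(abs(s1$b[[i]][w] - s0$b[[i]][w])),
             numeric(1))) + sum(abs(s1$R[w] - s0$R[w]))
}

#' Integrate to the stationary solution
#'
#' Repeats [step()] until the relative L1 change of all prognostic fields
#' per 100 h drops below `steady_tol`, or `t_max` is reached. The run
#' refuses to start on a failed [cfl_check()] unless `force = TRUE`.
#'
#' @param state0 initial state.
#' @param env,pops,grid model inputs.
#' @param settings [solver_settings()].
#' @param force run despite a failed stability check.
#' @return list `state`, `converged`, `t_final`, `history` (data frame of
#'   check times and relative change norms), `cfl`.
#' @export
integrate_to_steady <- function(state0, env, pops, grid,
                                settings = solver_settings(), force = FALSE) {
  cfl <- cfl_check(env, pops, settings, grid)
  if (!cfl$pass && !force)
    stop(sprintf("stability check failed (diffusive %.3g, advective %.3g); reduce dt or pass force = TRUE",
                 cfl$diffusive_number, cfl$advective_number))
  dt <- settings$dt
  n_check <- max(1L, as.integer(round(settings$check_every_h / dt)))
  state <- state0
  prev <- state
  converged <- FALSE
  hist_t <- numeric(0); hist_d <- numeric(0)
  while (state$t < settings$t_max - 1e-9) {
    for (s in seq_len(n_check)) {
      if (state$t >= settings$t_max - 1e-9) break
      state <- step(state, env, pops, grid, dt)
    }
    scale_h <- (state$t - prev$t) / 100      # normalise to per-100 h
    d <- state_diff_l1(state, prev, grid) / max(state_norm_l1(state, grid), 1e-300)
    d <- if (scale_h > 0) d / scale_h else d
    hist_t <- c(hist_t, state$t); hist_d <- c(hist_d, d)
    if (d < settings$steady_tol) { converged <- TRUE; break }
    prev <- state
  }
  list(state = state, converged = converged, t_final = state$t,
       history = data.frame(t = hist_t, rel_change = hist_d), cfl = cfl)
}
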