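# Shared builders for small test models.

# rectangular or staircase grid
make_test_grid <- function(widths_km = 10, depths_m = 10, dx = 5000, dz = 2) {
  ends <- cumsum(widths_km) * 1000
  starts <- c(0, ends[-length(ends)])
  build_grid(domain_geometry(
    data.frame(x_start = starts, x_end = ends, z_bottom = depths_m),
    dx = dx, dz = dz))
}

# hand-assembled environment on a given grid
make_test_env <- function(grid, D_v = 1e-4, D_h = 50, v_h = 0, I_in = 600,
                          a_bg = 0.045, R_in = 0.1, R_init = R_in,
                          nutrient_bc = "closed") {
  nx <- grid$nx; nz <- grid$nz
  asmat <- function(v) if (is.matrix(v)) v else matrix(v, nx, nz)
  structure(list(D_v = asmat(D_v), D_h = rep(D_h, length.out = nx),
                 v_h = asmat(v_h), I_in = rep(I_in, length.out = nx),
                 a_bg = a_bg,
                 R_in_bottom = rep(R_in, length.out = nx),
                 R_in_west = rep(R_in, length.out = nz),
                 R_in_east = rep(R_in, length.out = nz),
                 R_init = asmat(R_init), nutrient_bc = nutrient_bc),
            class = "env_fields")
}

single_pop <- function(r = 0.06, m = 0.02, K_I = 20, K_R = 0.025,
                       invY = 1e-13, eps = 0.5, a = 0.016, v_s = 0,
                       content = 30) {
  p <- population_params("test_pop", r = r, m = m, K_I = K_I, K_R = K_R,
                         invY = invY, eps = eps, a = a, v_s = v_s,
                         content = content)
  structure(list(test_pop = p), class = "plankton_community")
}

# population whose net growth is identically zero: light-limited everywhere
# at exactly the loss rate (no absorption, so I is depth-uniform), nutrient
# never limiting, full recycling
zero_growth_pop <- function(I_in = 600, r = 0.04, m = 0.02) {
  single_pop(r = r, m = m, K_I = I_in * (r - m) / m, K_R = 1e-6,
             eps = 1, a = 0, v_s = 0.1, content = 1.18)
}

# straight-line reimplementation of the coupled tendencies: nested loops,
# scalar arithmetic, no shared code with the vectorised operators.
oracle_rhs <- function(state, env, pops, grid) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx; dz <- grid$dz
  wet <- grid$wet
  npop <- length(pops)
  content <- lapply(pops, function(p) {
    if (is.data.frame(p$content))
      stats::approx(p$content$depth_m, p$content$fg_per_cell,
                    xout = grid$z_nodes, rule = 2)$y
    else rep(p$content, nz)
  })
  Dv <- env$D_v * 3600; Dh <- env$D_h * 3600; vh <- env$v_h * 3600

  I <- matrix(0, nx, nz)
  for (j in seq_len(nx)) {
    cum <- 0; Aprev <- 0
    for (k in seq_len(nz)) {
      A <- env$a_bg
      for (i in seq_len(npop))
        A <- A + pops[[i]]$a * state$b[[i]][j, k] * content[[i]][k] * 1e-12
      cum <- if (k == 1L) A * dz / 2 else cum + (Aprev + A) * dz / 2
      Aprev <- A
      if (wet[j, k]) I[j, k] <- env$I_in[j] * exp(-cum)
    }
  }

  face_val <- function(donor, dup, ddn, ok) {
    if (!ok || ddn == 0) return(donor)
    r <- dup / ddn
    phi <- max(0, min(2 * r, (2 + r) / 3, 2))
    donor + 0.5 * phi * ddn
  }
  adv_flux_x <- function(f, v, j, k) {        # flux through face (j+1/2, k)
    if (!wet[j, k] || !wet[j + 1L, k]) return(0)
    vf <- 0.5 * (v[j, k] + v[j + 1L, k])
    if (vf >= 0) {
      ok <- j > 1L && wet[j - 1L, k]
      fv <- face_val(f[j, k], if (ok) f[j, k] - f[j - 1L, k] else 0,
                     f[j + 1L, k] - f[j, k], ok)
    } else {
      ok <- j + 2L <= nx && wet[j + 2L, k]
      fv <- face_val(f[j + 1L, k], if (ok) f[j + 1L, k] - f[j + 2L, k] else 0,
                     f[j, k] - f[j + 1L, k], ok)
    }
    vf * fv
  }
  adv_flux_z <- function(f, v, j, k) {        # flux through face (j, k+1/2)
    if (!wet[j, k] || !wet[j, k + 1L]) return(0)
    vf <- 0.5 * (v[j, k] + v[j, k + 1L])
    if (vf >= 0) {
      ok <- k > 1L && wet[j, k - 1L]
      fv <- face_val(f[j, k], if (ok) f[j, k] - f[j, k - 1L] else 0,
                     f[j, k + 1L] - f[j, k], ok)
    } else {
      ok <- k + 2L <= nz && wet[j, k + 2L]
      fv <- face_val(f[j, k + 1L], if (ok) f[j, k + 1L] - f[j, k + 2L] else 0,
                     f[j, k] - f[j, k + 1L], ok)
    }
    vf * fv
  }

  db <- lapply(seq_len(npop), function(i) matrix(0, nx, nz))
  dR <- matrix(0, nx, nz)
  uptake <- matrix(0, nx, nz); recycle <- matrix(0, nx, nz)
  mm <- function(r, K, s) r * s / (s + K)

  for (i in seq_len(npop)) {
    p <- pops[[i]]
    KI <- if (length(p$K_I) > 1L) p$K_I else rep(p$K_I, nx)
    KR <- if (length(p$K_R) > 1L) p$K_R else rep(p$K_R, nx)
    G <- matrix(0, nx, nz); gross <- matrix(0, nx, nz)
    for (j in seq_len(nx)) for (k in seq_len(nz)) {
      fI <- mm(p$r, KI[j], max(I[j, k], 0))
      fR <- mm(p$r, KR[j], max(state$R[j, k], 0))
      gross[j, k] <- min(fI, fR)
      G[j, k] <- gross[j, k] - p$m
    }
    G <- G * wet; gross <- gross * wet
    vtax <- matrix(0, nx, nz)
    if (p$v_s > 0) {
      for (j in seq_len(nx)) for (k in seq_len(grid$nwet[j])) {
        up_ok <- k > 1L && wet[j, k - 1L]; dn_ok <- k < nz && wet[j, k + 1L]
        dG <- if (up_ok && dn_ok) (G[j, k + 1L] - G[j, k - 1L]) / (2 * dz)
        else if (dn_ok) (G[j, k + 1L] - G[j, k]) / dz
        else if (up_ok) (G[j, k] - G[j, k - 1L]) / dz else 0
        vtax[j, k] <- if (dG > 1e-12) p$v_s else if (dG < -1e-12) -p$v_s else 0
        if (k == 1L || k == grid$nwet[j]) vtax[j, k] <- 0
      }
    }
    bi <- state$b[[i]]
    for (j in seq_len(nx)) for (k in seq_len(grid$nwet[j])) {
      if (!wet[j, k]) next
      # vertical diffusion
      dif_z <- 0
      if (k < nz && wet[j, k + 1L])
        dif_z <- dif_z + 0.5 * (Dv[j, k] + Dv[j, k + 1L]) *
          (bi[j, k + 1L] - bi[j, k]) / dz / dz
      if (k > 1L && wet[j, k - 1L])
        dif_z <- dif_z - 0.5 * (Dv[j, k - 1L] + Dv[j, k]) *
          (bi[j, k] - bi[j, k - 1L]) / dz / dz
      # horizontal diffusion
      dif_x <- 0
      if (j < nx && wet[j + 1L, k])
        dif_x <- dif_x + 0.5 * (Dh[j] + Dh[j + 1L]) *
          (bi[j + 1L, k] - bi[j, k]) / dx / dx
      if (j > 1L && wet[j - 1L, k])
        dif_x <- dif_x - 0.5 * (Dh[j - 1L] + Dh[j]) *
          (bi[j, k] - bi[j - 1L, k]) / dx / dx
      adv_x <- ((if (j < nx) adv_flux_x(bi, vh, j, k) else 0) -
                  (if (j > 1L) adv_flux_x(bi, vh, j - 1L, k) else 0)) / dx
      adv_z <- ((if (k < nz) adv_flux_z(bi, vtax, j, k) else 0) -
                  (if (k > 1L) adv_flux_z(bi, vtax, j, k - 1L) else 0)) / dz
      db[[i]][j, k] <- bi[j, k] * G[j, k] + dif_z + dif_x - adv_x - adv_z
      uptake[j, k] <- uptake[j, k] + bi[j, k] * p$invY * gross[j, k]
      recycle[j, k] <- recycle[j, k] + p$eps * p$m * p$invY * bi[j, k]
    }
  }

  dir_bottom <- env$nutrient_bc %in% c("dirichlet", "bottom")
  dir_lateral <- identical(env$nutrient_bc, "dirichlet")
  R <- state$R
  for (j in seq_len(nx)) for (k in seq_len(grid$nwet[j])) {
    dif_z <- 0
    if (k < nz && wet[j, k + 1L])
      dif_z <- dif_z + 0.5 * (Dv[j, k] + Dv[j, k + 1L]) * (R[j, k + 1L] - R[j, k]) / dz / dz
    if (k > 1L && wet[j, k - 1L])
      dif_z <- dif_z - 0.5 * (Dv[j, k - 1L] + Dv[j, k]) * (R[j, k] - R[j, k - 1L]) / dz / dz
    if (dir_bottom && k == grid$nwet[j])
      dif_z <- dif_z + 2 * Dv[j, k] * (env$R_in_bottom[j] - R[j, k]) / dz^2
    dif_x <- 0
    if (j < nx && wet[j + 1L, k])
      dif_x <- dif_x + 0.5 * (Dh[j] + Dh[j + 1L]) * (R[j + 1L, k] - R[j, k]) / dx / dx
    if (j > 1L && wet[j - 1L, k])
      dif_x <- dif_x - 0.5 * (Dh[j - 1L] + Dh[j]) * (R[j, k] - R[j - 1L, k]) / dx / dx
    if (dir_lateral && j == 1L)
      dif_x <- dif_x + 2 * Dh[1L] * (env$R_in_west[k] - R[1L, k]) / dx^2
    if (dir_lateral && j == nx)
      dif_x <- dif_x + 2 * Dh[nx] * (env$R_in_east[k] - R[nx, k]) / dx^2
    adv_x <- ((if (j < nx) adv_flux_x(R, vh, j, k) else 0) -
                (if (j > 1L) adv_flux_x(R, vh, j - 1L, k) else 0)) / dx
    if (dir_lateral && j == 1L) {
      vw <- vh[1L, k]
      adv_x <- adv_x - vw * (if (vw > 0) env$R_in_west[k] else R[1L, k]) / dx
    }
    if (dir_lateral && j == nx) {
      ve <- vh[nx, k]
      adv_x <- adv_x + ve * (if (ve < 0) env$R_in_east[k] else R[nx, k]) / dx
    }
    dR[j, k] <- -uptake[j, k] + recycle[j, k] + dif_z + dif_x - adv_x
  }
  list(db = db, dR = dR, I = I)
}

# forward-Euler update mirroring step(), scalar loops
oracle_step <- function(state, env, pops, grid, dt) {
  td <- oracle_rhs(state, env, pops, grid)
  for (i in seq_along(state$b))
    state$b[[i]] <- pmax(state$b[[i]] + dt * td$db[[i]], 0)
  state$R <- pmax(state$R + dt * td$dR, 0)
  state$t <- state$t + dt
  state
}

rel_diff <- function(a, b) {
  scale <- max(abs(a), abs(b), 1e-300)
  abs(a - b) / scale
}
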