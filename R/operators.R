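# Masked flux-form finite-difference operators on the staircase grid.
# All operate on nx-by-nz matrices whose dry entries are zero, and return
# tendencies that are zero on dry nodes. Faces between a wet and a dry (or
# out-of-domain) node are closed: the flux through them is identically zero,
# so closed-boundary transport telescopes to exact discrete conservation.

# divergence of vertical diffusive flux d/dz (D df/dz); optional Dirichlet
# value applied at the bottom face of every column via a ghost value.
mdiff_z <- function(f, D, grid, dirichlet_bottom = NULL) {
  nx <- grid$nx; nz <- grid$nz; dz <- grid$dz
  tend <- matrix(0, nx, nz)
  if (nz > 1L) {
    Dface <- 0.5 * (D[, -nz, drop = FALSE] + D[, -1L, drop = FALSE]) * grid$open_z
    Fz <- Dface * (f[, -1L, drop = FALSE] - f[, -nz, drop = FALSE]) / dz
    tend <- (cbind(Fz, 0) - cbind(0, Fz)) / dz
  }
  if (!is.null(dirichlet_bottom)) {
    jb <- cbind(seq_len(nx), grid$nwet)
    tend[jb] <- tend[jb] + 2 * D[jb] * (dirichlet_bottom - f[jb]) / dz^2
  }
  tend * grid$wet
}

# divergence of horizontal diffusive flux d/dx (D_h df/dx); D_h per x node.
# Optional Dirichlet profiles at the west (x = 0) and east (x = x_l) walls.
mdiff_x <- function(f, D_h, grid, dirichlet_west = NULL, dirichlet_east = NULL) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx
  tend <- matrix(0, nx, nz)
  if (nx > 1L) {
    Dface <- matrix(0.5 * (D_h[-nx] + D_h[-1L]), nx - 1L, nz) * grid$open_x
    Fx <- Dface * (f[-1L, , drop = FALSE] - f[-nx, , drop = FALSE]) / dx
    tend <- (rbind(Fx, 0) - rbind(0, Fx)) / dx
  }
  if (!is.null(dirichlet_west)) {
    w <- grid$wet[1L, ]
    tend[1L, w] <- tend[1L, w] + 2 * D_h[1L] * (dirichlet_west[w] - f[1L, w]) / dx^2
  }
  if (!is.null(dirichlet_east)) {
    w <- grid$wet[nx, ]
    tend[nx, w] <- tend[nx, w] + 2 * D_h[nx] * (dirichlet_east[w] - f[nx, w]) / dx^2
  }
  tend * grid$wet
}

# third-order upwind-biased (kappa = 1/3) face reconstruction with the Koren
# flux limiter; falls back to first-order upwind where the wide stencil
# leaves the wet region. On smooth monotone data the limited faces equal the
# unlimited kappa = 1/3 values (third order retained); at sharp fronts --
# e.g. the taxis convergence layer at a thin biomass maximum, or the
# advective pile-up against a closed lateral wall -- the limiter keeps the
# scheme monotone so transported fields stay positive at CFL <= 1/2.
koren_face <- function(donor, d_up, d_down, wide_ok) {
  dd0 <- d_down == 0
  r <- d_up / (d_down + dd0)
  phi <- pmax(0, pmin(pmin(2 * r, (2 + r) / 3), 2))
  donor + 0.5 * phi * d_down * (wide_ok & !dd0)
}

upwind3_faces <- function(fm, fj, fjp, fp2, has_m, has_p2, vface) {
  face_pos <- koren_face(fj, fj - fm, fjp - fj, has_m)
  face_neg <- koren_face(fjp, fjp - fp2, fj - fjp, has_p2)
  pos <- vface >= 0
  pos * face_pos + (!pos) * face_neg
}

# divergence of horizontal advective flux d/dx (v f); closed lateral walls by
# default. `lateral` (list with R_in_west, R_in_east) opens the domain's two
# lateral boundaries with Dirichlet inflow values (first-order at the wall).
madv_x <- function(f, v, grid, lateral = NULL) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx
  tend <- matrix(0, nx, nz)
  if (nx > 1L) {
    j <- seq_len(nx - 1L)
    fj <- f[j, , drop = FALSE]; fjp <- f[j + 1L, , drop = FALSE]
    zrow <- matrix(0, 1L, nz); frow <- matrix(FALSE, 1L, nz)
    fm <- if (nx > 2L) rbind(zrow, f[seq_len(nx - 2L), , drop = FALSE]) else rbind(zrow)
    fp2 <- if (nx > 2L) rbind(f[3:nx, , drop = FALSE], zrow) else rbind(zrow)
    has_m <- if (nx > 2L) rbind(frow, grid$wet[seq_len(nx - 2L), , drop = FALSE]) else rbind(frow)
    has_p2 <- if (nx > 2L) rbind(grid$wet[3:nx, , drop = FALSE], frow) else rbind(frow)
    vface <- 0.5 * (v[j, , drop = FALSE] + v[j + 1L, , drop = FALSE])
    face <- upwind3_faces(fm, fj, fjp, fp2, has_m, has_p2, vface)
    Fx <- vface * face * grid$open_x
    tend <- (rbind(Fx, 0) - rbind(0, Fx)) / dx
  }
  if (!is.null(lateral)) {
    w <- grid$wet[1L, ]
    vw <- v[1L, ]
    Fw <- vw * ifelse(vw > 0, lateral$R_in_west, f[1L, ])
    tend[1L, w] <- tend[1L, w] - Fw[w] / dx
    w <- grid$wet[nx, ]
    ve <- v[nx, ]
    Fe <- ve * ifelse(ve < 0, lateral$R_in_east, f[nx, ])
    tend[nx, w] <- tend[nx, w] + Fe[w] / dx
  }
  tend * grid$wet
}

# divergence of vertical advective flux d/dz (v f); surface and bottom faces
# are always closed (no-flux), matching the closed-biomass boundaries.
madv_z <- function(f, v, grid) {
  nx <- grid$nx; nz <- grid$nz; dz <- grid$dz
  if (nz == 1L) return(matrix(0, nx, nz))
  k <- seq_len(nz - 1L)
  fj <- f[, k, drop = FALSE]; fjp <- f[, k + 1L, drop = FALSE]
  zcol <- matrix(0, nx, 1L); fcol <- matrix(FALSE, nx, 1L)
  fm <- if (nz > 2L) cbind(zcol, f[, seq_len(nz - 2L), drop = FALSE]) else cbind(zcol)
  fp2 <- if (nz > 2L) cbind(f[, 3:nz, drop = FALSE], zcol) else cbind(zcol)
  has_m <- if (nz > 2L) cbind(fcol, grid$wet[, seq_len(nz - 2L), drop = FALSE]) else cbind(fcol)
  has_p2 <- if (nz > 2L) cbind(grid$wet[, 3:nz, drop = FALSE], fcol) else cbind(fcol)
  vface <- 0.5 * (v[, k, drop = FALSE] + v[, k + 1L, drop = FALSE])
  face <- upwind3_faces(fm, fj, fjp, fp2, has_m, has_p2, vface)
  Fz <- vface * face * grid$open_z
  ((cbind(Fz, 0) - cbind(0, Fz)) / dz) * grid$wet
}

# centred vertical derivative of a field, one-sided at surface/bottom.
ddz_masked <- function(G, grid) {
  nx <- grid$nx; nz <- grid$nz; dz <- grid$dz
  if (nz == 1L) return(matrix(0, nx, nz))
  up <- cbind(0, G[, -nz, drop = FALSE])         # G[k-1]
  dn <- cbind(G[, -1L, drop = FALSE], 0)         # G[k+1]
  wup <- cbind(FALSE, grid$wet[, -nz, drop = FALSE])
  wdn <- cbind(grid$wet[, -1L, drop = FALSE], FALSE)
  both <- wup & wdn
  d <- both * (dn - up) / (2 * dz) +
    (wdn & !both) * (dn - G) / dz +
    (wup & !both) * (G - up) / dz
  d * grid$wet
}
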