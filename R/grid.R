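#' Describe a staircase transect domain
#'
#' The model domain is a union of contiguous rectangular subdomains along the
#' transect, each extending from the surface (z = 0, positive downward) to its
#' own bottom depth. The default scenario uses seven rectangles approximating
#' the bathymetry between the two coastal end stations.
#'
#' @param subdomains data frame with columns `x_start`, `x_end` (m along the
#'   transect, x = 0 at the Sicilian end) and `z_bottom` (m, positive).
#'   Subdomains must be contiguous, non-overlapping and ordered in x.
#' @param dx horizontal grid spacing in m (default 5000).
#' @param dz vertical grid spacing in m (default 2).
#' @return An object of class `domain_geometry`.
#' @examples
#' geo <- domain_geometry(data.frame(x_start = 0, x_end = 10000, z_bottom = 10))
#' @export
domain_geometry <- function(subdomains, dx = 5000, dz = 2) {
  stopifnot(is.data.frame(subdomains))
  req <- c("x_start", "x_end", "z_bottom")
  if (!all(req %in% names(subdomains)))
    stop("subdomains needs columns x_start, x_end, z_bottom")
  if (nrow(subdomains) < 1L) stop("empty geometry")
  if (!is.numeric(dx) || !is.numeric(dz) || dx <= 0 || dz <= 0)
    stop("dx and dz must be positive")
  sd <- subdomains[order(subdomains$x_start), req, drop = FALSE]
  if (any(sd$x_end <= sd$x_start)) stop("geometry error: subdomain with non-positive width")
  if (any(sd$z_bottom <= 0)) stop("geometry error: z_bottom must be > 0")
  if (nrow(sd) > 1L) {
    gaps <- sd$x_start[-1L] - sd$x_end[-nrow(sd)]
    if (any(abs(gaps) > 1e-6))
      stop("geometry error: subdomains must be contiguous and non-overlapping in x")
  }
  if (abs(sd$x_start[1L]) > 1e-6) stop("geometry error: first subdomain must start at x = 0")
  widths <- sd$x_end - sd$x_start
  if (any(abs(widths / dx - round(widths / dx)) > 1e-8))
    stop("geometry error: dx must divide every subdomain width")
  structure(list(subdomains = sd, x_l = sd$x_end[nrow(sd)], dx = dx, dz = dz),
            class = "domain_geometry")
}

#' Build the node-centred transect grid
#'
#' Lays a regular lattice of cell centres over the staircase domain. A node is
#' wet when its cell lies within the subdomain covering its x position; bottom
#' depths that are not multiples of `dz` are truncated downward (conservative
#' wet region) and the truncation is recorded in `$truncation_log`.
#'
#' Boundary classes (priority order): `surface`, `bottom`, `lateral_west`,
#' `lateral_east`, `internal_step` (a wet node whose left/right neighbour is a
#' dry node of a shallower subdomain), `interior`.
#'
#' @param geometry a [domain_geometry()].
#' @return An object of class `transect_grid` with fields `x_nodes`, `z_nodes`,
#'   `wet` (nx by nz logical), `boundary_class` (character matrix), `nwet`
#'   (wet nodes per column), face-openness masks `open_x`, `open_z`, and the
#'   spacings `dx`, `dz`.
#' @export
build_grid <- function(geometry) {
  if (!inherits(geometry, "domain_geometry")) stop("geometry must be a domain_geometry")
  dx <- geometry$dx; dz <- geometry$dz
  nx <- as.integer(round(geometry$x_l / dx))
  x_nodes <- (seq_len(nx) - 0.5) * dx
  sd <- geometry$subdomains
  # wet cells per column: floor(z_bottom/dz), truncating non-divisible depths
  zb_of_x <- vapply(x_nodes, function(x) {
    j <- which(x > sd$x_start - 1e-9 & x < sd$x_end + 1e-9)[1L]
    sd$z_bottom[j]
  }, numeric(1))
  nwet <- pmax(1L, as.integer(floor(zb_of_x / dz + 1e-9)))
  trunc_cols <- which(abs(zb_of_x / dz - round(zb_of_x / dz)) > 1e-8)
  truncation_log <- if (length(trunc_cols))
    sprintf("column x=%g m: z_bottom=%g m truncated to %g m",
            x_nodes[trunc_cols], zb_of_x[trunc_cols], nwet[trunc_cols] * dz)
  else character(0)
  nz <- max(nwet)
  z_nodes <- (seq_len(nz) - 0.5) * dz
  wet <- outer(nwet, seq_len(nz), `>=`)

  has_left  <- rbind(FALSE, wet[-nx, , drop = FALSE])
  has_right <- rbind(wet[-1L, , drop = FALSE], FALSE)
  has_up    <- cbind(FALSE, wet[, -nz, drop = FALSE])
  has_down  <- cbind(wet[, -1L, drop = FALSE], FALSE)

  cls <- matrix(NA_character_, nx, nz)
  cls[wet] <- "interior"
  cls[wet & !has_right & col(wet) <= nz] <- "internal_step"
  cls[wet & !has_left] <- "internal_step"
  cls[row(wet) == nx & wet] <- "lateral_east"
  cls[row(wet) == 1L & wet] <- "lateral_west"
  cls[wet & !has_down] <- "bottom"
  cls[wet & col(wet) == 1L] <- "surface"
  # interior nodes that merely sit next to another wet node stay interior:
  # re-mark nodes that have all four wet neighbours
  all4 <- wet & has_left & has_right & has_up & has_down
  cls[all4] <- "interior"

  open_x <- wet[-nx, , drop = FALSE] & wet[-1L, , drop = FALSE]   # (nx-1) x nz faces
  open_z <- wet[, -nz, drop = FALSE] & wet[, -1L, drop = FALSE]   # nx x (nz-1) faces

  structure(list(x_nodes = x_nodes, z_nodes = z_nodes, nx = nx, nz = nz,
                 dx = dx, dz = dz, wet = wet, nwet = nwet,
                 boundary_class = cls, open_x = open_x, open_z = open_z,
                 geometry = geometry, truncation_log = truncation_log),
            class = "transect_grid")
}

#' Cell areas and wet column depths
#'
#' @param grid a [build_grid()] result.
#' @return list with `area` (nx by nz matrix, m^2; dry cells 0) and
#'   `column_depth` (m per x node).
#' @export
cell_measures <- function(grid) {
  if (!inherits(grid, "transect_grid")) stop("grid must be a transect_grid")
  if (!any(grid$wet)) stop("empty grid")
  list(area = grid$dx * grid$dz * grid$wet,
       column_depth = grid$nwet * grid$dz)
}

#' @export
print.transect_grid <- function(x, ...) {
  cat(sprintf("transect grid: %d x-nodes (dx = %g m) x %d z-nodes (dz = %g m), %d wet\n",
              x$nx, x$dx, x$nz, x$dz, sum(x$wet)))
  invisible(x)
}

# matrix of x-node index / z-node index helpers used by the operators
wet_field <- function(grid, value = 0) {
  m <- matrix(value, grid$nx, grid$nz)
  m[!grid$wet] <- 0
  m
}
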