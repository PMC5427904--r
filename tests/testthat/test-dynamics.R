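test_that("Michaelis-Menten limitation behaves as defined", {
  expect_equal(michaelis_menten(0.06, 0.025, 0.025), 0.03)   # half saturation
  expect_equal(michaelis_menten(0.06, 0.025, 0), 0)
  expect_equal(michaelis_menten(0.06, 0.025, 0.1), 0.048)
  s <- seq(0, 1, 0.05)
  f <- michaelis_menten(0.06, 0.02, s)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 0.06))
  expect_error(michaelis_menten(0.06, 0.025, -1), "negative")
})

test_that("net growth follows the minimum rule", {
  g <- make_test_grid(widths_km = 10, depths_m = 10)
  pop <- single_pop(r = 0.06, m = 0.02, K_I = 20, K_R = 0.02)
  # saturating light, R at half saturation: G = r/2 - m
  I <- matrix(1e9, g$nx, g$nz); R <- matrix(0.02, g$nx, g$nz)
  gr <- net_growth_rate(I, R, pop$test_pop, g)
  expect_equal(gr$G[1, 1], 0.06 * 0.5 - 0.02)
  # dark water: G = -m
  gr0 <- net_growth_rate(matrix(0, g$nx, g$nz), R, pop$test_pop, g)
  expect_equal(unique(as.vector(gr0$G)), -0.02)
  # G never exceeds min(f_I, f_R) - m
  set.seed(3)
  I <- matrix(stats::runif(g$nx * g$nz, 0, 600), g$nx, g$nz)
  R <- matrix(stats::runif(g$nx * g$nz, 0, 0.5), g$nx, g$nz)
  gr <- net_growth_rate(I, R, pop$test_pop, g)
  expect_true(all(gr$G <= pmin(gr$f_I, gr$f_R) - 0.02 + 1e-15))
})

test_that("light field matches the closed-form exponential", {
  g <- make_test_grid(widths_km = 10, depths_m = 100, dx = 5000, dz = 2)
  # clear water
  I <- light_field(list(matrix(0, g$nx, g$nz)), rep(600, g$nx), 0.015, 0.045, g)
  expect_equal(I[1, ], 600 * exp(-0.045 * g$z_nodes))
  # uniform chlorophyll: constant-integrand trapezoid is exact
  C <- 0.3
  I2 <- light_field(list(matrix(C, g$nx, g$nz)), rep(600, g$nx), 0.016, 0.045, g)
  expect_equal(I2[2, ], 600 * exp(-(0.045 + 0.016 * C) * g$z_nodes))
  # monotone decreasing down every column when a_bg > 0
  set.seed(4)
  chl <- matrix(stats::runif(g$nx * g$nz, 0, 0.5), g$nx, g$nz)
  I3 <- light_field(list(chl), rep(600, g$nx), 0.016, 0.045, g)
  expect_true(all(apply(I3, 1, function(col) all(diff(col) < 0))))
  expect_error(light_field(list(matrix(-1, g$nx, g$nz)), rep(600, g$nx),
                           0.016, 0.045, g), "negative")
})

test_that("taxis velocity follows the growth-gradient sign rule", {
  g <- make_test_grid(widths_km = 5, depths_m = 40, dx = 5000, dz = 2)
  z <- matrix(g$z_nodes, g$nx, g$nz, byrow = TRUE)
  up <- taxis_velocity(0.001 * z, 0.5, g)        # G grows downward -> sink
  expect_true(all(up[1, 2:(g$nz - 1)] == 0.5))
  dn <- taxis_velocity(-0.001 * z, 0.5, g)       # G falls downward -> rise
  expect_true(all(dn[1, 2:(g$nz - 1)] == -0.5))
  flat <- taxis_velocity(matrix(0.01, g$nx, g$nz), 0.5, g)
  expect_true(all(flat == 0))                    # motionless inside deadband
  expect_equal(up[1, 1], 0)                      # pinned at surface
  expect_equal(up[1, g$nz], 0)                   # pinned at bottom
  expect_error(taxis_velocity(0.001 * z, -1, g), "non-negative")
})

test_that("trivial steady states have zero tendencies", {
  g <- make_test_grid(widths_km = c(10, 10), depths_m = 20)
  env <- make_test_env(g, v_h = 0.05, a_bg = 0, nutrient_bc = "dirichlet",
                       R_in = 0.1)
  pops <- zero_growth_pop()
  # b = 0 everywhere, R identically R_in
  st <- init_state(g, b0 = 0, R0 = 0.1, n_pops = 1)
  td <- rhs(st, env, pops, g)
  expect_equal(max(abs(td$db[[1]])), 0)
  expect_equal(max(abs(td$dR)), 0)
  # uniform b with G = 0, no advection: diffusion of a constant vanishes
  env2 <- make_test_env(g, v_h = 0, a_bg = 0, nutrient_bc = "closed", R_in = 0.1)
  st2 <- init_state(g, b0 = 1e9, R0 = 0.1, n_pops = 1)
  td2 <- rhs(st2, env2, pops, g)
  expect_lt(max(abs(td2$db[[1]])) / 1e9, 1e-14)
})

test_that("diffusion of a point perturbation matches the five-point stencil", {
  g <- make_test_grid(widths_km = 25, depths_m = 10, dx = 5000, dz = 2)
  env <- make_test_env(g, D_v = 2e-4, D_h = 30, v_h = 0, a_bg = 0,
                       nutrient_bc = "closed")
  pops <- zero_growth_pop()
  st <- init_state(g, b0 = 1e9, R0 = 0.1, n_pops = 1)
  st$b[[1]][3, 3] <- 2e9
  td <- rhs(st, env, pops, g)
  Dz <- 2e-4 * 3600; Dx <- 30 * 3600
  lap <- function(j, k) {
    Dz * (st$b[[1]][j, k + 1] - 2 * st$b[[1]][j, k] + st$b[[1]][j, k - 1]) / 4 +
      Dx * (st$b[[1]][j + 1, k] - 2 * st$b[[1]][j, k] + st$b[[1]][j - 1, k]) / 25e6
  }
  expect_equal(td$db[[1]][3, 3], lap(3, 3))
  expect_equal(td$db[[1]][3, 4], lap(3, 4))
  expect_equal(td$db[[1]][2, 3], lap(2, 3))
})

test_that("rhs and two Euler steps match the brute-force oracle node by node", {
  geo <- domain_geometry(data.frame(x_start = c(0, 15000),
                                    x_end = c(15000, 30000),
                                    z_bottom = c(10, 16)), dx = 5000, dz = 2)
  g <- build_grid(geo)                                # 6 x 8 staircase
  set.seed(99)
  env <- make_test_env(g, D_v = matrix(stats::runif(g$nx * g$nz, 5e-5, 2e-4), g$nx, g$nz),
                       D_h = 40, v_h = matrix(stats::rnorm(g$nx * g$nz, 0.05, 0.05), g$nx, g$nz),
                       I_in = 600, a_bg = 0.05,
                       R_in = 0.3, nutrient_bc = "dirichlet")
  env$R_in_west <- stats::runif(g$nz, 0.1, 0.4)
  env$R_in_east <- stats::runif(g$nz, 0.1, 0.4)
  env$R_in_bottom <- stats::runif(g$nx, 0.2, 0.5)
  pops <- structure(list(
    a = population_params("a", r = 0.06, m = 0.02, K_I = 25, K_R = 0.03,
                          invY = 1e-13, eps = 0.6, a = 0.015, v_s = 0.3,
                          content = 1.18),
    b = population_params("b", r = 0.05, m = 0.01, K_I = 8, K_R = 0.02,
                          invY = 5e-13, eps = 0.4, a = 0.016, v_s = 0.2,
                          content = data.frame(depth_m = c(0, 16),
                                               fg_per_cell = c(20, 40)))),
    class = "plankton_community")
  st <- init_state(g, b0 = c(2e9, 1e9), R0 = matrix(stats::runif(g$nx * g$nz, 0.01, 0.3),
                                                    g$nx, g$nz), n_pops = 2)
  st$b[[1]] <- st$b[[1]] * matrix(stats::runif(g$nx * g$nz, 0.5, 1.5), g$nx, g$nz) * g$wet
  st$b[[2]] <- st$b[[2]] * matrix(stats::runif(g$nx * g$nz, 0.5, 1.5), g$nx, g$nz) * g$wet

  td <- rhs(st, env, pops, g)
  ora <- oracle_rhs(st, env, pops, g)
  expect_lt(max(rel_diff(td$db[[1]], ora$db[[1]])), 1e-12)
  expect_lt(max(rel_diff(td$db[[2]], ora$db[[2]])), 1e-12)
  expect_lt(max(rel_diff(td$dR, ora$dR)), 1e-12)
  expect_lt(max(rel_diff(td$I, ora$I)), 1e-12)

  s2 <- step(step(st, env, pops, g, 0.05), env, pops, g, 0.05)
  o2 <- oracle_step(oracle_step(st, env, pops, g, 0.05), env, pops, g, 0.05)
  expect_lt(max(rel_diff(s2$b[[1]], o2$b[[1]])), 1e-12)
  expect_lt(max(rel_diff(s2$b[[2]], o2$b[[2]])), 1e-12)
  expect_lt(max(rel_diff(s2$R, o2$R)), 1e-12)
})
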