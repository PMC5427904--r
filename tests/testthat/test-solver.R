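test_that("centred diffusion is exact for the cases it should resolve", {
  z <- seq(1, 99, 2)
  expect_equal(diffuse_centered(rep(3, 50), 1e-4, 2), rep(0, 50))
  # quadratic field, constant D: interior second difference is exact (2D)
  f <- z^2
  out <- diffuse_centered(f, 0.5, 2)
  expect_equal(out[2:49], rep(1, 48))
  # linearly varying D with linear f: matches a direct face-flux assembly
  D <- 1e-4 + 1e-6 * z
  f <- 2 + 0.1 * z
  out <- diffuse_centered(f, D, 2)
  brute <- numeric(50)
  Fl <- vapply(1:49, function(j) 0.5 * (D[j] + D[j + 1]) * (f[j + 1] - f[j]) / 2,
               numeric(1))
  for (j in 1:50) brute[j] <- ((if (j < 50) Fl[j] else 0) - (if (j > 1) Fl[j - 1] else 0)) / 2
  expect_equal(out, brute)
  expect_error(diffuse_centered(f, -1, 2), "positive")
})

test_that("third-order upwind advection is exact on low-order fields", {
  x <- seq(0.5, 19.5, 1)
  # constant field: zero divergence everywhere on a periodic axis, and on
  # the interior of a closed axis (the walls accumulate, by construction)
  expect_equal(advect_upwind3(rep(2, 20), -0.7, 1, boundary = "periodic"),
               rep(0, 20))
  expect_equal(advect_upwind3(rep(2, 20), 0.7, 1)[2:19], rep(0, 18))
  # linear field, constant v: interior divergence equals v exactly
  out <- advect_upwind3(x, 1.5, 1)
  expect_equal(out[3:18], rep(1.5, 16))
  expect_error(advect_upwind3(x, c(1, 2), 1), "length")
})

test_that("advection truncation error converges at third order on a Gaussian", {
  orders <- c()
  errs <- vapply(c(50, 100, 200, 400), function(n) {
    x <- (seq_len(n) - 0.5) / n
    ds <- 1 / n
    f <- exp(-(x - 0.5)^2 / (2 * 0.07^2))
    num <- advect_upwind3(f, 1, ds, boundary = "periodic")
    ana <- -(x - 0.5) / 0.07^2 * f
    sqrt(mean((num - ana)^2))
  }, numeric(1))
  orders <- diff(log(errs)) / log(0.5)
  expect_true(all(orders >= 2.5))
})

test_that("stability report reproduces hand-computed CFL numbers", {
  g <- make_test_grid(widths_km = 20, depths_m = 100, dx = 5000, dz = 2)
  pops <- single_pop(v_s = 0)
  env <- make_test_env(g, D_v = 1e-4, D_h = 10, v_h = 0.5)
  rep1 <- cfl_check(env, pops, solver_settings(dt = 0.05), g)
  expect_equal(rep1$diffusive_number, 1e-4 * 180 / 4)        # 4.5e-3
  expect_equal(rep1$advective_number, 0.5 * 180 / 5000)      # 0.018
  expect_true(rep1$pass)
  env2 <- make_test_env(g, D_v = 1e-2, D_h = 10, v_h = 0)
  rep2 <- cfl_check(env2, pops, solver_settings(dt = 0.05), g)
  expect_equal(rep2$diffusive_number, 0.45)
  expect_false(rep2$pass)
  st <- init_state(g, b0 = 1e8, R0 = 0.1, n_pops = 1)
  expect_error(integrate_to_steady(st, env2, pops, g, solver_settings(dt = 0.05)),
               "stability")
})

test_that("one Euler step integrates pure decay exactly", {
  g <- make_test_grid(widths_km = 10, depths_m = 10)
  # dark water: G = -m uniformly; no transport
  pops <- single_pop(r = 0.04, m = 0.02, a = 0, v_s = 0)
  env <- make_test_env(g, D_v = 1e-9, D_h = 1e-6, v_h = 0, I_in = 0,
                       a_bg = 0, R_in = 0.1, nutrient_bc = "closed")
  st <- init_state(g, b0 = 1e9, R0 = 0.1, n_pops = 1)
  s1 <- step(st, env, pops, g, 0.05)
  expect_equal(s1$b[[1]][g$wet], rep(1e9 * (1 - 0.02 * 0.05), sum(g$wet)),
               tolerance = 1e-12)
  # a zero-tendency state stays put
  pops0 <- zero_growth_pop()
  env0 <- make_test_env(g, v_h = 0, a_bg = 0, nutrient_bc = "closed")
  st0 <- init_state(g, b0 = 1e9, R0 = 0.1, n_pops = 1)
  s0 <- step(st0, env0, pops0, g, 0.05)
  expect_equal(s0$b[[1]], st0$b[[1]], tolerance = 1e-13)
  expect_equal(s0$R, st0$R)
})

test_that("cosine eigenmode on a closed column decays at the analytic rate", {
  L <- 100; dz <- 2
  g <- make_test_grid(widths_km = 1, depths_m = L, dx = 1000, dz = dz)
  D <- 1e-4 * 3600
  f <- 1 + 0.5 * cos(pi * g$z_nodes / L)
  dt <- 0.02
  for (i in 1:200) f <- f + dt * diffuse_centered(f, D, dz)
  amp <- max(abs(f - 1))
  expect_equal(amp, 0.5 * exp(-D * (pi / L)^2 * dt * 200), tolerance = 0.01)
})

test_that("well-mixed nutrient-limited column settles at the 0D equilibrium", {
  g <- make_test_grid(widths_km = 1, depths_m = 10, dx = 1000, dz = 2)
  pops <- single_pop(r = 0.06, m = 0.02, K_I = 1e-4, K_R = 0.02, invY = 1e-13,
                     eps = 1, a = 0.015, v_s = 0, content = 1.18)
  env <- make_test_env(g, D_v = 1e-3, D_h = 1, v_h = 0, I_in = 1e6, a_bg = 0,
                       R_in = 0.05, nutrient_bc = "closed")
  st <- init_state(g, b0 = 1e8, R0 = 0.05, n_pops = 1)
  run <- integrate_to_steady(st, env, pops, g,
                             solver_settings(dt = 0.2, t_max = 2e4,
                                             steady_tol = 1e-9))
  expect_true(run$converged)
  r_star <- 0.02 * 0.02 / (0.06 - 0.02)                       # m K_R / (r - m)
  expect_equal(mean(run$state$R[g$wet]), r_star, tolerance = 0.05)
  # biomass absorbed the phosphorus removed from solution (eps = 1)
  expect_equal(mean(run$state$b[[1]][g$wet]) * 1e-13, 0.05 - r_star,
               tolerance = 0.05)
})

test_that("conservation holds when growth vanishes and boundaries are closed", {
  g <- make_test_grid(widths_km = c(100, 100), depths_m = c(60, 100),
                      dx = 5000, dz = 2)                       # 40 x 50 grid
  pops <- zero_growth_pop()
  env <- make_test_env(g, D_v = 1e-4, D_h = 50,
                       v_h = matrix(0.1 * sin(outer(g$x_nodes / 2e5,
                                                    g$z_nodes / 50, "+")),
                                    g$nx, g$nz),
                       a_bg = 0, R_in = 0.1, nutrient_bc = "closed")
  set.seed(2)
  st <- init_state(g, b0 = 1e9, R0 = 0.1, n_pops = 1)
  st$b[[1]] <- st$b[[1]] * matrix(stats::runif(g$nx * g$nz, 0.5, 1.5),
                                  g$nx, g$nz) * g$wet
  area <- cell_measures(g)$area
  m0 <- sum(st$b[[1]] * area)
  for (i in 1:1000) st <- step(st, env, pops, g, 0.05)
  expect_lt(abs(sum(st$b[[1]] * area) - m0) / m0, 1e-9)
  expect_equal(st$clipped_mass, 0)
})

test_that("total phosphorus is conserved with full recycling and closed boundaries", {
  g <- make_test_grid(widths_km = c(100, 100), depths_m = c(60, 100),
                      dx = 5000, dz = 2)
  pops <- single_pop(r = 0.05, m = 0.02, K_I = 30, K_R = 0.03, invY = 2e-13,
                     eps = 1, a = 0.016, v_s = 0.1, content = 30)
  env <- make_test_env(g, D_v = 1e-4, D_h = 50, v_h = 0.05, I_in = 600,
                       a_bg = 0.045, R_in = 0.2, nutrient_bc = "closed")
  st <- init_state(g, b0 = 1e9, R0 = 0.2, n_pops = 1)
  area <- cell_measures(g)$area
  total_p <- function(s) sum((s$R + 2e-13 * s$b[[1]]) * area)
  p0 <- total_p(st)
  for (i in 1:1000) st <- step(st, env, pops, g, 0.05)
  expect_lt(abs(total_p(st) - p0) / p0, 1e-9)
})

test_that("steady state does not depend on the initial uniform abundance", {
  g <- make_test_grid(widths_km = 1, depths_m = 10, dx = 1000, dz = 2)
  pops <- single_pop(r = 0.06, m = 0.02, K_I = 1e-4, K_R = 0.02, invY = 1e-13,
                     eps = 1, a = 0, v_s = 0, content = 1.18)
  env <- make_test_env(g, D_v = 1e-3, D_h = 1, v_h = 0, I_in = 1e6, a_bg = 0,
                       R_in = 0.05, nutrient_bc = "closed")
  run_from <- function(b0) {
    st <- init_state(g, b0 = b0, R0 = 0.05, n_pops = 1)
    integrate_to_steady(st, env, pops, g,
                        solver_settings(dt = 0.2, t_max = 2e4,
                                        steady_tol = 1e-9))$state
  }
  s1 <- run_from(1e7); s2 <- run_from(1e9)
  expect_equal(mean(s1$R[g$wet]), mean(s2$R[g$wet]), tolerance = 1e-3)
})
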