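test_that("Richardson number matches hand evaluation and limiting cases", {
  depth <- c(0, 10, 20)
  # linear density gradient 0.01 kg/m^4, shear 0.01 1/s
  ri <- richardson_number(depth, 1025 + 0.01 * depth, 0.01 * depth)
  n2 <- 9.81 / 1025 * 0.01
  expect_equal(ri, rep(n2 / 1e-4, 3), tolerance = 1e-10)
  expect_equal(ri[2], 0.9571, tolerance = 1e-4)
  # uniform density: Ri = 0
  expect_equal(richardson_number(depth, rep(1025, 3), 0.01 * depth), rep(0, 3))
  # zero shear: capped
  expect_equal(richardson_number(depth, 1025 + 0.01 * depth, rep(0.1, 3)),
               rep(1e6, 3))
  expect_error(richardson_number(c(0, 10), c(1025, 1026), c(0, 0.1)), "3 depth")
  expect_error(richardson_number(c(0, 20, 10), rep(1025, 3), rep(0, 3)),
               "increasing")
})

test_that("Pacanowski-Philander closure hits its limits and hand value", {
  expect_equal(pacanowski_philander(0), 0.01 + 1e-4 + 1e-5)
  expect_equal(pacanowski_philander(1e12), 1e-5, tolerance = 1e-6)
  nu <- 0.01 / 36 + 1e-4
  expect_equal(pacanowski_philander(1), nu / 6 + 1e-5)
  expect_equal(pacanowski_philander(1), 7.296e-5, tolerance = 1e-4)
  expect_error(pacanowski_philander(-0.1), "negative")
})

test_that("diffusivity decreases with Richardson number", {
  set.seed(7)
  for (i in 1:50) {
    ri <- sort(stats::runif(2, 0, 50))
    dv <- pacanowski_philander(ri)
    expect_true(dv[2] < dv[1])
  }
})

test_that("interpolation reproduces station values and linear structure", {
  g <- make_test_grid(widths_km = 20, depths_m = 100, dx = 5000, dz = 2)
  st <- function(x, val) list(station_id = paste0("s", x), x = x, I_in = 600,
                              depth = c(1, 50, 99), density = c(1025, 1026, 1027),
                              u = rep(val, 3), phosphate = rep(val, 3),
                              chl = rep(val, 3))
  profs <- hydro_profiles(list(st(2500, 1), st(12500, 3)))
  u <- interpolate_to_grid(profs, g, "u")
  expect_equal(u[1, ], rep(1, g$nz))             # exact at station x
  expect_equal(u[3, ], rep(3, g$nz))
  expect_equal(u[2, 1], 2)                       # linear midpoint in x
  # linear in z: v = 0.1 - 0.001 z sampled at z = 50
  pr2 <- hydro_profiles(list(
    modifyList(st(2500, 0), list(u = 0.1 - 0.001 * c(1, 50, 99))),
    st(17500, 0)))
  u2 <- interpolate_to_grid(pr2, g, "u")
  expect_equal(u2[1, which(g$z_nodes == 49)], 0.1 - 0.001 * 49)
  expect_error(interpolate_to_grid(profs, g, "no_such_field"), "field_name")
  expect_error(interpolate_to_grid(hydro_profiles(list(st(2500, 1))), g, "u"),
               "2 stations")
})

test_that("assembled environment satisfies its invariants on a seeded scenario", {
  cfg <- scenario_config(n_stations = 6, transect_length = 100e3, dx = 10000,
                         dz = 4, seed = 11)
  profs <- generate_hydrology(cfg)
  g <- build_grid(domain_geometry(cfg$subdomains, dx = 10000, dz = 4))
  env <- assemble_environment(profs, g)
  w <- g$wet
  expect_true(all(env$D_v[w] >= 1e-5))
  expect_true(all(is.finite(env$D_v[w])))
  expect_true(all(env$D_h > 0))
  expect_true(all(env$R_in_bottom >= 0))
  # mixing is stronger in the surface layer than in the quiet interior:
  # transect-wide, and distinctly so at the sheared coastal end stations
  above_tot <- 0; below_tot <- 0
  for (s in profs) {
    j <- which.min(abs(g$x_nodes - s$x))
    above <- g$z_nodes < 20; below <- g$z_nodes > 60 & g$wet[j, ]
    above_tot <- above_tot + mean(env$D_v[j, above])
    below_tot <- below_tot + mean(env$D_v[j, below])
  }
  expect_gt(above_tot, below_tot)
  j1 <- which.min(abs(g$x_nodes - profs[[1]]$x))
  expect_gt(mean(env$D_v[j1, g$z_nodes < 20]),
            mean(env$D_v[j1, g$z_nodes > 60 & g$wet[j1, ]]))
  # piecewise-constant D_h honours the configured segments
  cfgd <- environment_config(dh_segments = data.frame(
    x_start = c(0, 50e3), x_end = c(50e3, 100e3), value = c(100, 10)))
  env2 <- assemble_environment(profs, g, cfgd)
  expect_equal(env2$D_h, ifelse(g$x_nodes < 50e3, 100, 10))
})

test_that("identical hydrology at all stations gives x-uniform fields", {
  g <- make_test_grid(widths_km = 20, depths_m = 100, dx = 5000, dz = 2)
  base <- list(depth = seq(1, 99, 2))
  mk <- function(x) list(station_id = paste0("s", x), x = x, I_in = 500,
                         depth = base$depth,
                         density = 1025 + 0.02 * base$depth,
                         u = 0.1 * exp(-base$depth / 40),
                         phosphate = 0.02 + 0.004 * base$depth,
                         chl = rep(0.1, length(base$depth)))
  env <- assemble_environment(hydro_profiles(list(mk(2500), mk(17500))), g)
  expect_equal(env$D_v[1, ], env$D_v[4, ])
  expect_equal(env$v_h[1, ], env$v_h[3, ])
})
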