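test_that("Poiseuille: parabolic profile and wall shear within 1%", {
  fx <- poiseuille_fixture()
  out <- fx$run()
  expect_lt(out$profile_error, 0.01)
  expect_lt(out$tau_error, 0.01)
  # radial velocity and residual divergence are at round-off
  expect_lt(max(abs(out$state$ur)), 1e-10)
  expect_lt(out$state$div_norm, 1e-10)
})

test_that("zero wall motion from rest keeps the fluid exactly at rest", {
  geom <- wall_geometry(0.5, 0, 2.4, "segmentation", period = 5)
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                        n_periods = 1)
  case$geometry <- geom
  prob <- lumenflow:::segmentation_problem(case, list(
    nr = 12, nz_per_wavelength = 16, stretch = 1.5, cfl = 0.35,
    dt_max_frac = 1 / 50))
  out <- lumenflow:::run_flow(prob, 1)
  expect_lt(max(abs(out$state$uz), abs(out$state$ur)), 1e-12)
})

test_that("manufactured solution converges at second order in space", {
  fx <- manufactured_solution_fixture()
  out <- fx$run()
  expect_true(all(out$orders >= 1.9))
  expect_lt(out$errors[length(out$errors)], 0.005)
})

test_that("wave-frame peristaltic flow matches the lubrication oracle within
           5% in the long-wavelength low-Reynolds limit", {
  lam <- 25; r0 <- 0.5; c_w <- 0.2     # lambda/r0 = 50
  fl <- fluid_model("stokes_oil", density = 0.02, mu = 200)  # Re ~ 1e-3
  geom <- wall_geometry(r0, 0.4 * r0, lam, "peristalsis", wave_speed = c_w)
  case <- motility_case("peristalsis", "moderate", "water_37C", 2, 0.3)
  case$geometry <- geom
  case$fluid <- fl
  expect_lt(reynolds_number(case), 0.1)
  wf <- solve_peristalsis_flow(case, resolution = list(
    nr = 20, nz_per_wavelength = 48, stretch = 1.5, cfl = 0.35,
    dt_max_frac = 1 / 100), tol = 2e-5, max_steps = 60000)
  q <- mean(rowSums(wf$fluxZ))
  oracle <- lubrication_peristalsis_oracle(geom)
  Q_solver <- q + c_w * pi * oracle$mean_h2
  expect_lt(abs(Q_solver / oracle$Q_lab_mean - 1), 0.05)
  # wave-frame flux is identical through every cross-section (mass)
  expect_lt(diff(range(rowSums(wf$fluxZ))) / abs(q), 1e-8)
  # lab-frame transform adds exactly the wave speed
  lab <- lab_frame(wf)
  expect_equal(lab$uz, wf$uz + c_w)
  expect_equal(lab$ur, wf$ur)
  # steady by construction: advancing further does not change the field
  prob <- lumenflow:::peristalsis_problem(case, list(
    nr = 20, nz_per_wavelength = 48, stretch = 1.5, cfl = 0.35,
    dt_max_frac = 1 / 100))
  st <- list(t = 0, uz = wf$uz, ur = wf$ur, p = wf$p,
             geom = lumenflow:::geom_at(prob, 0))
  st2 <- st
  dtm <- prob$dt_max         # the step size the steady march itself used
  for (k in 1:50) st2 <- lumenflow:::flow_step(prob, st2, dtm)
  expect_lt(max(abs(st2$uz - wf$uz)) / c_w, 1e-3)
})

test_that("lubrication oracle limits: no wave means no flow; full occlusion
           transports the whole lumen content", {
  r0 <- 0.5; lam <- 25
  g0 <- wall_geometry(r0, 0, lam, "peristalsis", wave_speed = 1)
  expect_equal(lubrication_peristalsis_oracle(g0)$Q_lab_mean, 0,
               tolerance = 1e-12)
  g1 <- wall_geometry(r0, 0.995 * r0, lam, "peristalsis", wave_speed = 1)
  o1 <- lubrication_peristalsis_oracle(g1)
  # -> c * pi * <h^2> as delta -> r0 (complete bolus transport)
  expect_equal(o1$Q_lab_mean / (pi * o1$mean_h2), 1, tolerance = 0.05)
})

test_that("segmentation flow: divergence-free fluxes, bounded CFL, laminar
           Reynolds numbers across the study grid", {
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3)
  prob <- lumenflow:::segmentation_problem(case, list(
    nr = 14, nz_per_wavelength = 20, stretch = 2, cfl = 0.35,
    dt_max_frac = 1 / 60))
  out <- lumenflow:::run_flow(prob, 2.5, diagnostics = TRUE)
  expect_lt(max(out$diagnostics$div), 1e-8)
  expect_lt(max(out$diagnostics$cfl), 1.0)
  expect_gt(max(out$diagnostics$umax), 0.1)
  # laminar assumption across the full factorial grid
  grid <- sweep_grid()
  re <- vapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    reynolds_number(motility_case(row$motility, row$intensity, row$fluid,
                                  row$pocket_volume, row$occlusion_ratio,
                                  row$release))
  }, numeric(1))
  expect_true(all(re < 2000))
})

test_that("wall shear stress of a zero-flow state is zero", {
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3)
  prob <- lumenflow:::segmentation_problem(case, list(
    nr = 12, nz_per_wavelength = 16, stretch = 1.5, cfl = 0.35,
    dt_max_frac = 1 / 50))
  st <- lumenflow:::flow_initial_state(prob)
  fs <- lumenflow:::field_state(prob, st)
  ws <- wall_shear_stress(fs)
  expect_equal(ws$max, 0, tolerance = 1e-12)
})
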