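test_that("bolus initialisation: released moles match the closed-form
           Gaussian integral, peaks approach ci with resolution", {
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3)
  sb <- case$geometry$rest_radius / 10
  # coarse, wall-stretched grid: moles still exact (cell-averaged init)
  g <- flow_grid(7.2, 96, 20, 2.2)
  h <- rep(0.515, 96)
  tr <- initialize_bolus(case, g, h,
                         release = list(z = 3.6, pocket = 2, sigma_b = sb))
  expect_equal(unname(total_moles(tr) / (c(2, 100) * (2 * pi * sb^2)^1.5)),
               c(1, 1), tolerance = 1e-3)
  # adequately resolved grid: the discrete peak approaches ci
  gf <- flow_grid(7.2, 384, 64, 0.5)
  trf <- initialize_bolus(case, gf, rep(0.515, 384),
                          release = list(z = 3.6, pocket = 2, sigma_b = sb))
  expect_equal(max(trf$conc$insulin), 2, tolerance = 0.04)
  expect_equal(max(trf$conc$C10), 100, tolerance = 4)
  # bolus overlapping the wall is rejected
  expect_error(
    initialize_bolus(case, g, h, release = list(z = 3.6, pocket = 2,
                                                sigma_b = 0.3)),
    "overlap")
})

test_that("pure diffusion: Gaussian variance grows as sigma^2 + 2Dt within
           1%, mass conserved, concentrations non-negative", {
  fx <- diffusion_fixture()
  out <- fx$run()
  expect_lt(out$variance_error, 0.01)
  expect_lt(out$mass_error, 1e-12)
  expect_gte(out$min_conc, -1e-12)
  expect_lt(out$released_error, 1e-3)
})

test_that("uniform concentration in the moving closed lumen stays uniform to
           1e-10 and mass drifts below 0.1%", {
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                        n_periods = 1)
  prob <- lumenflow:::segmentation_problem(case, list(
    nr = 14, nz_per_wavelength = 20, stretch = 2, cfl = 0.35,
    dt_max_frac = 1 / 60))
  g <- prob$grid
  h0 <- prob$hfun(g$zc, 0)
  sp <- list(species_model("u", 1, D = 1e-6))
  tr <- lumenflow:::new_transport_state(g, h0, sp,
                                        list(u = matrix(1, g$Nz, g$Nr)), 1)
  tr$Vol <- lumenflow:::cell_volumes(g, h0)
  m0 <- sum(tr$conc[[1]] * tr$Vol)
  st <- lumenflow:::flow_initial_state(prob); dt <- 0.01
  for (k in 1:80) {
    st1 <- lumenflow:::flow_step(prob, st, dt)
    Fzc <- st1$fluxZ; Fzc[g$Nz, ] <- 0       # closed ends for the scalar
    tr <- lumenflow:::scalar_step(tr, Fzc, st1$fluxE, st1$Vol0, st1$Vol1,
                                  st$geom$h, st1$geom$h, st1$hzm, dt,
                                  case$fluid, 1,
                                  open_left_flux = rep(0, g$Nr))
    st <- st1
    dt <- lumenflow:::next_dt(prob, st, dt)
  }
  expect_lt(max(abs(tr$conc[[1]] - 1)), 1e-10)
  expect_lt(abs(sum(tr$conc[[1]] * tr$Vol) / m0 - 1), 1e-3)
})

test_that("species with equal diffusivity and concentration stay identical
           through a coupled segmentation run", {
  sp1 <- species_model("a", 5, D = 2e-6)
  sp2 <- species_model("b", 5, D = 2e-6)
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                        species = list(sp1, sp2), n_periods = 1)
  res <- run_case(case, list(nr = 14, nz_per_wavelength = 20, stretch = 2,
                             cfl = 0.35, dt_max_frac = 1 / 60),
                  n_periods = 1)
  m <- res$metrics
  a <- m[m$species == "a", ]; b <- m[m$species == "b", ]
  expect_equal(a$nearwall_D15_pct, b$nearwall_D15_pct, tolerance = 1e-10)
  expect_equal(a$wall_cmax_norm, b$wall_cmax_norm, tolerance = 1e-10)
  # convection-dominated transport: Peclet >> 1
  expect_gt(glance(res)$peclet, 1e3)
  # positivity after limiting
  expect_gte(min(vapply(res$final_moles, min, numeric(1))), 0)
})

test_that("peristalsis transport with a zero-amplitude wave reduces to
           advected pure diffusion", {
  # plug flow in the wave frame (u = -c), static straight wall: the bolus
  # drifts but its axial variance grows exactly as 2 D t
  D <- 5e-5
  sp <- species_model("tracer", 1, D = D)
  case <- motility_case("peristalsis", "moderate", "water_37C", 2, 0.3,
                        species = list(sp, species_model("t2", 1, D = D)))
  # compact domain with a well-resolved bolus so numerical smearing of the
  # (exactly rigid) plug advection stays below the diffusive growth
  case$geometry <- wall_geometry(0.515, 0, 2.4, "peristalsis", wave_speed = 1,
                                 n_pockets = 6L)
  wf <- solve_peristalsis_flow(case, resolution = list(
    nr = 14, nz_per_wavelength = 32, stretch = 1.5, cfl = 0.35,
    dt_max_frac = 1 / 100), tol = 1e-6, max_steps = 20000)
  expect_lt(max(abs(wf$uz + 1)), 1e-4)   # rigid plug at -c
  sb <- 0.12
  res <- peristalsis_transport(case, wf, n_periods = 2, sigma_b = sb,
                               scalar_resolution = list(
                                 nz_per_wavelength = 256L, nr = 28L,
                                 stretch = 1.5))
  t_end <- 2 * case$geometry$period
  tr <- res$final_state
  M <- tr$conc[[1]] * tr$Vol
  zm <- matrix(tr$grid$zc, tr$grid$Nz, tr$grid$Nr)
  zb <- sum(M * zm) / sum(M)
  v1 <- sum(M * (zm - zb)^2) / sum(M)
  expect_equal(v1, sb^2 + 2 * D * t_end, tolerance = 0.01)
  expect_lt(abs(glance(res)$mass_balance_error), 1e-3)
})

test_that("in-domain moles decrease monotonically once mass reaches the open
           ends", {
  D <- 2e-4
  sp <- species_model("tracer", 1, D = D)
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                        species = list(sp))
  g <- flow_grid(2.0, 40, 12, stretch = 1)
  h <- rep(0.5, 40)
  # release near the right end, advect toward it
  tr <- initialize_bolus(case, g, h,
                         release = list(z = 1.7, pocket = 1, sigma_b = 0.05))
  uz <- matrix(0.5, 40, 12)
  Fz <- uz * pi * outer(rep(0.5^2, 40), diff(g$etaf^2))
  Fe <- matrix(0, 40, 11)
  m_hist <- c()
  st <- tr
  for (k in 1:60) {
    st <- lumenflow:::scalar_step(st, Fz, Fe, st$Vol, st$Vol, h, h,
                                  rep(0, 40), 0.02,
                                  fluid_registry("water_37C"), 1,
                                  open_left_flux = rep(0, 12))
    m_hist <- c(m_hist, total_moles(st)[1])
  }
  expect_true(all(diff(m_hist) <= 1e-12))
  expect_lt(tail(m_hist, 1), total_moles(tr)[1] * 0.8)
  # escaped mass is accounted for
  expect_equal(unname(tail(m_hist, 1) + st$escaped[1]),
               unname(total_moles(tr)[1]), tolerance = 1e-10)
})
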