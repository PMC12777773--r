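test_that("effective viscosity: Newtonian constant, power-law with clamp", {
  w <- fluid_registry("water_37C")
  expect_equal(effective_viscosity(w, c(0.01, 1, 500)), rep(0.6913, 3))
  pl <- fluid_model("pl", 1, K = 100, n = 0.5)
  expect_equal(effective_viscosity(pl, 4), 50)       # 100 * 4^-0.5
  n1 <- fluid_model("n1", 1, K = 42, n = 1)
  expect_equal(effective_viscosity(n1, c(0.1, 10)), c(42, 42))
  # clamp: below/above the window the viscosity saturates
  expect_equal(effective_viscosity(pl, 0),
               effective_viscosity(pl, 1e-3))
  expect_equal(effective_viscosity(pl, 1e6),
               effective_viscosity(pl, 1e3))
})

test_that("species diffusivities reproduce the anchor ratios in water", {
  ins <- species_registry("insulin")
  c10 <- species_registry("C10")
  expect_equal(species_diffusivity(ins, 2), 1.11e-6)
  r100 <- species_diffusivity(c10, 100) / species_diffusivity(ins, 2)
  r1 <- species_diffusivity(c10, 1) / species_diffusivity(ins, 2)
  expect_equal(r100, 3.15, tolerance = 1e-12)
  expect_equal(r1, 5.50, tolerance = 1e-12)
  expect_equal(species_diffusivity(c10, 1), 6.105e-6, tolerance = 1e-3)
  expect_error(species_diffusivity(ins, -1), "negative")
})

test_that("C10 diffusivity decreases monotonically with concentration and
           clamps outside the anchor range", {
  c10 <- species_registry("C10")
  cc <- seq(1, 100, length.out = 200)
  d <- species_diffusivity(c10, cc)
  expect_true(all(diff(d) <= 0))
  expect_equal(species_diffusivity(c10, 0.1), species_diffusivity(c10, 1))
  expect_equal(species_diffusivity(c10, 500), species_diffusivity(c10, 100))
})

test_that("Stokes-Einstein scaling: doubling reference viscosity halves D", {
  ins <- species_registry("insulin")
  f1 <- fluid_model("a", 1, mu = 0.6913)
  f2 <- fluid_model("b", 1, mu = 2 * 0.6913)
  expect_equal(species_diffusivity(ins, 2, f1) / 2,
               species_diffusivity(ins, 2, f2))
  # power-law fluid: scaling uses the apparent viscosity at the reference
  # shear rate
  drink <- fluid_registry("nutridrink_default")
  gref <- 0.76
  mu_ref <- effective_viscosity(drink, gref)
  expect_equal(species_diffusivity(ins, 2, drink, reference_shear_rate = gref),
               1.11e-6 * 0.6913 / mu_ref)
})

test_that("fluid model validates inputs", {
  expect_error(fluid_model("bad", 1, K = 10, n = 1.4), "n")
  expect_error(fluid_model("bad", -1, mu = 1))
  expect_error(fluid_model("bad", 1, K = 10, n = 0.5,
                           shear_clamp = c(1, 0.1)))
})
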