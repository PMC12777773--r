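test_that("derived geometry holds the pocket volume in a rest cylinder", {
  g2 <- derive_geometry(2, 2.4, 0.3, "segmentation")
  expect_equal(g2$rest_radius, sqrt(2 / (pi * 2.4)), tolerance = 1e-12)
  expect_equal(g2$rest_radius, 0.5150, tolerance = 1e-3)
  g10 <- derive_geometry(10, 4.1, 0.3, "segmentation")
  expect_equal(g10$rest_radius, 0.8811, tolerance = 1e-3)
  # oracle: integrate pi h^2 over one wavelength at t = 0 and recover V
  for (g in list(g2, g10)) {
    zq <- seq(0, g$wavelength, length.out = 513)
    w <- lumenflow:::simpson_weights(512, g$wavelength / 512)
    V <- sum(w * pi * wall_radius(g, zq, 0)^2)
    expect_equal(V, g$pocket_volume, tolerance = 1e-10)
  }
})

test_that("occlusion amplitude solves min wall radius = OR * r0", {
  for (OR in c(0.3, 0.5, 0.7)) {
    g <- derive_geometry(2, 2.4, OR, "segmentation")
    zg <- seq(0, g$wavelength, length.out = 401)
    tg <- seq(0, g$period, length.out = 401)
    hmin <- min(outer(zg, tg, function(z, t) wall_radius(g, z, t)))
    expect_equal(hmin, OR * g$rest_radius, tolerance = 1e-4)
    gp <- derive_geometry(2, 2.4, OR, "peristalsis")
    expect_equal(gp$amplitude, (1 - OR) * gp$rest_radius, tolerance = 1e-12)
  }
})

test_that("radial excursion of the 10 mL pocket is ~1.7x the 2 mL pocket", {
  g2 <- derive_geometry(2, 2.4, 0.3, "segmentation")
  g10 <- derive_geometry(10, 4.1, 0.3, "segmentation")
  ratio <- g10$amplitude / g2$amplitude
  expect_equal(ratio, g10$rest_radius / g2$rest_radius, tolerance = 1e-12)
  expect_equal(ratio, 1.7, tolerance = 0.02)
})

test_that("non-physical occlusion ratios are rejected with explanation", {
  expect_error(derive_geometry(2, 2.4, 0, "segmentation"), "occlusion_ratio")
  expect_error(derive_geometry(2, 2.4, 1.2, "segmentation"), "occlusion_ratio")
  expect_error(wall_geometry(0.5, 0.5 * sqrt(2), 2.4, "segmentation",
                             period = 5), "sqrt")
})

test_that("correction term: f(0) = 0, zero mean over a period, and Ur at
           z = lambda/4 reduces to f(t)", {
  g <- derive_geometry(2, 2.4, 0.3, "segmentation")
  expect_equal(segmentation_correction(g, 0), 0, tolerance = 1e-14)
  # quadrature of f over one full period vanishes (B is tp-periodic)
  tq <- seq(0, g$period, length.out = 2049)
  w <- lumenflow:::simpson_weights(2048, g$period / 2048)
  expect_lt(abs(sum(w * segmentation_correction(g, tq))),
            1e-12 * max(abs(segmentation_correction(g, tq))) * g$period)
  for (t in c(0.3, 1.2, 4.9)) {
    expect_equal(wall_velocity(g, g$wavelength / 4, t),
                 segmentation_correction(g, t), tolerance = 1e-12)
  }
})

test_that("wall velocity is the exact time derivative of wall radius", {
  g <- derive_geometry(2, 2.4, 0.3, "segmentation")
  zg <- seq(0, 3 * g$wavelength, length.out = 37)
  tg <- seq(0.05, g$period, length.out = 41)
  eps <- 1e-6
  for (t in tg) {
    fd <- (wall_radius(g, zg, t + eps) - wall_radius(g, zg, t - eps)) / (2 * eps)
    expect_equal(fd, wall_velocity(g, zg, t),
                 tolerance = 1e-6 * max(abs(wall_velocity(g, zg, t)), 1e-3))
  }
})

test_that("segmentation conserves luminal volume to 1e-10 at 1000 times", {
  g <- derive_geometry(2, 2.4, 0.3, "segmentation")
  terr <- check_volume_conservation(g, seq(0, g$period, length.out = 1000))
  expect_lt(max(terr), 1e-10)
  # delta = 0 gives exactly zero error
  g0 <- wall_geometry(g$rest_radius, 0, g$wavelength, "segmentation", period = 5)
  expect_equal(max(check_volume_conservation(g0, c(0, 1, 2))), 0)
})

test_that("disabling the correction offset produces the predicted analytic
           volume error", {
  g <- derive_geometry(2, 2.4, 0.3, "segmentation")
  # without B(t): integral pi (r0 + A cos)^2 dz = pi lambda (r0^2 + A^2/2),
  # so the relative error at peak contraction (t = tp/4) is delta^2/(2 r0^2)
  err <- check_volume_conservation(g, g$period / 4, use_offset = FALSE)
  expect_equal(err, g$amplitude^2 / (2 * g$rest_radius^2), tolerance = 1e-6)
})

test_that("wall shapes are periodic in time and space; peristalsis is a pure
           travelling wave", {
  gs <- derive_geometry(2, 2.4, 0.5, "segmentation")
  z <- seq(0, 7.2, length.out = 23); t <- c(0.7, 2.2)
  expect_equal(wall_radius(gs, z, t[1] + gs$period), wall_radius(gs, z, t[1]))
  expect_equal(wall_radius(gs, z + gs$wavelength, t[2]), wall_radius(gs, z, t[2]))
  gp <- derive_geometry(2, 2.4, 0.5, "peristalsis")
  dt <- 0.37
  expect_equal(wall_radius(gp, z, 1 + dt),
               wall_radius(gp, z - gp$wave_speed * dt, 1), tolerance = 1e-12)
})

test_that("intensity presets and volume-wavelength pairing", {
  expect_equal(intensity_levels("light"), list(period = 7, wave_speed = 0.5))
  expect_equal(intensity_levels("moderate"), list(period = 5, wave_speed = 1))
  expect_equal(intensity_levels("vigorous"), list(period = 3, wave_speed = 1.5))
  c2 <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3)
  expect_equal(c2$geometry$wavelength, 2.4)
  c10 <- motility_case("segmentation", "moderate", "water_37C", 10, 0.3)
  expect_equal(c10$geometry$wavelength, 4.1)
  expect_error(motility_case("segmentation", "moderate", "water_37C", 5, 0.3),
               "wavelength")
})
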