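test_that("near-wall fraction of a uniform field matches the annulus ratio", {
  g <- flow_grid(4, 24, 40, stretch = 0)   # uniform radial cells
  R <- 0.5
  h <- rep(R, 24)
  sp <- list(species_model("u", 1, D = 1e-6))
  st <- lumenflow:::new_transport_state(g, h, sp, list(u = matrix(1, 24, 40)), 1)
  st$Vol <- lumenflow:::cell_volumes(g, h)
  st$released <- sum(st$conc[[1]] * st$Vol)
  for (a in c(0.05, 0.12)) {
    pct <- lumenflow:::near_wall_pct_state(st, a)
    expect_equal(pct, 100 * (1 - (1 - a / R)^2), tolerance = 1e-10)
  }
})

test_that("near-wall fraction is ~0 for mass on the axis and errors when the
           layer swallows the lumen", {
  g <- flow_grid(4, 24, 40, stretch = 0)
  h <- rep(0.5, 24)
  cm <- matrix(0, 24, 40); cm[, 1] <- 1   # innermost cells only
  sp <- list(species_model("u", 1, D = 1e-6))
  st <- lumenflow:::new_transport_state(g, h, sp, list(u = cm), 1)
  st$Vol <- lumenflow:::cell_volumes(g, h)
  st$released <- sum(cm * st$Vol)
  expect_equal(lumenflow:::near_wall_pct_state(st, 0.05), 0)
  expect_error(lumenflow:::near_wall_pct_state(st, 0.6), "exceeds")
})

test_that("thin layer percentage never exceeds the thick layer percentage", {
  g <- flow_grid(4, 16, 24, stretch = 2)
  h <- 0.5 + 0.1 * sin(2 * pi * g$zc / 4)
  set.seed(42)
  for (rep in 1:5) {
    cm <- matrix(stats::runif(16 * 24), 16, 24)
    sp <- list(species_model("u", 1, D = 1e-6))
    st <- lumenflow:::new_transport_state(g, h, sp, list(u = cm), 1)
    st$Vol <- lumenflow:::cell_volumes(g, h)
    st$released <- sum(cm * st$Vol)
    thick <- lumenflow:::near_wall_pct_state(st, 0.08)
    thin <- lumenflow:::near_wall_pct_state(st, 0.04)
    expect_lte(thin, thick)
    expect_gte(thin, 0); expect_lte(thick, 100)
  }
})

test_that("escape fraction is 0 for a bolus inside the pocket and 100 in the
           advected-away limit", {
  g <- flow_grid(7.2, 96, 20, stretch = 2)
  h <- rep(0.515, 96)
  case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                        n_periods = 1)
  tr <- initialize_bolus(case, g, h,
                         release = list(z = 3.6, pocket = 2, sigma_b = 0.05))
  esc0 <- lumenflow:::escape_pct_state(tr, 3.6 - 1.2, 3.6 + 1.2)
  expect_lt(max(esc0), 1e-6)
  # all mass removed from the domain (escaped through the ends)
  tr$conc <- lapply(tr$conc, function(cm) cm * 0)
  esc1 <- lumenflow:::escape_pct_state(tr, 3.6 - 1.2, 3.6 + 1.2)
  expect_equal(unname(esc1), rep(100, length(esc1)))
})

test_that("wall concentration extrapolation recovers a prescribed field", {
  g <- flow_grid(4, 16, 24, stretch = 2)
  # field quadratic in eta with zero slope at the wall: c = 3 - (1 - eta)^2
  cm <- matrix(rep(3 - (1 - g$eta)^2, each = 16), 16, 24)
  cw <- lumenflow:::wall_concentration(g, cm)
  expect_equal(cw, rep(3, 16), tolerance = 1e-10)
})

test_that("colocalisation score: bounds, arithmetic and monotonicity", {
  expect_equal(colocalisation_score(1, 1, 0, 0, 0), 1)
  expect_equal(colocalisation_score(0.5, 0.8, 1, 0, 0,
                                    norms = list(t = 1, z = 1, r = 1)), 0.2)
  expect_error(colocalisation_score(1.2, 0.5, 0, 0, 0), "\\[0, 1\\]")
  set.seed(7)
  n <- 500
  cs <- colocalisation_score(runif(n), runif(n), runif(n, 0, 50),
                             runif(n, 0, 5), runif(n, 0, 1),
                             norms = list(t = 150, z = 2.4, r = 0.5))
  expect_true(all(cs >= 0 & cs <= 1))
  # monotone: decreasing in each separation, increasing in each peak
  base <- colocalisation_score(0.6, 0.7, 10, 1, 0.1,
                               norms = list(t = 150, z = 2.4, r = 0.5))
  expect_lt(colocalisation_score(0.6, 0.7, 20, 1, 0.1,
                                 norms = list(t = 150, z = 2.4, r = 0.5)), base)
  expect_lt(colocalisation_score(0.6, 0.7, 10, 2, 0.1,
                                 norms = list(t = 150, z = 2.4, r = 0.5)), base)
  expect_lt(colocalisation_score(0.6, 0.7, 10, 1, 0.3,
                                 norms = list(t = 150, z = 2.4, r = 0.5)), base)
  expect_gt(colocalisation_score(0.8, 0.7, 10, 1, 0.1,
                                 norms = list(t = 150, z = 2.4, r = 0.5)), base)
})

test_that("ensemble normalisation gives at least one case with C = 1 per
           species", {
  fake_result <- function(cmm, cpe, id) {
    case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3)
    structure(list(
      case = case, case_id = id,
      peaks = tibble::tibble(species = c("insulin", "C10"),
                             c_norm = c(cmm, cpe), t = c(10, 12),
                             z_lab = c(3.6, 3.7), r_wall = c(0.5, 0.5))
    ), class = "case_result")
  }
  res <- list(fake_result(0.02, 0.5, 1), fake_result(0.01, 0.8, 2))
  ct <- colocalise(res)
  expect_equal(max(ct$c_mm), 1)
  expect_equal(max(ct$c_pe), 1)
  expect_true(all(ct$cs >= 0 & ct$cs <= 1))
})
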