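# Independent verification oracles: analytic and quadrature references that
# exercise the production solvers without sharing any discretisation code.

#' Poiseuille verification fixture
#'
#' Straight rigid tube driven by a uniform axial pressure gradient (applied
#' as a body force). The analytic steady solution is the parabolic profile
#' \eqn{u_z(r) = G(R^2 - r^2)/(4\mu)} with wall shear \eqn{\tau_w = 4\mu U/R}
#' (U the mean velocity). `run_fixture()` solves the steady problem with the
#' production solver and reports the profile and wall-shear errors.
#'
#' @param radius tube radius (cm).
#' @param length domain length (cm).
#' @param umax target centreline velocity (cm/s); sets the forcing.
#' @param fluid a Newtonian [fluid_model()].
#' @param Nz,Nr,stretch grid controls.
#' @return a `verification_fixture` with fields `name`, `tolerance` and
#'   `run` (function returning the error measures).
#' @export
poiseuille_fixture <- function(radius = 0.5, length = 2, umax = 1,
                               fluid = fluid_registry("water_37C"),
                               Nz = 16, Nr = 24, stretch = 1.5) {
  mu <- fluid$rheology$mu * MPAS_TO_POISE
  G <- 4 * mu * umax / radius^2
  run <- function() {
    prob <- tube_problem(radius, length, fluid, Nz = Nz, Nr = Nr,
                         stretch = stretch,
                         force = function(z, r, t)
                           list(fz = matrix(G / fluid$density, nrow(z), ncol(z)),
                                fr = 0 * z),
                         dt_max = 0.25 * radius^2 / (mu / fluid$density) / 10)
    st <- steady_flow(prob, tol = 1e-6, max_steps = 6000)
    gge <- prob$grid
    uex <- G * (radius^2 - (gge$eta * radius)^2) / (4 * mu)
    err <- max(abs(sweep(st$uz, 2, uex, "-"))) / max(uex)
    fs <- field_state(prob, st)
    ws <- wall_shear_stress(fs)
    tau_exact <- 4 * fluid$rheology$mu * (umax / 2) / radius  # mPa
    list(profile_error = err,
         tau_error = abs(ws$average - tau_exact) / tau_exact,
         tau = ws$average, tau_exact = tau_exact,
         umax = max(st$uz), state = st)
  }
  structure(list(name = "poiseuille", tolerance = 0.01, run = run),
            class = "verification_fixture")
}

#' Lubrication-theory oracle for peristaltic pumping
#'
#' Classical long-wavelength, low-Reynolds analysis of peristaltic transport
#' in an axisymmetric tube. In the wave frame the flux
#' \eqn{q = -\pi h^4 p'/(8\mu) - c\pi h^2} is constant and the zero net
#' pressure rise over one wavelength (free pumping) fixes
#' \eqn{q = -c\pi \langle h^{-2}\rangle / \langle h^{-4}\rangle}; the
#' time-mean laboratory flow rate at a station is
#' \eqn{\bar Q = q + c\pi\langle h^2\rangle}. The averages are evaluated by
#' composite Simpson quadrature over the wave shape, fully independent of
#' the finite-volume solver.
#'
#' @param geom a peristalsis [wall_geometry()].
#' @param n_quad quadrature intervals (even).
#' @return list with `q_wave` (wave-frame flux, cm^3/s), `Q_lab_mean`
#'   (time-mean laboratory flow rate) and the shape averages.
#' @export
lubrication_peristalsis_oracle <- function(geom, n_quad = 2048L) {
  stopifnot(geom$motility == "peristalsis")
  lam <- geom$wavelength
  z <- seq(0, lam, length.out = n_quad + 1L)
  w <- simpson_weights(n_quad, lam / n_quad) / lam
  h <- geom$rest_radius + geom$amplitude * sin(2 * pi * z / lam)
  c_w <- geom$wave_speed
  I2 <- sum(w / h^2)
  I4 <- sum(w / h^4)
  h2m <- sum(w * h^2)
  q <- -c_w * pi * I2 / I4
  list(q_wave = q, Q_lab_mean = q + c_w * pi * h2m,
       mean_h2 = h2m, I2 = I2, I4 = I4)
}

#' Gaussian-diffusion verification fixture
#'
#' Static cylinder, zero flow: an isotropic Gaussian bolus must spread with
#' variance \eqn{\sigma^2(t) = \sigma_b^2 + 2Dt} along every axis. The
#' fixture integrates the production transport module and compares the axial
#' variance of the mass distribution against the analytic law.
#'
#' @param D diffusivity (cm^2/s); deliberately large so the growth is well
#'   resolved within a short run.
#' @param t_end integration time (s).
#' @param radius,length domain size (cm).
#' @param sigma_b initial bolus standard deviation (cm).
#' @param Nz,Nr grid controls.
#' @return a `verification_fixture`.
#' @export
diffusion_fixture <- function(D = 1e-4, t_end = 30, radius = 0.515,
                              length = 7.2, sigma_b = 0.0515,
                              Nz = 96, Nr = 20) {
  run <- function() {
    sp <- species_model("tracer", 1, D = D)
    case <- motility_case("segmentation", "moderate", "water_37C", 2, 0.3,
                          species = list(sp))
    g <- flow_grid(length, Nz, Nr, 2.2)
    h <- rep(radius, Nz)
    tr <- initialize_bolus(case, g, h,
                           release = list(z = length / 2, pocket = 2,
                                          sigma_b = sigma_b))
    m0 <- total_moles(tr)
    zvar <- function(st) {
      M <- st$conc[[1]] * st$Vol
      zm <- matrix(st$grid$zc, st$grid$Nz, st$grid$Nr)
      zb <- sum(M * zm) / sum(M)
      sum(M * (zm - zb)^2) / sum(M)
    }
    v0 <- zvar(tr)
    tr2 <- advance_concentration(tr, h = h, t_end = t_end,
                                 fluid = case$fluid, closed = TRUE)
    v1 <- zvar(tr2)
    pred <- v0 + 2 * D * t_end
    list(variance_error = abs(v1 - pred) / pred,
         mass_error = abs(total_moles(tr2)[1] / m0[1] - 1),
         min_conc = min(tr2$conc[[1]]),
         released_error = abs(m0[1] / ((2 * pi * sigma_b^2)^1.5) - 1))
  }
  structure(list(name = "diffusion", tolerance = 0.01, run = run),
            class = "verification_fixture")
}

#' Manufactured-solution convergence fixture
#'
#' A divergence-free manufactured velocity field (built from a Stokes
#' streamfunction) and a smooth pressure are substituted into the
#' axisymmetric Navier-Stokes equations; the residual becomes a body-force
#' source term, evaluated by high-accuracy finite differences of the
#' closed-form fields (independent of the solver's discretisation). The
#' solver is marched to steady state on a sequence of grids and the observed
#' convergence order of the velocity error is reported.
#'
#' @param radius,length domain size (cm).
#' @param V0 velocity scale (cm/s).
#' @param mu viscosity (mPa*s); high, so the steady state is reached fast.
#' @param grids list of `c(Nz, Nr)` grid sizes, coarse to fine.
#' @return a `verification_fixture`; `run()` returns per-grid L2 errors and
#'   the observed orders between consecutive grids.
#' @export
manufactured_solution_fixture <- function(radius = 1, length = 4, V0 = 0.3,
                                          mu = 80,
                                          grids = list(c(16, 10), c(32, 20),
                                                       c(64, 40))) {
  rho <- 1
  fluid <- fluid_model("mms_fluid", density = rho, mu = mu)
  muP <- mu * MPAS_TO_POISE
  k <- 2 * pi / length
  uz_ex <- function(z, r) {
    s <- r / radius
    V0 * 2 * (1 - s^2) * (1 - 3 * s^2) * sin(k * z)
  }
  ur_ex <- function(z, r) {
    s <- r / radius
    -V0 * k * radius * s * (1 - s^2)^2 * cos(k * z)
  }
  p_ex <- function(z, r) cos(k * z) * (1 - (r / radius)^2)^2

  dd <- function(f, z, r, dz_ = 0, dr_ = 0) {
    # central finite differences of the analytic fields (tiny steps; the
    # oracle's own differentiation, not the solver's)
    hz <- 1e-5 * length; hr <- 1e-5 * radius
    if (dz_ == 1) return((f(z + hz, r) - f(z - hz, r)) / (2 * hz))
    if (dz_ == 2) return((f(z + hz, r) - 2 * f(z, r) + f(z - hz, r)) / hz^2)
    if (dr_ == 1) return((f(z, r + hr) - f(z, r - hr)) / (2 * hr))
    if (dr_ == 2) return((f(z, r + hr) - 2 * f(z, r) + f(z, r - hr)) / hr^2)
    f(z, r)
  }
  force <- function(z, r, t) {
    uz <- uz_ex(z, r); ur <- ur_ex(z, r)
    uz_z <- dd(uz_ex, z, r, dz_ = 1); uz_r <- dd(uz_ex, z, r, dr_ = 1)
    ur_z <- dd(ur_ex, z, r, dz_ = 1); ur_r <- dd(ur_ex, z, r, dr_ = 1)
    lap_uz <- dd(uz_ex, z, r, dr_ = 2) + uz_r / r + dd(uz_ex, z, r, dz_ = 2)
    lap_ur <- dd(ur_ex, z, r, dr_ = 2) + ur_r / r + dd(ur_ex, z, r, dz_ = 2) -
      ur / r^2
    fz <- uz * uz_z + ur * uz_r + dd(p_ex, z, r, dz_ = 1) / rho -
      (muP / rho) * lap_uz
    fr <- uz * ur_z + ur * ur_r + dd(p_ex, z, r, dr_ = 1) / rho -
      (muP / rho) * lap_ur
    list(fz = fz, fr = fr)
  }
  run_one <- function(Nz, Nr) {
    prob <- tube_problem(radius, length, fluid, Nz = Nz, Nr = Nr,
                         stretch = 1.0, force = force,
                         dt_max = 0.02 * radius^2 / (muP / rho))
    st <- steady_flow(prob, tol = 5e-7, max_steps = 8000, uscale = V0)
    gge <- prob$grid
    rmat <- gge$eta_mat * radius
    zmat <- matrix(gge$zc, gge$Nz, gge$Nr)
    Vol <- cell_volumes(gge, rep(radius, gge$Nz))
    e2 <- (st$uz - uz_ex(zmat, rmat))^2 + (st$ur - ur_ex(zmat, rmat))^2
    sqrt(sum(e2 * Vol) / sum(Vol)) / V0
  }
  run <- function() {
    errs <- vapply(grids, function(gr) run_one(gr[1], gr[2]), numeric(1))
    orders <- log2(errs[-length(errs)] / errs[-1])
    list(errors = errs, orders = orders,
         grids = vapply(grids, paste, "", collapse = "x"))
  }
  structure(list(name = "manufactured_solution", tolerance = 2,
                 run = run, exact = list(uz = uz_ex, ur = ur_ex, p = p_ex)),
            class = "verification_fixture")
}

#' Synthetic parameter-sweep generator with planted factor effects
#'
#' Generates a full-factorial sweep table over the six variability factors
#' (motility type, intensity, fluid, pocket volume, occlusion ratio, release
#' position) with a colocalisation score built from planted additive
#' effects plus Gaussian noise. Used to verify end to end that the
#' clustering and gradient-boosted attribution pipeline recovers a known
#' dominant factor.
#'
#' @param seed RNG seed.
#' @param effects named effect sizes on the CS scale for
#'   `pocket_volume`, `occlusion_ratio`, `motility`, `fluid`, `intensity`,
#'   `release`. The default ordering mirrors the dominant factors of the
#'   motility study (volume > contractility > motility type).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_rep replicates of the factorial (adds jittered copies).
#' @return a tibble shaped like a [run_sweep()] table (class `sweep_table`).
#' @export
synthetic_sweep_fixture <- function(seed = 1,
                                    effects = c(pocket_volume = 0.30,
                                                occlusion_ratio = 0.18,
                                                motility = 0.12,
                                                fluid = 0.06,
                                                intensity = 0.04,
                                                release = 0.02),
                                    noise_sd = 0.04, n_rep = 1L) {
  set.seed(seed)
  grid <- expand.grid(
    motility = c("segmentation", "peristalsis"),
    intensity = c("light", "moderate", "vigorous"),
    fluid = c("water_37C", "nutridrink_default"),
    pocket_volume = c(2, 10),
    occlusion_ratio = c(0.3, 0.5, 0.7),
    release = c("most_occluded", "least_occluded"),
    stringsAsFactors = FALSE
  )
  grid <- grid[rep(seq_len(nrow(grid)), n_rep), ]
  cs <- 0.15 +
    effects["pocket_volume"] * (grid$pocket_volume == 2) +
    effects["occlusion_ratio"] * (0.7 - grid$occlusion_ratio) / 0.4 +
    effects["motility"] * (grid$motility == "segmentation") +
    effects["fluid"] * (grid$fluid == "nutridrink_default") +
    effects["intensity"] * (grid$intensity == "light") +
    effects["release"] * (grid$release == "most_occluded") +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid$cs <- pmin(pmax(cs, 1e-3), 1)
  out <- tibble::as_tibble(grid)
  out$case_id <- seq_len(nrow(out))
  class(out) <- c("sweep_table", class(out))
  out
}

#' Optimal 1-D clustering by dynamic programming
#'
#' Exact minimiser of the within-cluster sum of squares for one-dimensional
#' data (the 1-D K-means objective), by the standard O(k n^2) dynamic
#' programme over sorted values. Serves as the independent oracle for the
#' K-means clustering of colocalisation scores.
#'
#' @param x numeric vector.
#' @param k number of clusters.
#' @return list with `cluster` (assignments in sorted-mean order),
#'   `centers`, and the optimal `withinss`.
#' @export
optimal_1d_clustering <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ssq <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) { D[1, j] <- ssq(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; barg <- q
        for (i in q:j) {
          v <- D[q - 1, i - 1] + ssq(i, j)
          if (v < best) { best <- v; barg <- i }
        }
        D[q, j] <- best; B[q, j] <- barg
      }
    }
  }
  bounds <- integer(k + 1L); bounds[k + 1L] <- n
  j <- n
  for (q in k:1) { i <- B[q, j]; bounds[q] <- i - 1L; j <- i - 1L }
  cl_sorted <- integer(n)
  for (q in 1:k) cl_sorted[(bounds[q] + 1L):bounds[q + 1L]] <- q
  cl <- integer(n); cl[o] <- cl_sorted
  centers <- vapply(1:k, function(q) mean(xs[cl_sorted == q]), numeric(1))
  list(cluster = cl, centers = centers, withinss = D[k, n])
}

#' @export
print.verification_fixture <- function(x, ...) {
  cat(sprintf("<verification_fixture> %s (tolerance %g)\n", x$name, x$tolerance))
  invisible(x)
}
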