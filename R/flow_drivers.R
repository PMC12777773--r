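# Drivers around the core time stepper: transient runs, steady (pseudo-time)
# solves, problem builders for the motility cases and verification fixtures,
# field snapshots and wall shear stress.

# ---- problem builders ----------------------------------------------------

# flow problem for a segmentation case (lab frame, moving wall, periodic z).
# The wall kinematics are lambda-periodic, so the flow can be solved on any
# number of wavelengths; run_case() solves one wavelength and tiles the
# fluxes over the full pocket count for the transport stage.
segmentation_problem <- function(case, resolution = "coarse",
                                 n_wavelengths = NULL) {
  res <- resolution_preset(resolution)
  geom <- case$geometry
  n_wavelengths <- n_wavelengths %||% geom$n_pockets
  L <- n_wavelengths * geom$wavelength
  g <- flow_grid(L, res$nz_per_wavelength * n_wavelengths, res$nr, res$stretch)
  nu <- effective_viscosity(case$fluid, reference_shear_rate(case)) *
    MPAS_TO_POISE / case$fluid$density
  dt_visc <- 0.05 * geom$rest_radius^2 / nu   # resolve smooth-mode relaxation
  new_flow_problem(
    g, case$fluid,
    hfun = function(z, t) wall_radius(geom, z, t),
    htfun = function(z, t) wall_velocity(geom, z, t),
    hzfun = function(z, t) wall_slope(geom, z, t),
    wall_uz = function(z, t) rep_len(0, length(z)),
    wall_ur = function(z, t) wall_velocity(geom, z, t),
    moving = TRUE, cfl = res$cfl,
    dt_max = min(geom$period * res$dt_max_frac, dt_visc)
  )
}

# flow problem for one peristaltic wavelength in the wave frame: static wall
# shape h(z) = r0 + delta sin(2 pi z / lambda); wall material moves with
# (-c, -c h') in this frame (no-slip, radial-only motion in the lab frame)
peristalsis_problem <- function(case, resolution = "coarse") {
  res <- resolution_preset(resolution)
  geom <- case$geometry
  lam <- geom$wavelength
  g <- flow_grid(lam, res$nz_per_wavelength, res$nr, res$stretch)
  c_w <- geom$wave_speed
  hz0 <- function(z) geom$amplitude * (2 * pi / lam) * cos(2 * pi * z / lam)
  # resolve the viscous relaxation of the smooth radial modes (the
  # pressure-viscous splitting of the projection scheme is O(dt) only when
  # nu dt (pi/r0)^2 < ~0.5)
  nu <- effective_viscosity(case$fluid, reference_shear_rate(case)) *
    MPAS_TO_POISE / case$fluid$density
  dt_visc <- 0.05 * geom$rest_radius^2 / nu
  new_flow_problem(
    g, case$fluid,
    hfun = function(z, t) geom$rest_radius + geom$amplitude * sin(2 * pi * z / lam),
    htfun = function(z, t) rep_len(0, length(z)),
    hzfun = function(z, t) hz0(z),
    wall_uz = function(z, t) rep_len(-c_w, length(z)),
    wall_ur = function(z, t) -c_w * hz0(z),
    moving = FALSE, cfl = res$cfl,
    dt_max = min(geom$period * res$dt_max_frac * 20, dt_visc)
  )
}

# straight rigid tube of radius R, periodic in z, optional body force:
# harness for the Poiseuille and manufactured-solution fixtures
tube_problem <- function(R, L, fluid, Nz = 32, Nr = 24, stretch = 1.5,
                         force = NULL, cfl = 0.4, dt_max = Inf) {
  g <- flow_grid(L, Nz, Nr, stretch)
  new_flow_problem(
    g, fluid,
    hfun = function(z, t) rep_len(R, length(z)),
    htfun = function(z, t) rep_len(0, length(z)),
    hzfun = function(z, t) rep_len(0, length(z)),
    wall_uz = function(z, t) rep_len(0, length(z)),
    wall_ur = function(z, t) rep_len(0, length(z)),
    force = force, moving = FALSE, cfl = cfl, dt_max = dt_max
  )
}

# ---- drivers -------------------------------------------------------------

# march a flow problem to t_end; optionally store snapshots and per-step
# diagnostics. `on_step(st0, st1, prob)` runs after every accepted step
# (used for coupled scalar transport and online metrics).
run_flow <- function(prob, t_end, state = NULL, dt_init = NULL,
                     snapshot_every = NULL, on_step = NULL,
                     diagnostics = FALSE) {
  st <- state %||% flow_initial_state(prob)
  dt <- dt_init %||% min(prob$dt_max, 1e-2)
  snaps <- list()
  next_snap <- if (!is.null(snapshot_every)) st$t + snapshot_every else Inf
  diag_rows <- list()
  while (st$t < t_end - 1e-12) {
    dt_step <- min(dt, t_end - st$t, next_snap - st$t + 1e-12)
    st1 <- flow_step(prob, st, dt_step)
    if (!is.null(on_step)) on_step(st, st1, prob)
    st <- st1
    if (diagnostics) {
      diag_rows[[length(diag_rows) + 1L]] <- c(
        t = st$t, dt = st$dt_used, cfl = st$cfl, div = st$div_norm,
        umax = max(sqrt(st$uz^2 + st$ur^2))
      )
    }
    if (st$t >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- field_state(prob, st)
      next_snap <- next_snap + snapshot_every
    }
    dt <- next_dt(prob, st, dt_step)
  }
  diag <- if (length(diag_rows)) {
    tibble::as_tibble(do.call(rbind, diag_rows))
  } else NULL
  list(state = st, snapshots = snaps, diagnostics = diag)
}

# pseudo-time march to steady state (static geometry problems);
# min_time guards against declaring convergence before the slow transients
# (axial momentum diffusion, advective turnover) have had a chance to act
steady_flow <- function(prob, tol = 1e-5, max_steps = 20000L, dt_init = NULL,
                        uscale = NULL, min_time = 0, quiet = TRUE) {
  st <- flow_initial_state(prob)
  dt <- dt_init %||% min(prob$dt_max, 1e-2)
  res <- Inf
  for (k in seq_len(max_steps)) {
    st1 <- flow_step(prob, st, dt)
    us <- uscale %||% max(abs(st1$uz), abs(st1$ur), 1e-8)
    res <- max(abs(st1$uz - st$uz), abs(st1$ur - st$ur)) / (dt * us)
    st <- st1
    if (res < tol && st$t >= min_time) break
    dt <- next_dt(prob, st, dt)
  }
  if (res >= tol && !quiet) {
    warning("steady_flow: residual ", signif(res, 3), " after ", max_steps,
            " steps (tol ", tol, ")")
  }
  st$steady_residual <- res
  st
}

# ---- snapshots and derived quantities -----------------------------------

#' Field snapshot of the flow solution
#'
#' Collects the instantaneous velocity, pressure and shear-rate fields on the
#' boundary-fitted grid into a `field_state` object. Velocities are in the
#' frame the problem was solved in (`frame` attribute); peristaltic
#' wave-frame states are converted with [lab_frame()].
#'
#' @keywords internal
field_state <- function(prob, st, frame = "lab", wave_speed = NULL) {
  g <- prob$grid
  uzw <- prob$wall_uz(g$zc, st$t); urw <- prob$wall_ur(g$zc, st$t)
  m <- g$eta_mat * matrix(st$geom$hz / st$geom$h, g$Nz, g$Nr)
  shear <- shear_rate_field(g, st$uz, st$ur, st$geom$h, st$geom$hz, m, uzw, urw)
  structure(list(
    time = st$t, z = g$zc, eta = g$eta, h = st$geom$h,
    hz = st$geom$hz, ht = st$geom$ht,
    uz = st$uz, ur = st$ur, p = st$p, shear_rate = shear,
    wall_uz = uzw, wall_ur = urw,
    fluid = prob$fluid, grid = g, frame = frame, wave_speed = wave_speed,
    div_norm = st$div_norm
  ), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "<field_state> t = %.3f s, %d x %d cells, |u|max = %.3f cm/s (%s frame)\n",
    x$time, length(x$z), length(x$eta), max(sqrt(x$uz^2 + x$ur^2)), x$frame
  ))
  invisible(x)
}

#' Transform a wave-frame peristaltic field to the laboratory frame
#'
#' The lab-frame axial velocity is the wave-frame velocity plus the wave
#' speed; radial velocity and pressure are frame-invariant.
#'
#' @param state a `field_state` in the wave frame.
#' @return a `field_state` in the lab frame.
#' @export
lab_frame <- function(state) {
  stopifnot(inherits(state, "field_state"))
  if (identical(state$frame, "lab")) return(state)
  c_w <- state$wave_speed
  state$uz <- state$uz + c_w
  state$wall_uz <- state$wall_uz + c_w
  state$frame <- "lab"
  state
}

#' Solve the transient segmentation flow of a motility case
#'
#' Marches the axisymmetric incompressible Navier-Stokes equations on the
#' deforming 3-wavelength periodic lumen with the wall motion prescribed by
#' the case's segmentation kinematics. Power-law viscosity is evaluated from
#' the local shear rate at every step.
#'
#' @param case a segmentation [motility_case()].
#' @param resolution preset name or list, see [resolution_preset()].
#' @param n_periods number of periods to simulate (default: the case's).
#' @param snapshots_per_period snapshots of the full field per period.
#' @param diagnostics keep per-step scalar diagnostics (CFL, divergence
#'   norm, max velocity) as a tibble?
#' @return a list of class `flow_history`: `snapshots` (list of
#'   `field_state`), `final` state, `diagnostics`, `case`.
#' @export
solve_segmentation_flow <- function(case, resolution = "coarse",
                                    n_periods = NULL,
                                    snapshots_per_period = 4,
                                    diagnostics = FALSE) {
  stopifnot(inherits(case, "motility_case"), case$motility == "segmentation")
  n_periods <- n_periods %||% case$n_periods
  prob <- segmentation_problem(case, resolution)
  tp <- case$geometry$period
  out <- run_flow(prob, n_periods * tp,
                  snapshot_every = tp / snapshots_per_period,
                  diagnostics = diagnostics)
  structure(list(snapshots = out$snapshots,
                 final = field_state(prob, out$state),
                 diagnostics = out$diagnostics,
                 case = case, problem = prob),
            class = "flow_history")
}

#' Solve the steady peristaltic flow in the wave frame
#'
#' Solves the steady incompressible flow over one wavelength in the frame
#' moving with the peristaltic wave (periodic ends, zero net pressure rise
#' per wavelength: free pumping). The lab-frame field is obtained by adding
#' the wave speed to the axial component ([lab_frame()]).
#'
#' @param case a peristalsis [motility_case()].
#' @param resolution preset name or list.
#' @param tol steady-state residual tolerance (relative velocity change per
#'   advective time unit).
#' @param max_steps pseudo-time step budget.
#' @return a `field_state` in the wave frame (attributes carry the wave
#'   speed); use [lab_frame()] for laboratory-frame velocities.
#' @export
solve_peristalsis_flow <- function(case, resolution = "coarse",
                                   tol = 2e-4, max_steps = 20000L) {
  stopifnot(inherits(case, "motility_case"), case$motility == "peristalsis")
  prob <- peristalsis_problem(case, resolution)
  geom <- case$geometry
  nu <- effective_viscosity(case$fluid, reference_shear_rate(case)) *
    MPAS_TO_POISE / case$fluid$density
  # slowest transient: viscous relaxation in the Stokes regime, advective
  # turnover plus radial diffusion when inertia matters
  tmin <- if (reynolds_number(case) < 1) {
    min(geom$wavelength^2 / (4 * nu), 50 * geom$rest_radius^2 / nu)
  } else {
    max(5 * geom$period, geom$rest_radius^2 / nu)
  }
  st <- steady_flow(prob, tol = tol, max_steps = max_steps,
                    uscale = case$geometry$wave_speed, min_time = tmin)
  fs <- field_state(prob, st, frame = "wave",
                    wave_speed = case$geometry$wave_speed)
  fs$fluxZ <- st$fluxZ
  fs$fluxE <- st$fluxE
  fs$Vol <- st$Vol1
  fs$steady_residual <- st$steady_residual
  fs
}

#' Wall shear stress along the epithelial surface
#'
#' Evaluates the tangential shear rate at the wall from a one-sided
#' quadratic fit of the tangential velocity along the wall normal (using the
#' no-slip wall value), multiplies by the local apparent viscosity, and
#' returns the axial profile with its area-weighted surface average and
#' maximum.
#'
#' @param state a `field_state`.
#' @param fluid a [fluid_model()]; defaults to the state's fluid.
#' @return a list with `profile` (tibble: z, shear_rate, tau_mPa),
#'   `average` and `max` wall shear stress in mPa.
#' @export
wall_shear_stress <- function(state, fluid = NULL) {
  stopifnot(inherits(state, "field_state"))
  fluid <- fluid %||% state$fluid
  g <- state$grid
  Nr <- g$Nr
  hz <- state$hz
  sq <- sqrt(1 + hz^2)
  ut <- function(uz, ur) (uz + ur * hz) / sq   # tangential component, per column
  utw <- ut(state$wall_uz, state$wall_ur)
  u1 <- (state$uz[, Nr] + state$ur[, Nr] * hz) / sq
  u2 <- (state$uz[, Nr - 1] + state$ur[, Nr - 1] * hz) / sq
  x1 <- (1 - g$eta[Nr]) * state$h / sq          # normal distances from wall
  x2 <- (1 - g$eta[Nr - 1]) * state$h / sq
  dudn <- (u1 - utw) / x1 * (x2 / (x2 - x1)) - (u2 - utw) / x2 * (x1 / (x2 - x1))
  gw <- abs(dudn)
  tau <- effective_viscosity(fluid, gw) * gw    # mPa (viscosity mPa*s x 1/s)
  dA <- state$h * sq                            # area weight per unit z
  list(
    profile = tibble::tibble(z = state$z, shear_rate = gw, tau_mPa = tau),
    average = sum(tau * dA) / sum(dA),
    max = max(tau)
  )
}

#' Reynolds number of a case
#'
#' \eqn{Re = \rho U r_0 / \mu_{ref}} with U the characteristic wall/wave
#' speed and \eqn{\mu_{ref}} the apparent viscosity at the case's reference
#' shear rate. All simulated configurations are laminar (Re well below 2000).
#'
#' @param case a [motility_case()].
#' @param umax optionally, a measured peak velocity (cm/s) to use for U.
#' @return Reynolds number (dimensionless).
#' @export
reynolds_number <- function(case, umax = NULL) {
  geom <- case$geometry
  U <- umax %||% if (case$motility == "segmentation") {
    two_pi * geom$amplitude / geom$period
  } else {
    geom$wave_speed
  }
  mu <- effective_viscosity(case$fluid, reference_shear_rate(case)) * MPAS_TO_POISE
  case$fluid$density * U * geom$rest_radius / mu
}

`%||%` <- function(a, b) if (is.null(a)) b else a
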