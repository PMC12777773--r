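# Two-species advection-diffusion on the moving mapped grid.
#
# Conservative finite-volume transport driven by the projected face volume
# fluxes of the flow solver. Advection uses dimension-split PPM (piecewise
# parabolic, monotonized) sweeps: each 1-D sweep is monotone (positivity),
# exactly conservative, and the splitting carries intermediate cell volumes
# so that a uniform field in an incompressible flow stays uniform to
# round-off including the moving-mesh geometric terms. The low numerical
# diffusion of PPM matters here: the motility cases are convection
# dominated (Pe >> 1) and near-wall delivery rides on thin filaments that
# low-order upwinding would smear away. Diffusion is explicit (diffusive
# time steps are far above advective ones for macromolecules). Axial ends
# are open: first-order advective outflow, zero diffusive flux,
# zero-concentration inflow.

#' Release specification for the dissolved bolus
#'
#' The bolus is an isotropic Gaussian in (z, r) about the centreline with
#' standard deviation `sigma_b`, released instantaneously at t = 0 at the
#' case's release position; each species' peak concentration is its initial
#' concentration.
#'
#' @param case a [motility_case()].
#' @param sigma_b bolus standard deviation (cm); default r0/10.
#' @return a list with the release position and width.
#' @export
release_spec <- function(case, sigma_b = NULL) {
  geom <- case$geometry
  auto <- is.null(sigma_b)
  sigma_b <- sigma_b %||% (geom$rest_radius / 10)
  pos <- release_position(case)
  list(z = pos$z, pocket = pos$pocket, sigma_b = sigma_b, auto = auto)
}

# transport state: own grid (may be a refined axial tiling of the flow
# grid), per-species concentration matrices, released and escaped moles
new_transport_state <- function(grid, h, species, conc, released) {
  list(grid = grid, h = h, species = species, conc = conc,
       released = released, escaped = rep(0, length(species)),
       t = 0, flip = FALSE)
}

#' Initialise the dissolved bolus of all species of a case
#'
#' Both species share the same bolus geometry; cells receive exact cell
#' averages (erf integrals axially, annulus integrals radially), so the
#' released moles match the closed-form Gaussian integral
#' \eqn{c_i (2\pi)^{3/2}\sigma_b^3} at any resolution.
#'
#' @param case a [motility_case()].
#' @param grid the transport [flow_grid()].
#' @param h wall radius per axial cell at t = 0 (cm).
#' @param release a [release_spec()]; default from the case.
#' @return a `transport_state` with one concentration matrix per species.
#' @export
initialize_bolus <- function(case, grid, h, release = NULL) {
  release <- release %||% release_spec(case)
  sb <- release$sigma_b
  z0 <- release$z
  # the bolus must sit fully inside the lumen: the default width shrinks in
  # narrow release sites (e.g. the peristaltic trough) so that 3 sigma stays
  # within three quarters of the local lumen radius; an explicit user width
  # that overlaps the wall is an error instead
  zr <- abs(grid$zc - z0) <= 3 * sb
  if (!any(zr)) stop("release position lies outside the transport domain")
  if (isTRUE(release$auto)) {
    sb <- min(sb, 0.25 * min(h[zr]))
    zr <- abs(grid$zc - z0) <= 3 * sb
  }
  if (min(h[zr]) <= 3 * sb) {
    stop("bolus (3 sigma = ", signif(3 * sb, 3),
         " cm) would overlap the wall (min lumen radius ",
         signif(min(h[zr]), 3), " cm at the release site)")
  }
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  zl <- grid$zc - grid$dz / 2
  zr2 <- grid$zc + grid$dz / 2
  fz <- sb * sqrt(pi / 2) *
    (erf((zr2 - z0) / (sb * sqrt(2))) - erf((zl - z0) / (sb * sqrt(2)))) / grid$dz
  rlo2 <- outer(h^2, grid$etaf[-(grid$Nr + 1)]^2)
  rhi2 <- outer(h^2, grid$etaf[-1]^2)
  fr <- sb^2 * (exp(-rlo2 / (2 * sb^2)) - exp(-rhi2 / (2 * sb^2))) /
    ((rhi2 - rlo2) / 2)
  shape <- matrix(fz, grid$Nz, grid$Nr) * fr
  Vol <- cell_volumes(grid, h)
  conc <- lapply(case$species, function(sp) sp$initial_concentration * shape)
  names(conc) <- vapply(case$species, `[[`, "", "name")
  released <- vapply(conc, function(cm) sum(cm * Vol), numeric(1))
  st <- new_transport_state(grid, h, case$species, conc, released)
  st$Vol <- Vol
  st
}

cell_volumes <- function(grid, h) {
  pi * outer(h^2, diff(grid$etaf^2)) * grid$dz
}

# ---- PPM sweeps (compiled kernels in src/ppm_sweeps.cpp) ----------------

# build the eta edge-interpolation plan for a grid (4-point nonuniform
# cubic weights per interior face; reduced stencils at the ends)
ppm_eta_plan <- function(eta, Nr, etaf) {
  idx <- matrix(1L, Nr - 1L, 4)
  wt <- matrix(0, Nr - 1L, 4)
  for (j in seq_len(Nr - 1L)) {
    x <- etaf[j + 1L]
    ks <- (j - 1L):(j + 2L)
    ks <- ks[ks >= 1L & ks <= Nr]
    if (length(ks) < 2) ks <- c(j, j + 1L)
    xk <- eta[ks]
    for (m in seq_along(ks)) {
      idx[j, m] <- ks[m]
      wt[j, m] <- prod((x - xk[-m]) / (xk[m] - xk[-m]))
    }
  }
  list(idx = idx, wt = wt)
}

# conservative PPM sweep along zeta; Fz rows are right faces (row Nz = open
# right end), FzL the left-end face fluxes
sweep_z <- function(g, cm, Fz, FzL, V_in, dt) {
  out <- ppm_sweep_z_cpp(cm, Fz, FzL, V_in, dt)
  list(c = out$c, V = out$V, escaped = out$escaped)
}

# conservative PPM sweep along eta; interior faces only (axis and wall
# carry no flux)
sweep_eta <- function(g, cm, Fe, V_in, dt) {
  out <- ppm_sweep_eta_cpp(cm, Fe, V_in, dt, g$ppm_eta$idx, g$ppm_eta$wt)
  list(c = out$c, V = out$V)
}

# explicit conservative diffusion update on geometry h (static within the
# update); cross-derivative terms included for the slanted eta faces
diffuse <- function(g, cm, sp, h, hz, Vol, dt, fluid, reference_shear) {
  Nz <- g$Nz; Nr <- g$Nr
  Dcell <- matrix(species_diffusivity(sp, pmax(as.vector(cm), 0), fluid,
                                      reference_shear), Nz, Nr)
  hmmat <- matrix(h, Nz, Nr)
  etaf_i <- g$etaf[2:Nr]
  # zeta faces (interior)
  Df_z <- (Dcell[-Nz, , drop = FALSE] + Dcell[-1, , drop = FALSE]) / 2
  dAz <- pi * outer(((h[-Nz] + h[-1]) / 2)^2, diff(g$etaf^2))
  gz <- (cm[-1, , drop = FALSE] - cm[-Nz, , drop = FALSE]) / g$dz
  dif_z <- -Df_z * gz * dAz
  # eta faces
  Df_e <- Dcell[, -Nr, drop = FALSE] * g$one_wfM +
    Dcell[, -1, drop = FALSE] * g$wfM
  mf <- outer(hz, etaf_i)
  gete <- (cm[, -1, drop = FALSE] - cm[, -Nr, drop = FALSE]) * g$inv_detafM
  dcz <- rbind((cm[2, ] - cm[1, ]) / g$dz,
               (cm[-(1:2), , drop = FALSE] -
                  cm[1:(Nz - 2), , drop = FALSE]) / (2 * g$dz),
               (cm[Nz, ] - cm[Nz - 1, ]) / g$dz)
  dcz_f <- dcz[, -Nr, drop = FALSE] * g$one_wfM + dcz[, -1, drop = FALSE] * g$wfM
  grad_n <- (1 + mf^2) * gete / hmmat[, -Nr, drop = FALSE] - mf * dcz_f
  areaE <- 2 * pi * g$dz * outer(h, etaf_i)
  dif_e <- -Df_e * grad_n * areaE
  net <- rbind(dif_z, 0) - rbind(0, dif_z) + cbind(dif_e, 0) - cbind(0, dif_e)
  cm - dt * net / Vol
}

# one full transport step: alternating-order PPM sweeps plus diffusion.
# Fz: Nz x Nr fluid fluxes on right faces (row Nz = open right end);
# Fe: Nz x (Nr-1) total eta-face fluxes (fluid + mesh motion);
# Vol0/Vol1: cell volumes before/after; h0,h1,hz: wall geometry.
scalar_step <- function(st, Fz, Fe, Vol0, Vol1, h0, h1, hz, dt, fluid,
                        reference_shear, open_left_flux = NULL) {
  g <- st$grid
  FzL <- open_left_flux %||% Fz[g$Nz, ]
  hm <- (h0 + h1) / 2
  for (s in seq_along(st$species)) {
    cm <- st$conc[[s]]
    if (st$flip) {
      swe <- sweep_eta(g, cm, Fe, Vol0, dt)
      swz <- sweep_z(g, swe$c, Fz, FzL, swe$V, dt)
      cm <- swz$c
    } else {
      swz <- sweep_z(g, cm, Fz, FzL, Vol0, dt)
      swe <- sweep_eta(g, swz$c, Fe, swz$V, dt)
      cm <- swe$c
    }
    cm <- diffuse(g, cm, st$species[[s]], hm, hz, Vol1, dt, fluid,
                  reference_shear)
    # positivity limiter: clip the tiny undershoots of the split scheme and
    # restore the clipped mass by a global rescale (conservative)
    neg <- cm < 0
    if (any(neg)) {
      m_pre <- sum(cm * Vol1)
      cm[neg] <- 0
      m_post <- sum(cm * Vol1)
      if (m_post > 0) cm <- cm * (m_pre / m_post)
    }
    st$conc[[s]] <- cm
    st$escaped[s] <- st$escaped[s] + dt * swz$escaped
  }
  st$flip <- !st$flip
  st$h <- h1
  st$Vol <- Vol1
  st$t <- st$t + dt
  st
}

# stable scalar sub-step count for frozen fluxes
scalar_substeps <- function(st, Fz, Fe, Vol, dt, cfl = 0.85) {
  Nz <- nrow(Fz)
  outz <- pmax(Fz, 0) - pmin(rbind(Fz[Nz, ], Fz[-Nz, , drop = FALSE]), 0)
  oute <- pmax(cbind(Fe, 0), 0) - pmin(cbind(0, Fe), 0)
  rate <- max(outz / Vol, oute / Vol)
  max(1L, ceiling(dt * rate / cfl))
}

#' Advance a concentration state with a frozen flow field
#'
#' Integrates the conservative advection-diffusion update over `t_end` using
#' the face volume fluxes of a single (steady or frozen) `field_state`.
#' Intended for steady wave-frame transport and for verification fixtures
#' (zero-velocity diffusion, solenoidal test fields); the fully coupled
#' moving-wall path used by [run_case()] advances the scalars inside the
#' flow loop instead.
#'
#' @param st a transport state from [initialize_bolus()].
#' @param Fz,Fe face volume fluxes (cm^3/s) on the transport grid; `NULL`
#'   for pure diffusion.
#' @param h wall radius per axial cell (static for this entry point).
#' @param hz wall slope per axial cell.
#' @param t_end integration time (s).
#' @param dt time step (s); sub-stepped further if the flux CFL demands it.
#' @param fluid the carrying [fluid_model()].
#' @param reference_shear reference shear rate for Stokes-Einstein scaling.
#' @param closed treat the axial ends as walls (no advective or diffusive
#'   flux) instead of open boundaries?
#' @param on_sample optional `function(st)` called after each step.
#' @return the advanced transport state.
#' @export
advance_concentration <- function(st, Fz = NULL, Fe = NULL, h = NULL,
                                  hz = NULL, t_end, dt = NULL,
                                  fluid = fluid_registry("water_37C"),
                                  reference_shear = 1,
                                  closed = FALSE, on_sample = NULL) {
  g <- st$grid
  h <- h %||% st$h
  hz <- hz %||% rep(0, g$Nz)
  Fz <- Fz %||% matrix(0, g$Nz, g$Nr)
  Fe <- Fe %||% matrix(0, g$Nz, g$Nr - 1L)
  if (closed) Fz[g$Nz, ] <- 0
  open_left <- if (closed) rep(0, g$Nr) else NULL
  Vol <- cell_volumes(g, h)
  # explicit-diffusion stability bound (radial and axial cell widths)
  Dmax <- max(vapply(st$species, function(sp)
    max(species_diffusivity(sp, c(0, sp$initial_concentration), fluid,
                            reference_shear)), numeric(1)))
  dr_min <- min(diff(g$etaf)) * min(h)
  dt_diff <- 0.2 * min(dr_min, g$dz)^2 / Dmax
  dt <- min(dt %||% t_end, dt_diff)
  nstep <- ceiling(t_end / dt)
  dt <- t_end / nstep
  nsub <- scalar_substeps(st, Fz, Fe, Vol, dt)
  dts <- dt / nsub
  for (k in seq_len(nstep * nsub)) {
    st <- scalar_step(st, Fz, Fe, Vol, Vol, h, h, hz, dts, fluid,
                      reference_shear, open_left_flux = open_left)
    if (!is.null(on_sample) && k %% nsub == 0) on_sample(st)
  }
  st
}

#' Total moles currently inside the domain, per species
#' @param st a transport state.
#' @return named vector of moles (umol).
#' @export
total_moles <- function(st) {
  Vol <- st$Vol %||% cell_volumes(st$grid, st$h)
  vapply(st$conc, function(cm) sum(cm * Vol), numeric(1))
}
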