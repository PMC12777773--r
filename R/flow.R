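# Transient axisymmetric incompressible laminar flow on the deforming lumen.
#
# Discretisation: cell-centred finite volumes on the mapped coordinates
# (zeta, eta = r/h(z,t)); arbitrary Lagrangian-Eulerian advection (mesh
# velocity enters the eta advection speed); full consistent viscous operator
# explicit with a Douglas ADI stabilisation (theta = 1) of the stiff axial
# and radial diffusion; incremental pressure projection performed on face
# volume fluxes with Rhie-Chow momentum interpolation, so the corrected face
# fluxes are discretely divergence-free (including the geometric
# conservation terms of the moving mesh). Internal units are CGS (cm, s, g);
# viscosities entering from fluid models in mPa*s are converted to poise.

MPAS_TO_POISE <- 0.01

#' Resolution presets for the flow and transport solvers
#'
#' `"coarse"` is the default for tests and sweeps; `"production"` mirrors a
#' grid-converged setting with strong near-wall refinement (first wall cell
#' well under r0/200).
#'
#' @param resolution `"coarse"`, `"production"`, or a list with fields
#'   `nr`, `nz_per_wavelength`, `stretch`, `cfl`, `dt_max_frac` (max time
#'   step as a fraction of the motility period).
#' @return a list of resolution parameters.
#' @export
resolution_preset <- function(resolution = "coarse") {
  if (is.list(resolution)) return(resolution)
  switch(resolution,
    coarse = list(nr = 20L, nz_per_wavelength = 32L, stretch = 2.2,
                  cfl = 0.35, dt_max_frac = 1 / 100,
                  scalar_nr = 80L, scalar_nz_per_wavelength = 128L,
                  scalar_stretch = 1.6),
    production = list(nr = 64L, nz_per_wavelength = 128L, stretch = 3.2,
                      cfl = 0.4, dt_max_frac = 1 / 400,
                      scalar_nr = 128L, scalar_nz_per_wavelength = 256L,
                      scalar_stretch = 1.8),
    stop("unknown resolution preset: ", resolution)
  )
}

# ---- problem definition --------------------------------------------------

# A flow problem bundles the grid, fluid, wall-shape functions and boundary
# velocities. All wall functions are vectorised over z.
#   hfun(z,t), htfun(z,t), hzfun(z,t): wall radius, radial rate, axial slope
#   wall_uz(z,t), wall_ur(z,t): no-slip velocity of wall material points
#   force(z_mat, r_mat, t): optional body acceleration list(fz, fr) (cm/s^2)
new_flow_problem <- function(grid, fluid, hfun, htfun, hzfun,
                             wall_uz, wall_ur, force = NULL,
                             moving = TRUE, cfl = 0.35, dt_max = Inf) {
  Nz <- grid$Nz; Nr <- grid$Nr
  # sparse-matrix index template for the pressure Poisson operator:
  # pentadiagonal with periodic axial wrap
  idx <- cell_index_template(Nz, Nr)
  rho <- fluid$density
  list(grid = grid, fluid = fluid, rho = rho,
       hfun = hfun, htfun = htfun, hzfun = hzfun,
       wall_uz = wall_uz, wall_ur = wall_ur, force = force,
       moving = moving, cfl = cfl, dt_max = dt_max, idx = idx,
       lu_cache = new.env(parent = emptyenv()))
}

cell_index_template <- function(Nz, Nr) {
  k <- function(i, j) i + (j - 1L) * Nz
  i_all <- rep(seq_len(Nz), Nr)
  j_all <- rep(seq_len(Nr), each = Nz)
  ip <- c(2:Nz, 1L)[i_all]
  im <- c(Nz, 1:(Nz - 1L))[i_all]
  kP <- k(i_all, j_all)
  kE <- k(ip, j_all)
  kW <- k(im, j_all)
  has_N <- j_all < Nr
  has_S <- j_all > 1L
  kN <- ifelse(has_N, k(i_all, pmin(j_all + 1L, Nr)), NA_integer_)
  kS <- ifelse(has_S, k(i_all, pmax(j_all - 1L, 1L)), NA_integer_)
  list(kP = kP, kE = kE, kW = kW, kN = kN[has_N], kS = kS[has_S],
       hasN = has_N, hasS = has_S, n = Nz * Nr)
}

# geometry bundle at a given time
geom_at <- function(prob, t) {
  g <- prob$grid
  h <- prob$hfun(g$zc, t)
  list(h = h, ht = prob$htfun(g$zc, t), hz = prob$hzfun(g$zc, t),
       hf = prob$hfun(g$zf, t))
}

# initial rest state
flow_initial_state <- function(prob, t0 = 0) {
  g <- prob$grid
  z0 <- matrix(0, g$Nz, g$Nr)
  gm <- geom_at(prob, t0)
  list(t = t0, uz = z0, ur = z0, p = z0, geom = gm,
       fluxZ = NULL, fluxE = NULL, Vol0 = NULL, Vol1 = NULL,
       dt_used = NA_real_, div_norm = 0, cfl = 0)
}

# ---- differential helpers on a state ------------------------------------

# physical z-derivative at fixed r: d/dz|_r = d/dzeta - (eta hz / h) d/deta
ddz_field <- function(g, f, m, axis, wall, wall_value = NULL) {
  dz_central(g, f) - m * deta_c(g, f, axis, wall, wall_value)
}

# strain-rate magnitude sqrt(2 S:S) for axisymmetric flow
shear_rate_field <- function(g, uz, ur, h, hz, m, uzw, urw) {
  duz_e <- deta_c(g, uz, "even", "dirichlet", uzw)
  dur_e <- deta_c(g, ur, "odd", "dirichlet", urw)
  hmat <- matrix(h, g$Nz, g$Nr)
  r <- g$eta_mat * hmat
  Szz <- dz_central(g, uz) - m * duz_e
  Srr <- dur_e / hmat
  Stt <- ur / r
  Szr <- 0.5 * (duz_e / hmat + dz_central(g, ur) - m * dur_e)
  sqrt(pmax(2 * (Szz^2 + Srr^2 + Stt^2 + 2 * Szr^2), 0))
}

# radial FV diffusion coefficients: operator
#   L f |_j = (etaf_j nuf_j G_j - etaf_{j-1} nuf_{j-1} G_{j-1}) / (h^2 etab_j w_j)
# with G_j = (f_{j+1} - f_j)/deta_f_j; returns tridiagonal coefficient
# matrices (Nz x Nr) plus the wall Dirichlet fold. nuf: Nz x (Nr-1) interior
# face diffusivity; nuw: Nz vector at the wall face (or NULL for Neumann).
radial_diff_ops <- function(g, h, nuf, nuw = NULL) {
  Nz <- g$Nz; Nr <- g$Nr
  etaf_int <- g$etaf[2:Nr]
  etab <- (g$etaf[-1] + g$etaf[-(Nr + 1)]) / 2   # cell mid eta
  w <- diff(g$etaf)                               # cell widths
  h2 <- h^2
  denom <- outer(h2, etab * w)                    # Nz x Nr
  cf <- nuf * g$etafiM * g$inv_detafM             # face conductances (interior)
  sub <- cbind(0, cf) / denom                     # coefficient of f_{j-1}
  sup <- cbind(cf, 0) / denom                     # coefficient of f_{j+1}
  diag <- -(sub + sup)
  wall <- NULL
  if (!is.null(nuw)) {
    wall <- (nuw / g$d_wall) / denom[, Nr]        # multiplies the wall value
    diag[, Nr] <- diag[, Nr] - wall
  }
  list(sub = sub, diag = diag, sup = sup, wall = wall)
}

# apply the radial operator to a field (explicit use)
radial_diff_apply <- function(ops, f, wall_value = NULL) {
  Nr <- ncol(f)
  res <- ops$diag * f +
    ops$sub * cbind(0, f[, -Nr, drop = FALSE]) +
    ops$sup * cbind(f[, -1, drop = FALSE], 0)
  if (!is.null(ops$wall) && !is.null(wall_value)) {
    res[, Nr] <- res[, Nr] + ops$wall * wall_value
  }
  res
}

# implicit radial solve: (I - dt L) x = rhs, Dirichlet wall folded
radial_diff_solve <- function(ops, rhs, dt, wall_value = NULL, extra_diag = NULL) {
  Nr <- ncol(rhs)
  a <- -dt * ops$sub
  b <- 1 - dt * ops$diag
  cc <- -dt * ops$sup
  if (!is.null(extra_diag)) b <- b + dt * extra_diag
  d <- rhs
  if (!is.null(ops$wall) && !is.null(wall_value)) {
    d[, Nr] <- d[, Nr] + dt * ops$wall * wall_value
  }
  thomas_batch(a, b, cc, d)
}

# axial (periodic, uniform) FV diffusion with face diffusivity nue (Nz x Nr,
# face i between cells i and i+1)
axial_diff_apply <- function(g, f, nue) {
  up <- nue * (f[g$ip, , drop = FALSE] - f)
  (up - up[g$im, , drop = FALSE]) / g$dz^2
}

axial_diff_solve <- function(g, rhs, nue, dt) {
  cfE <- dt * nue / g$dz^2
  cfW <- cfE[g$im, , drop = FALSE]
  a <- -cfW; b <- 1 + cfE + cfW; cc <- -cfE
  cyclic_thomas_batch(a, b, cc, rhs)
}

# second-order upwind eta-derivative; falls back to centred at the ends.
# fg: ghosted field (Nz x (Nr+2)), a: advection coefficient (sign decides)
deta_upwind <- function(g, fg, a) {
  Nr <- g$Nr
  cen <- deta_central(g, fg)
  up <- g$upw
  # minus stencil (information from below), one-sided weights; invalid at j=1
  dm <- cbind(0, fg[, 1:(Nr - 1), drop = FALSE]) * up$mW[[1]] +
        fg[, 1:Nr, drop = FALSE] * up$mW[[2]] +
        fg[, 2:(Nr + 1), drop = FALSE] * up$mW[[3]]
  # plus stencil (information from above); invalid at j=Nr
  dp <- fg[, 2:(Nr + 1), drop = FALSE] * up$pW[[1]] +
        fg[, 3:(Nr + 2), drop = FALSE] * up$pW[[2]] +
        cbind(fg[, 4:(Nr + 2), drop = FALSE], 0) * up$pW[[3]]
  pos <- (a >= 0)
  res <- dm * pos + dp * (1 - pos)
  res[, 1] <- cen[, 1] * pos[, 1] + dp[, 1] * (1 - pos[, 1])
  res[, Nr] <- dm[, Nr] * pos[, Nr] + cen[, Nr] * (1 - pos[, Nr])
  res
}

# ---- the time step -------------------------------------------------------

flow_step <- function(prob, st, dt, scalars = NULL) {
  g <- prob$grid
  Nz <- g$Nz; Nr <- g$Nr
  rho <- prob$rho
  eta <- g$eta_mat
  t0 <- st$t; t1 <- t0 + dt
  gm0 <- st$geom
  gm1 <- geom_at(prob, t1)
  h0 <- gm0$h; h1 <- gm1$h
  hm <- (h0 + h1) / 2
  hmf <- (gm0$hf + gm1$hf) / 2
  hzm <- (gm0$hz + gm1$hz) / 2
  ht_hat <- (h1^2 - h0^2) / (2 * hm * dt)      # discrete GCL wall rate

  h0mat <- matrix(h0, Nz, Nr)
  m0 <- eta * matrix(gm0$hz / h0, Nz, Nr)      # eta hz / h at t0
  r0mat <- eta * h0mat

  uz <- st$uz; ur <- st$ur; p <- st$p
  uzw0 <- prob$wall_uz(g$zc, t0); urw0 <- prob$wall_ur(g$zc, t0)
  uzw1 <- prob$wall_uz(g$zc, t1); urw1 <- prob$wall_ur(g$zc, t1)

  # -- viscosity from local shear rate (lagged) --
  gdot <- shear_rate_field(g, uz, ur, h0, gm0$hz, m0, uzw0, urw0)
  mu <- matrix(effective_viscosity(prob$fluid, as.vector(gdot)), Nz, Nr) *
    MPAS_TO_POISE
  nu <- mu / rho
  wf <- eta_face_weights(g)
  nu_fe <- nu[, -Nr, drop = FALSE] * g$one_wfM +
           nu[, -1, drop = FALSE] * g$wfM                 # interior eta faces
  nu_wall <- nu[, Nr]                                     # wall face (one-sided)
  nu_fz <- (nu + nu[g$ip, , drop = FALSE]) / 2            # zeta faces

  # -- advection (ALE): mesh-relative eta speed --
  a_eta <- (ur - eta * matrix(gm0$ht, Nz, Nr) -
              eta * matrix(gm0$hz, Nz, Nr) * uz) / h0mat
  uz_g <- eta_ghosts(g, uz, "even", "dirichlet", uzw0)
  ur_g <- eta_ghosts(g, ur, "odd", "dirichlet", urw0)
  N_uz <- uz * dz_upwind(g, uz, uz) + a_eta * deta_upwind(g, uz_g, a_eta)
  N_ur <- uz * dz_upwind(g, ur, uz) + a_eta * deta_upwind(g, ur_g, a_eta)

  # -- full consistent viscous operator (explicit) --
  ops_z <- radial_diff_ops(g, h0, nu_fe, nu_wall)
  ezz <- ddz_field(g, uz, m0, "even", "dirichlet", uzw0)
  ezr <- ddz_field(g, ur, m0, "odd", "dirichlet", urw0)
  V_uz <- radial_diff_apply(ops_z, uz, uzw0) +
    ddz_field(g, nu * ezz, m0, "even", "extrapolate")
  V_ur <- radial_diff_apply(ops_z, ur, urw0) - nu * ur / r0mat^2 +
    ddz_field(g, nu * ezr, m0, "odd", "extrapolate")

  # old-pressure gradient (incremental projection); it rides through the
  # implicit stages so the converged state satisfies the full steady
  # momentum balance at any time step
  Gp_z <- ddz_field(g, p, m0, "even", "extrapolate")
  Gp_r <- deta_c(g, p, "even", "extrapolate") / h0mat

  F_uz <- -N_uz + V_uz - Gp_z / rho
  F_ur <- -N_ur + V_ur - Gp_r / rho
  if (!is.null(prob$force)) {
    zmat <- matrix(g$zc, Nz, Nr)
    fr <- prob$force(zmat, r0mat, t0)
    F_uz <- F_uz + fr$fz
    F_ur <- F_ur + fr$fr
  }

  # -- Douglas ADI stages: stiff axial and radial diffusion implicit --
  # implicit radial operator carries the mapped eta-eta coefficient
  # nu (1 + (etaf hz)^2) that covers the mixed-derivative stiffness
  nu_fe_imp <- nu_fe * (1 + outer(hzm, g$etaf[2:Nr])^2)
  nu_wall_imp <- nu_wall * (1 + hzm^2)
  ops_imp <- radial_diff_ops(g, hm, nu_fe_imp, nu_wall_imp)
  r_imp <- eta * matrix(hm, Nz, Nr)

  douglas <- function(u0, Fexp, wall_val1, wall_val0, odd = FALSE) {
    Y0 <- u0 + dt * Fexp
    # stage 1: axial
    Lz_u0 <- axial_diff_apply(g, u0, nu_fz)
    Y1 <- axial_diff_solve(g, Y0 - dt * Lz_u0, nu_fz, dt)
    # stage 2: radial (+ curvature damping for the radial component)
    extra <- if (odd) 1 / r_imp^2 * nu else NULL
    L_u0 <- radial_diff_apply(ops_imp, u0, wall_val0) -
      (if (odd) nu * u0 / r_imp^2 else 0)
    radial_diff_solve(ops_imp, Y1 - dt * L_u0, dt, wall_val1, extra_diag = extra)
  }
  uz_s <- douglas(uz, F_uz, uzw1, uzw0, odd = FALSE)
  ur_s <- douglas(ur, F_ur, urw1, urw0, odd = TRUE)

  # -- face volume fluxes with Rhie-Chow momentum interpolation --
  # (accurate when the viscous relaxation of the smooth physical modes is
  # resolved, nu dt k^2 < 1; the steady drivers bound dt accordingly)
  mm <- eta * matrix(hzm / hm, Nz, Nr)
  hmmat <- matrix(hm, Nz, Nr)
  Gpm_z <- ddz_field(g, p, mm, "even", "extrapolate")
  Gpm_r <- deta_c(g, p, "even", "extrapolate") / hmmat
  uz_h <- uz_s + (dt / rho) * Gpm_z
  ur_h <- ur_s + (dt / rho) * Gpm_r

  etaf_int <- g$etaf[2:Nr]
  dAz <- pi * outer(hmf^2, diff(g$etaf^2))      # zeta-face areas (Nz x Nr)
  aZ <- dAz / g$dz                               # Poisson conductances, zeta
  # eta-face conductance: area/normal-distance of the slanted face,
  # (1 + (etaf hz)^2) is the slope factor; the h metric cancels
  aE <- (2 * pi * g$dz) * (1 + outer(hzm, etaf_int)^2) *
    g$etafiM * g$inv_detafM

  # zeta-face flux: interpolate pressure-free velocity, subtract face gradient
  uzf <- (uz_h + uz_h[g$ip, , drop = FALSE]) / 2
  Fz <- uzf * dAz - (dt / rho) * aZ * (p[g$ip, , drop = FALSE] - p)

  # eta-face flux: mesh-relative normal flux through the slanted moving face
  interp_face <- function(f) {
    f[, -Nr, drop = FALSE] * g$one_wfM + f[, -1, drop = FALSE] * g$wfM
  }
  urf <- interp_face(ur_h)
  uzf_e <- interp_face(uz_h)
  w_rel <- urf - uzf_e * g$etafiM * matrix(hzm, Nz, Nr - 1) -
    outer(ht_hat, etaf_int)
  areaE <- 2 * pi * g$dz * outer(hm, etaf_int)
  Fe <- w_rel * areaE -
    (dt / rho) * aE * (p[, -1, drop = FALSE] - p[, -Nr, drop = FALSE])

  # -- projection: make fluxes satisfy sum(F) + dV/dt = 0 --
  Vol0 <- pi * outer(h0^2, diff(g$etaf^2)) * g$dz
  Vol1 <- pi * outer(h1^2, diff(g$etaf^2)) * g$dz
  dVdt <- (Vol1 - Vol0) / dt
  Rdiv <- Fz - Fz[g$im, , drop = FALSE] +
    cbind(Fe, 0) - cbind(0, Fe) + dVdt
  rhs <- as.vector(Rdiv)
  rhs <- rhs - mean(rhs)
  psi <- solve_poisson(prob, aZ, aE, rhs)
  psi_m <- matrix(psi, Nz, Nr)

  Fz <- Fz + aZ * (psi_m[g$ip, , drop = FALSE] - psi_m)
  Fe <- Fe + aE * (psi_m[, -1, drop = FALSE] - psi_m[, -Nr, drop = FALSE])

  uz1 <- uz_s + ddz_field(g, psi_m, mm, "even", "extrapolate")
  ur1 <- ur_s + deta_c(g, psi_m, "even", "extrapolate") / hmmat
  p1 <- p - (rho / dt) * psi_m

  # residual divergence of corrected fluxes (solver tolerance check)
  Rpost <- Fz - Fz[g$im, , drop = FALSE] + cbind(Fe, 0) - cbind(0, Fe) + dVdt
  fscale <- max(abs(Fz), abs(Fe), max(abs(dVdt)), 1e-300)
  div_norm <- max(abs(Rpost - mean(Rdiv))) / fscale

  # advective CFL of the step just taken
  cfl_now <- dt * max(abs(uz1) / g$dz + abs(a_eta) / g$widthM)

  st1 <- list(t = t1, uz = uz1, ur = ur1, p = p1, geom = gm1,
              fluxZ = Fz, fluxE = Fe, Vol0 = Vol0, Vol1 = Vol1,
              hm = hm, hzm = hzm, ht_hat = ht_hat, h0 = h0, h1 = h1,
              dt_used = dt, div_norm = div_norm, cfl = cfl_now,
              mu = mu, shear = gdot)
  st1
}

# The pressure operator is symmetric positive semidefinite (constant null
# mode); a tiny Tikhonov shift makes it SPD so CHOLMOD can factor it, and
# the symbolic analysis is reused across steps (the sparsity pattern is
# fixed). The mean of psi is irrelevant (only differences enter).
poisson_values <- function(prob, aZ, aE) {
  g <- prob$grid
  idx <- prob$idx
  aZv <- as.vector(aZ)             # face East of each cell
  aWv <- aZv[as.vector(outer(g$im, (seq_len(g$Nr) - 1L) * g$Nz, `+`))]
  aNv <- as.vector(cbind(aE, 0))
  aSv <- as.vector(cbind(0, aE))
  diagv <- aZv + aWv + aNv + aSv
  eps <- 1e-12 * mean(diagv)
  c(diagv + eps, -aZv, -aWv, -aNv[idx$hasN], -aSv[idx$hasS])
}

poisson_template <- function(prob) {
  idx <- prob$idx
  n <- idx$n
  ii <- c(idx$kP, idx$kP, idx$kP, idx$kP[idx$hasN], idx$kP[idx$hasS])
  jj <- c(idx$kP, idx$kE, idx$kW, idx$kN, idx$kS)
  A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = seq_along(ii), dims = c(n, n))
  list(A = A0, perm = A0@x)
}

solve_poisson <- function(prob, aZ, aE, rhs) {
  cache <- prob$lu_cache
  if (is.null(cache$tpl)) cache$tpl <- poisson_template(prob)
  xx <- poisson_values(prob, aZ, aE)
  A <- cache$tpl$A
  A@x <- xx[cache$tpl$perm]
  if (is.null(cache$chol)) {
    cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                                   perm = TRUE)
    cache$static_done <- FALSE
  }
  if (prob$moving || !cache$static_done) {
    cache$chol <- Matrix::update(cache$chol, Matrix::forceSymmetric(A))
    cache$static_done <- TRUE
  }
  as.vector(Matrix::solve(cache$chol, rhs))
}

# choose the next time step from the advective CFL
next_dt <- function(prob, st, dt_prev) {
  g <- prob$grid
  eta <- g$eta_mat
  h <- matrix(st$geom$h, g$Nz, g$Nr)
  a_eta <- (st$ur - eta * matrix(st$geom$ht, g$Nz, g$Nr) -
              eta * matrix(st$geom$hz, g$Nz, g$Nr) * st$uz) / h
  rate <- max(abs(st$uz) / g$dz + abs(a_eta) / g$widthM, 1e-12)
  dt <- prob$cfl / rate
  dt <- min(dt, prob$dt_max, 1.25 * dt_prev)
  dt
}
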