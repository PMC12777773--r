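# Conservative transfer of face volume fluxes from the flow grid to a finer
# (and axially tiled) transport grid.
#
# The projected face fluxes F (fluid + mesh-relative motion) satisfy
# div F = -dV/dt cell by cell. The volume-change source separates into an
# axial "sweep" field: dV/dt is proportional to d(h^2)/dt, whose axial sum
# over a wavelength vanishes exactly under the volume-conserving
# kinematics, so F_s(i,j) = -pi dz Delta(etaf^2)_j G(i), with G the axial
# cumulative of (h1^2 - h0^2)/dt, has divergence -dV/dt and carries no
# radial flux. F - F_s is then exactly divergence-free with zero wall and
# axis flux, hence derives from a discrete Stokes streamfunction psi on
# cell corners (psi = 0 on the axis, constant along the wall).
# Interpolating psi (cubic, tensor product) onto the corners of the
# transport grid and differencing, then adding the analytically rebuilt
# fine F_s, yields fine fluxes whose divergence equals the fine -dV/dt to
# round-off at any refinement and axial tiling: mass conservation and
# uniform-field preservation carry over to the transport grid exactly.

# cubic Lagrange weights for target points xt within source nodes xs
# (1-D, nonuniform); returns index matrix (n x 4) and weight matrix (n x 4)
cubic_weights <- function(xs, xt, periodic = FALSE, period = NULL) {
  n <- length(xs)
  idx <- matrix(1L, length(xt), 4)
  wt <- matrix(0, length(xt), 4)
  for (q in seq_along(xt)) {
    x <- xt[q]
    if (periodic) {
      xr <- (x - xs[1]) %% period + xs[1]
      j <- findInterval(xr - 1e-12, xs)
      ks <- (j - 1):(j + 2)
      xk <- xs[((ks - 1) %% n) + 1] + period * floor((ks - 1) / n)
      # re-centre the stencil coordinates around xr
      idx[q, ] <- ((ks - 1L) %% n) + 1L
      for (k in 1:4) wt[q, k] <- prod((xr - xk[-k]) / (xk[k] - xk[-k]))
    } else {
      j <- findInterval(x, xs, rightmost.closed = TRUE)
      j <- min(max(j, 2L), n - 2L)
      ks <- (j - 1):(j + 2)
      xk <- xs[ks]
      idx[q, ] <- ks
      for (k in 1:4) wt[q, k] <- prod((x - xk[-k]) / (xk[k] - xk[-k]))
    }
  }
  list(idx = idx, wt = wt)
}

# Precompute the interpolation plan from a coarse flow grid (one axial
# period, length gc$L) to a fine transport grid spanning n_tile copies.
flux_refine_plan <- function(gc, gf, n_tile = 1L) {
  stopifnot(abs(gf$L - n_tile * gc$L) < 1e-9)
  eta_plan <- cubic_weights(gc$etaf, gf$etaf)
  z_plan <- cubic_weights(gc$zf, gf$zf %% gc$L, periodic = TRUE,
                          period = gc$L)
  list(eta = eta_plan, z = z_plan, gc = gc, gf = gf, n_tile = n_tile)
}

# axial sweep field carrying the volume-change source on a grid g:
# gsq = (h1^2 - h0^2)/dt per axial cell
sweep_field <- function(g, gsq) {
  G <- cumsum(gsq)
  -pi * g$dz * outer(G, diff(g$etaf^2))
}

# Refine the total face fluxes (fluid + mesh-relative) of one flow step.
# Fz, Fe: coarse fluxes; gsq_c / gsq_f: (h1^2 - h0^2)/dt on the coarse and
# fine axial cells. Returns fine Fz (Nzf x Nrf) and Fe (Nzf x (Nrf-1)).
refine_fluxes <- function(plan, Fz, gsq_c, gsq_f) {
  gc <- plan$gc; gf <- plan$gf
  Fs_c <- sweep_field(gc, gsq_c)
  Fz_psi <- Fz - Fs_c
  psi <- matrix(0, gc$Nz, gc$Nr + 1L)
  psi[, -1] <- t(apply(Fz_psi, 1, cumsum))
  # eta interpolation: columns -> fine eta faces
  pe <- matrix(0, gc$Nz, gf$Nr + 1L)
  for (k in 1:4) {
    pe <- pe + psi[, plan$eta$idx[, k], drop = FALSE] *
      matrix(plan$eta$wt[, k], gc$Nz, gf$Nr + 1L, byrow = TRUE)
  }
  # zeta interpolation: rows -> fine zeta faces (wrapped over the period)
  pf <- matrix(0, gf$Nz, gf$Nr + 1L)
  for (k in 1:4) {
    pf <- pf + pe[plan$z$idx[, k], , drop = FALSE] * plan$z$wt[, k]
  }
  Fzf <- (pf[, -1, drop = FALSE] - pf[, -(gf$Nr + 1L), drop = FALSE]) +
    sweep_field(gf, gsq_f)
  Fef <- -(pf[, 2:gf$Nr, drop = FALSE] -
             pf[c(gf$Nz, 1:(gf$Nz - 1L)), 2:gf$Nr, drop = FALSE])
  list(Fz = Fzf, Fe = Fef)
}
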