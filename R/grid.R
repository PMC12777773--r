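# Boundary-fitted grid and discrete operators.
#
# The deforming lumen z in [0, L], r in [0, h(z,t)] is mapped onto a fixed
# rectangle (zeta, eta) with eta = r / h(z,t) in [0, 1]. Cells are
# cell-centred in both directions: zeta is uniform and periodic (flow), eta
# is smoothly stretched toward the wall via eta = s(xi) with uniform xi.
# Fields are Nz x Nr matrices (rows = axial cells, columns = radial cells).

# wall-clustering map: s(0) = 0, s(1) = 1, monotone, refines near eta = 1
stretch_map <- function(xi, gamma) {
  if (gamma <= 0) return(xi)
  tanh(gamma * xi) / tanh(gamma)
}

#' Construct a boundary-fitted flow grid
#'
#' @param L axial extent (cm); axially periodic for the flow solver.
#' @param Nz number of axial cells.
#' @param Nr number of radial cells.
#' @param stretch wall-clustering strength (0 = uniform radial spacing);
#'   larger values concentrate cells at the epithelial wall.
#' @return A `flow_grid` object with cell centres, faces and precomputed
#'   difference coefficients.
#' @keywords internal
#' @export
flow_grid <- function(L, Nz, Nr, stretch = 2.2) {
  stopifnot(L > 0, Nz >= 4, Nr >= 4)
  dz <- L / Nz
  zc <- (seq_len(Nz) - 0.5) * dz          # cell centres
  zf <- seq_len(Nz) * dz                  # face i sits between cells i, i+1
  xif <- (0:Nr) / Nr
  etaf <- stretch_map(xif, stretch)       # radial faces, etaf[1]=0, etaf[Nr+1]=1
  eta <- (etaf[-1] + etaf[-(Nr + 1)]) / 2 # cell centres
  deta_f <- diff(eta)                     # centre-to-centre spacing (len Nr-1)
  d_wall <- 1 - eta[Nr]                   # last centre to wall face
  d_axis <- eta[1]                        # first centre to axis face

  # centred 3-point first-derivative coefficients at cell centres, using
  # ghost nodes mirrored across axis (eta = -eta_1) and wall (eta = 2 - eta_Nr)
  nodes <- c(-eta[1], eta, 2 - eta[Nr])
  dc <- t(vapply(seq_len(Nr), function(j) {
    x <- nodes[j:(j + 2)] - nodes[j + 1]
    # 3-point nonuniform first-derivative weights evaluated at the centre node
    xl <- x[1]; xr <- x[3]
    c(-xr / (xl * (xl - xr)),
      -(xl + xr) / (xl * xr),
      -xl / (xr * (xr - xl)))
  }, numeric(3)))

  g <- list(
    L = L, Nz = as.integer(Nz), Nr = as.integer(Nr), dz = dz,
    zc = zc, zf = zf, eta = eta, etaf = etaf,
    eta_mat = matrix(eta, Nz, Nr, byrow = TRUE),
    deta_f = deta_f, d_wall = d_wall, d_axis = d_axis,
    dcoef = dc,
    ip = c(2:Nz, 1L), im = c(Nz, 1:(Nz - 1L)),
    ip2 = c(3:Nz, 1L, 2L), im2 = c(Nz - 1L, Nz, 1:(Nz - 2L)),
    stretch = stretch
  )
  # precomputed row-replicated weight matrices (hot loops avoid sweep())
  rowmat <- function(v) matrix(v, Nz, length(v), byrow = TRUE)
  g$dcW <- lapply(1:3, function(k) rowmat(dc[, k]))
  wfv <- (etaf[2:Nr] - eta[-Nr]) / (eta[-1] - eta[-Nr])
  g$wfM <- rowmat(wfv)
  g$one_wfM <- rowmat(1 - wfv)
  g$inv_detafM <- rowmat(1 / deta_f)
  g$etafiM <- rowmat(etaf[2:Nr])
  g$widthM <- rowmat(diff(etaf))
  g$upw <- upwind_coefs_build(eta, Nr)
  g$upw$mW <- lapply(1:3, function(k) rowmat(g$upw$m[, k]))
  g$upw$pW <- lapply(1:3, function(k) rowmat(g$upw$p[, k]))
  g$ppm_eta <- ppm_eta_plan(eta, Nr, etaf)
  structure(g, class = "flow_grid")
}

upwind_coefs_build <- function(eta, Nr) {
  nodes <- c(-eta[1], eta, 2 - eta[Nr])
  onesided <- function(xs, x0) {
    x <- xs - x0
    l <- x[1]; m <- x[2]; r <- x[3]
    c(((0 - m) + (0 - r)) / ((l - m) * (l - r)),
      ((0 - l) + (0 - r)) / ((m - l) * (m - r)),
      ((0 - l) + (0 - m)) / ((r - l) * (r - m)))
  }
  mcoef <- matrix(0, Nr, 3)
  pcoef <- matrix(0, Nr, 3)
  for (j in 2:Nr) mcoef[j, ] <- onesided(nodes[(j - 1):(j + 1)], nodes[j + 1])
  for (j in 1:(Nr - 1)) pcoef[j, ] <- onesided(nodes[(j + 1):(j + 3)], nodes[j + 1])
  list(m = mcoef, p = pcoef)
}

# ---- zeta-direction (uniform, periodic) operators ------------------------

dz_central <- function(g, f) (f[g$ip, , drop = FALSE] - f[g$im, , drop = FALSE]) / (2 * g$dz)

d2z_central <- function(g, f) {
  (f[g$ip, , drop = FALSE] - 2 * f + f[g$im, , drop = FALSE]) / g$dz^2
}

# second-order upwind zeta-derivative given cellwise advection speed a
dz_upwind <- function(g, f, a) {
  fp <- (3 * f - 4 * f[g$im, , drop = FALSE] + f[g$im2, , drop = FALSE]) / (2 * g$dz)
  fm <- (-3 * f + 4 * f[g$ip, , drop = FALSE] - f[g$ip2, , drop = FALSE]) / (2 * g$dz)
  pos <- (a >= 0)
  fp * pos + fm * (1 - pos)
}

# ---- eta-direction helpers ----------------------------------------------

# append ghost columns for a field given boundary treatment.
# axis: "even" (symmetric) or "odd" (antisymmetric);
# wall: "dirichlet" (value = vector over zeta or matrix) or "neumann"
eta_ghosts <- function(g, f, axis = "even", wall = "neumann", wall_value = NULL) {
  Nr <- g$Nr
  gl <- if (axis == "even") f[, 1] else -f[, 1]
  gr <- switch(wall,
    neumann = f[, Nr],
    dirichlet = 2 * wall_value - f[, Nr],
    # linear extrapolation to the mirror node at eta = 2 - eta_Nr
    extrapolate = f[, Nr] + (2 * g$d_wall) *
      (f[, Nr] - f[, Nr - 1]) / g$deta_f[Nr - 1]
  )
  cbind(gl, f, gr, deparse.level = 0)
}

# centred eta-derivative at cell centres from a ghosted field
deta_central <- function(g, fg) {
  Nr <- g$Nr
  fg[, 1:Nr, drop = FALSE] * g$dcW[[1]] +
    fg[, 2:(Nr + 1), drop = FALSE] * g$dcW[[2]] +
    fg[, 3:(Nr + 2), drop = FALSE] * g$dcW[[3]]
}

# convenience: centred eta derivative with BC spec
deta_c <- function(g, f, axis = "even", wall = "neumann", wall_value = NULL) {
  deta_central(g, eta_ghosts(g, f, axis, wall, wall_value))
}

# ---- batched tridiagonal solvers ----------------------------------------

# solve, for each row k, the tridiagonal system with sub/main/super
# diagonals a[k,], b[k,], c[k,] (a[,1] and c[,n] ignored) - Thomas algorithm
# vectorised across rows
thomas_batch <- function(a, b, c, d) {
  n <- ncol(b)
  cp <- matrix(0, nrow(b), n)
  dp <- matrix(0, nrow(b), n)
  cp[, 1] <- c[, 1] / b[, 1]
  dp[, 1] <- d[, 1] / b[, 1]
  for (j in 2:n) {
    m <- b[, j] - a[, j] * cp[, j - 1]
    cp[, j] <- c[, j] / m
    dp[, j] <- (d[, j] - a[, j] * dp[, j - 1]) / m
  }
  x <- dp
  for (j in (n - 1):1) x[, j] <- dp[, j] - cp[, j] * x[, j + 1]
  x
}

# tridiagonal solve along the FIRST dimension, batched across columns
thomas_first <- function(a, b, c, d) {
  n <- nrow(b)
  cp <- matrix(0, n, ncol(b))
  dp <- matrix(0, n, ncol(b))
  cp[1, ] <- c[1, ] / b[1, ]
  dp[1, ] <- d[1, ] / b[1, ]
  for (i in 2:n) {
    m <- b[i, ] - a[i, ] * cp[i - 1, ]
    cp[i, ] <- c[i, ] / m
    dp[i, ] <- (d[i, ] - a[i, ] * dp[i - 1, ]) / m
  }
  x <- dp
  for (i in (n - 1):1) x[i, ] <- dp[i, ] - cp[i, ] * x[i + 1, ]
  x
}

# cyclic (periodic) tridiagonal solve along the FIRST dimension, batched
# across columns; a, b, c are Nz x Nc (sub, main, super with wraparound)
cyclic_thomas_batch <- function(a, b, c, d) {
  n <- nrow(b)
  # Sherman-Morrison: modified system plus rank-one correction
  alpha <- -b[1, ]
  bm <- b
  bm[1, ] <- b[1, ] - alpha
  bm[n, ] <- b[n, ] - c[n, ] * a[1, ] / alpha
  x1 <- thomas_first(a, bm, c, d)
  u <- matrix(0, n, ncol(b))
  u[1, ] <- alpha
  u[n, ] <- c[n, ]
  x2 <- thomas_first(a, bm, c, u)
  fact <- (x1[1, ] + a[1, ] * x1[n, ] / alpha) /
    (1 + x2[1, ] + a[1, ] * x2[n, ] / alpha)
  x1 - x2 * matrix(fact, n, ncol(b), byrow = TRUE)
}

# linear interpolation weight of eta faces between neighbouring centres:
# value_face_j = (1-w_j) f[,j] + w_j f[,j+1], j = 1..Nr-1 (interior faces)
eta_face_weights <- function(g) {
  j <- seq_len(g$Nr - 1L)
  (g$etaf[j + 1L] - g$eta[j]) / (g$eta[j + 1L] - g$eta[j])
}
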