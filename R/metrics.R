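# Epithelial delivery metrics: near-wall mole percentages, escape fraction,
# wall surface concentrations, and the colocalisation score.

# fraction of each cell's volume lying within `thickness` of the wall,
# measured from the instantaneous wall position h(z). Nz x Nr weights.
near_wall_weights <- function(grid, h, thickness) {
  if (any(thickness >= h)) {
    stop("near-wall layer thickness ", signif(thickness, 3),
         " cm exceeds the lumen radius somewhere (min h = ",
         signif(min(h), 3), " cm)")
  }
  etaf <- grid$etaf
  Nr <- grid$Nr
  lo2 <- matrix(etaf[-(Nr + 1)]^2, grid$Nz, Nr, byrow = TRUE)
  hi2 <- matrix(etaf[-1]^2, grid$Nz, Nr, byrow = TRUE)
  cut2 <- matrix((1 - thickness / h)^2, grid$Nz, Nr)
  w <- (hi2 - pmax(lo2, cut2)) / (hi2 - lo2)
  pmin(pmax(w, 0), 1)
}

# mole percentage of the released amount inside the wall-adjacent shell
near_wall_pct_state <- function(st, thickness) {
  w <- near_wall_weights(st$grid, st$h, thickness)
  vapply(seq_along(st$conc), function(s) {
    100 * sum(st$conc[[s]] * st$Vol * w) / st$released[s]
  }, numeric(1))
}

# mole percentage outside the fixed axial interval [z_lo, z_hi]
# (escaped-through-ends mass counts as outside)
escape_pct_state <- function(st, z_lo, z_hi) {
  g <- st$grid
  zl <- g$zc - g$dz / 2
  zr <- g$zc + g$dz / 2
  frac_in <- pmin(zr, z_hi) - pmax(zl, z_lo)
  frac_in <- pmax(frac_in, 0) / g$dz
  vapply(seq_along(st$conc), function(s) {
    inside <- sum((st$conc[[s]] * st$Vol) * frac_in)
    100 * (st$released[s] - inside) / st$released[s]
  }, numeric(1))
}

# wall concentration per axial position: quadratic extrapolation with zero
# normal slope at the impermeable wall
wall_concentration <- function(grid, cm) {
  Nr <- grid$Nr
  x1 <- 1 - grid$eta[Nr]
  x2 <- 1 - grid$eta[Nr - 1]
  (cm[, Nr] * x2^2 - cm[, Nr - 1] * x1^2) / (x2^2 - x1^2)
}

#' Near-wall mole percentage time series
#'
#' Percentage of the released moles lying within a wall-adjacent shell of
#' the given thickness (measured from the instantaneous wall position), for
#' every stored sample of a case run.
#'
#' @param result a `case_result` from [run_case()].
#' @param thickness shell thickness (cm); the conventional layers are D/15
#'   and D/30 with D = 2 r0 the rest diameter.
#' @return tibble with time, species, and percentage.
#' @export
near_wall_fraction <- function(result, thickness) {
  m <- result$metrics
  col <- if (isTRUE(all.equal(thickness, result$layers["D15"]))) {
    "nearwall_D15_pct"
  } else if (isTRUE(all.equal(thickness, result$layers["D30"]))) {
    "nearwall_D30_pct"
  } else {
    stop("only the layers tracked during the run are available (D/15 = ",
         signif(result$layers["D15"], 3), ", D/30 = ",
         signif(result$layers["D30"], 3), " cm)")
  }
  m[, c("t", "period", "species", col)]
}

#' Escape percentage time series from the release pocket
#' @param result a `case_result` from [run_case()].
#' @return tibble with time, species and escape percentage.
#' @export
escape_fraction <- function(result) {
  result$metrics[, c("t", "period", "species", "escape_pct")]
}

#' Wall surface-concentration statistics of a case run
#'
#' Axial profiles of normalised wall concentration (c/ci) at the stored
#' snapshot times, the running maximum time series, the per-species peak
#' (value, time and axial position), and the detection onset: the first time
#' the wall concentration exceeds c/ci = 0.001.
#'
#' @param result a `case_result` from [run_case()].
#' @return list with `profiles` (tibble), `max_series` (tibble), `peaks`
#'   (tibble), `onset` (named numeric, NA when never detected).
#' @export
surface_concentration_stats <- function(result) {
  ms <- result$metrics
  onset <- vapply(split(ms, ms$species), function(d) {
    i <- which(d$wall_cmax_norm > 1e-3)
    if (length(i)) d$t[min(i)] else NA_real_
  }, numeric(1))
  list(profiles = result$profiles,
       max_series = ms[, c("t", "period", "species", "wall_cmax_norm")],
       peaks = result$peaks,
       onset = onset)
}

#' Colocalisation score of macromolecule and enhancer delivery
#'
#' \deqn{CS = \frac{\bar C_{MM}\,\bar C_{PE}}{1 + \bar{dt}^2 + \bar{dz}^2 + \bar{dr}^2}}
#' where \eqn{\bar C} are the ensemble-normalised peak wall concentrations
#' (each case's time-maximum wall concentration divided by the ensemble
#' maximum, per species) and the penalty terms are the absolute temporal,
#' axial and radial separations of the two species' wall-concentration peaks
#' normalised by the total simulated time, the wavelength and the rest
#' radius respectively. CS is bounded in [0, 1], increases with either
#' normalised concentration and decreases with any separation.
#'
#' @param c_mm,c_pe normalised peak concentrations in `[0, 1]`.
#' @param dt,dz,dr absolute peak separations (s, cm, cm).
#' @param norms list with `t`, `z`, `r`: the normalisation constants
#'   (total simulated time, wavelength, rest radius).
#' @return the colocalisation score (vectorised).
#' @export
colocalisation_score <- function(c_mm, c_pe, dt, dz, dr,
                                 norms = list(t = 1, z = 1, r = 1)) {
  if (any(c_mm < 0 | c_mm > 1 | c_pe < 0 | c_pe > 1)) {
    stop("normalised peak concentrations must lie in [0, 1]; ",
         "ensemble normalisation is broken")
  }
  dtb <- abs(dt) / norms$t
  dzb <- abs(dz) / norms$z
  drb <- abs(dr) / norms$r
  c_mm * c_pe / (1 + dtb^2 + dzb^2 + drb^2)
}

#' Colocalisation records for an ensemble of case results
#'
#' Normalises each case's per-species peak wall concentrations by the
#' ensemble maximum (so at least one case attains 1 per species), computes
#' the peak-separation terms between the first (macromolecule) and second
#' (enhancer) species, and returns one colocalisation record per case.
#'
#' @param results list of `case_result` objects (or a `sweep_result`).
#' @return tibble of class `coloc_table`: one row per case with normalised
#'   peaks, separation terms and CS.
#' @export
colocalise <- function(results) {
  if (inherits(results, "sweep_result")) results <- results$results
  peaks <- lapply(results, function(r) r$peaks)
  sp_names <- unique(peaks[[1]]$species)
  stopifnot(length(sp_names) == 2)
  pk_mm <- do.call(rbind, lapply(peaks, function(p) p[p$species == sp_names[1], ]))
  pk_pe <- do.call(rbind, lapply(peaks, function(p) p[p$species == sp_names[2], ]))
  max_mm <- max(pk_mm$c_norm)
  max_pe <- max(pk_pe$c_norm)
  if (max_mm <= 0 || max_pe <= 0) {
    stop("no case shows a nonzero wall concentration; cannot normalise")
  }
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    geom <- r$case$geometry
    norms <- list(t = r$case$n_periods * geom$period,
                  z = geom$wavelength, r = geom$rest_radius)
    cmm <- pk_mm$c_norm[i] / max_mm
    cpe <- pk_pe$c_norm[i] / max_pe
    dt <- abs(pk_mm$t[i] - pk_pe$t[i])
    dz <- abs(pk_mm$z_lab[i] - pk_pe$z_lab[i])
    dr <- abs(pk_mm$r_wall[i] - pk_pe$r_wall[i])
    tibble::tibble(
      case_id = r$case_id %||% i,
      c_mm = cmm, c_pe = cpe,
      dt_bar = dt / norms$t, dz_bar = dz / norms$z, dr_bar = dr / norms$r,
      cs = colocalisation_score(cmm, cpe, dt, dz, dr, norms)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coloc_table", class(out))
  out
}
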