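#' Wall geometry for an intestinal motility pattern
#'
#' Parameterises the moving epithelial boundary of a lumen segment. For
#' segmentation the wall radius is
#' \deqn{h(z,t) = r_0 + \delta \sin(2\pi t/t_p)\cos(2\pi z/\lambda) + B(t)}
#' where the spatially uniform offset
#' \eqn{B(t) = \sqrt{r_0^2 - (\delta^2/2)\sin^2(2\pi t/t_p)} - r_0}
#' enforces exact conservation of luminal volume per wavelength at every
#' instant (its time derivative is the wall-velocity correction term
#' \code{\link{segmentation_correction}}). For peristalsis the wall is a pure
#' travelling wave \eqn{h(z,t) = r_0 + \delta\sin(2\pi(z - ct)/\lambda)}.
#'
#' @param rest_radius rest (undeformed) lumen radius \eqn{r_0} (cm).
#' @param amplitude occlusion amplitude \eqn{\delta} (cm); must satisfy
#'   \eqn{0 \le \delta < r_0\sqrt{2}} so the volume-conserving offset stays
#'   real for all times.
#' @param wavelength contraction wavelength \eqn{\lambda} (cm).
#' @param motility `"segmentation"` or `"peristalsis"`.
#' @param period segmentation period \eqn{t_p} (s). For peristalsis the
#'   period is derived as \eqn{\lambda/c} when `wave_speed` is given.
#' @param wave_speed peristaltic wave speed \eqn{c} (cm/s); ignored for
#'   segmentation.
#' @param n_pockets number of contraction pockets in the simulated segment
#'   (defaults: 3 for segmentation, 30 for peristalsis).
#'
#' @return An object of class `wall_geometry`.
#' @seealso [derive_geometry()], [wall_radius()], [wall_velocity()]
#' @export
wall_geometry <- function(rest_radius, amplitude, wavelength,
                          motility = c("segmentation", "peristalsis"),
                          period = NULL, wave_speed = NULL,
                          n_pockets = NULL) {
  motility <- match.arg(motility)
  stopifnot(rest_radius > 0, wavelength > 0, amplitude >= 0)
  if (amplitude >= rest_radius * sqrt(2)) {
    stop("amplitude must satisfy delta < r0*sqrt(2); the volume-conserving ",
         "radial offset would become imaginary (wall would invert).")
  }
  if (motility == "segmentation") {
    if (is.null(period)) stop("segmentation geometry needs `period` (s)")
    wave_speed <- NULL
  } else {
    if (is.null(wave_speed)) {
      if (is.null(period)) stop("peristalsis geometry needs `wave_speed` (cm/s)")
      wave_speed <- wavelength / period
    }
    period <- wavelength / wave_speed
    if (amplitude >= rest_radius) {
      stop("peristaltic amplitude must be < r0 (lumen would close completely)")
    }
  }
  if (is.null(n_pockets)) n_pockets <- if (motility == "segmentation") 3L else 30L
  structure(
    list(
      rest_radius = rest_radius, amplitude = amplitude,
      wavelength = wavelength, motility = motility,
      period = period, wave_speed = wave_speed,
      n_pockets = as.integer(n_pockets)
    ),
    class = "wall_geometry"
  )
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf(
    "<wall_geometry> %s: r0 = %.4f cm, delta = %.4f cm, lambda = %.3f cm, tp = %.3f s%s, %d pockets\n",
    x$motility, x$rest_radius, x$amplitude, x$wavelength, x$period,
    if (!is.null(x$wave_speed)) sprintf(", c = %.3f cm/s", x$wave_speed) else "",
    x$n_pockets
  ))
  invisible(x)
}

#' Derive wall geometry from pocket volume, wavelength and occlusion ratio
#'
#' The rest radius is chosen so a rest cylinder of one wavelength holds the
#' pocket volume, \eqn{r_0 = \sqrt{V/(\pi\lambda)}}. The occlusion amplitude
#' \eqn{\delta} is then solved so the minimum wall radius over a full cycle
#' equals \eqn{OR \cdot r_0}, where the occlusion ratio OR is the
#' minimum-to-rest radius ratio. For segmentation the minimum radius includes
#' the volume-conserving offset, giving the closed form
#' \eqn{\delta = r_0(-2\,OR + \sqrt{6 - 2\,OR^2})/3}; for peristalsis
#' \eqn{\delta = (1 - OR)\,r_0}.
#'
#' @param pocket_volume luminal volume of one pocket (mL).
#' @param wavelength contraction wavelength (cm).
#' @param occlusion_ratio OR in (0, 1); smaller = stronger contraction.
#' @param motility `"segmentation"` or `"peristalsis"`.
#' @param period segmentation period (s); default 5 (moderate intensity).
#' @param wave_speed peristaltic wave speed (cm/s); default 1 (moderate).
#' @param include_offset if `TRUE` (default) the segmentation OR inversion
#'   accounts for the volume-conserving radial offset realised by the wall;
#'   `FALSE` uses the bare sinusoidal amplitude \eqn{\delta = (1-OR) r_0}.
#' @inheritParams wall_geometry
#' @return A [wall_geometry()] object.
#' @examples
#' g <- derive_geometry(2, 2.4, 0.3, "segmentation")
#' g$rest_radius # ~0.515 cm
#' @export
derive_geometry <- function(pocket_volume, wavelength, occlusion_ratio,
                            motility = c("segmentation", "peristalsis"),
                            period = 5, wave_speed = 1,
                            n_pockets = NULL, include_offset = TRUE) {
  motility <- match.arg(motility)
  stopifnot(pocket_volume > 0, wavelength > 0)
  if (occlusion_ratio <= 0 || occlusion_ratio >= 1) {
    stop("occlusion_ratio must lie in (0, 1): it is the minimum-to-rest ",
         "radius ratio of the contracting lumen.")
  }
  r0 <- sqrt(pocket_volume / (pi * wavelength))
  if (motility == "segmentation") {
    delta <- if (include_offset) {
      r0 * (-2 * occlusion_ratio + sqrt(6 - 2 * occlusion_ratio^2)) / 3
    } else {
      (1 - occlusion_ratio) * r0
    }
    if (delta >= r0 * sqrt(2)) {
      stop("occlusion_ratio ", occlusion_ratio, " is non-physical: the ",
           "required amplitude delta = ", signif(delta, 4),
           " cm reaches r0*sqrt(2) and the volume-conserving offset is undefined.")
    }
    geom <- wall_geometry(r0, delta, wavelength, "segmentation",
                          period = period, n_pockets = n_pockets)
  } else {
    delta <- (1 - occlusion_ratio) * r0
    geom <- wall_geometry(r0, delta, wavelength, "peristalsis",
                          wave_speed = wave_speed, n_pockets = n_pockets)
  }
  geom$pocket_volume <- pocket_volume
  geom$occlusion_ratio <- occlusion_ratio
  geom
}

two_pi <- 2 * pi

#' Volume-conserving offset of the segmentation wall and its derivative
#'
#' `segmentation_offset()` returns
#' \eqn{B(t) = \sqrt{r_0^2 - (\delta^2/2)\sin^2(2\pi t/t_p)} - r_0}, the
#' spatially uniform radial offset that keeps the luminal volume per
#' wavelength exactly constant. `segmentation_correction()` returns its time
#' derivative \eqn{f(t) = B'(t)}, the correction term added to the prescribed
#' wall velocity so the wall motion ejects or sucks no net fluid.
#'
#' @param geom a segmentation [wall_geometry()].
#' @param t time (s), vectorised.
#' @return radial offset (cm) or its rate (cm/s).
#' @export
segmentation_offset <- function(geom, t) {
  stopifnot(inherits(geom, "wall_geometry"), geom$motility == "segmentation")
  r0 <- geom$rest_radius; d <- geom$amplitude; tp <- geom$period
  rad <- r0^2 - (d^2 / 2) * sin(two_pi * t / tp)^2
  if (any(rad <= 0)) stop("invalid amplitude: offset radicand non-positive")
  sqrt(rad) - r0
}

#' @rdname segmentation_offset
#' @export
segmentation_correction <- function(geom, t) {
  stopifnot(inherits(geom, "wall_geometry"), geom$motility == "segmentation")
  r0 <- geom$rest_radius; d <- geom$amplitude; tp <- geom$period
  rad <- r0^2 + (d^2 / 4) * (cos(4 * pi * t / tp) - 1)
  if (any(rad <= 0)) stop("invalid amplitude: correction radicand non-positive")
  -(pi * d^2 / tp) * sin(4 * pi * t / tp) / (2 * sqrt(rad))
}

#' Instantaneous wall radius
#'
#' Radial position of the epithelial boundary at axial position `z` and time
#' `t`. Segmentation starts from the undeformed cylinder at `t = 0`;
#' the peristaltic wave travels in +z.
#'
#' @inheritParams segmentation_offset
#' @param geom a [wall_geometry()].
#' @param z axial position (cm), vectorised (recycled against `t`).
#' @return wall radius (cm).
#' @export
wall_radius <- function(geom, z, t) {
  stopifnot(inherits(geom, "wall_geometry"))
  r0 <- geom$rest_radius; d <- geom$amplitude; lam <- geom$wavelength
  if (geom$motility == "segmentation") {
    tp <- geom$period
    r0 + d * sin(two_pi * t / tp) * cos(two_pi * z / lam) +
      segmentation_offset(geom, t)
  } else {
    r0 + d * sin(two_pi * (z - geom$wave_speed * t) / lam)
  }
}

#' Prescribed radial wall velocity
#'
#' For segmentation this is the prescribed contraction rate
#' \deqn{U_r(z,t) = \frac{2\pi\delta}{t_p}\cos(2\pi z/\lambda)\cos(2\pi t/t_p) + f(t)}
#' with the volume-conservation correction \eqn{f(t)} of
#' [segmentation_correction()]; it equals \eqn{\partial h/\partial t} of
#' [wall_radius()] exactly. For peristalsis it is the travelling-wave rate
#' \eqn{\partial h/\partial t = -c\, h_z}.
#'
#' @inheritParams wall_radius
#' @return radial wall velocity (cm/s).
#' @export
wall_velocity <- function(geom, z, t) {
  stopifnot(inherits(geom, "wall_geometry"))
  d <- geom$amplitude; lam <- geom$wavelength
  if (geom$motility == "segmentation") {
    tp <- geom$period
    (two_pi * d / tp) * cos(two_pi * z / lam) * cos(two_pi * t / tp) +
      segmentation_correction(geom, t)
  } else {
    c_w <- geom$wave_speed
    -c_w * (two_pi * d / lam) * cos(two_pi * (z - c_w * t) / lam)
  }
}

#' Axial slope of the wall
#' @inheritParams wall_radius
#' @return \eqn{\partial h/\partial z} (dimensionless).
#' @export
wall_slope <- function(geom, z, t) {
  d <- geom$amplitude; lam <- geom$wavelength
  if (geom$motility == "segmentation") {
    -d * sin(two_pi * t / geom$period) * sin(two_pi * z / lam) * (two_pi / lam)
  } else {
    d * (two_pi / lam) * cos(two_pi * (z - geom$wave_speed * t) / lam)
  }
}

#' Relative luminal-volume conservation error per wavelength
#'
#' Evaluates \eqn{|\int_0^\lambda h^2\,dz - r_0^2\lambda| / (r_0^2\lambda)}
#' by composite Simpson quadrature. For the volume-conserving segmentation
#' wall this is zero to round-off; with the correction offset disabled
#' (`use_offset = FALSE`) the analytic error at peak contraction is
#' \eqn{\delta^2/(2 r_0^2)} to leading order.
#'
#' @param geom a segmentation [wall_geometry()].
#' @param t time(s) at which to evaluate (vectorised).
#' @param n_quad number of quadrature intervals (even).
#' @param use_offset include the volume-conserving offset B(t)? Setting
#'   `FALSE` reproduces the error of an uncorrected sinusoidal wall.
#' @return relative volume error, same length as `t`.
#' @export
check_volume_conservation <- function(geom, t, n_quad = 512L, use_offset = TRUE) {
  stopifnot(inherits(geom, "wall_geometry"), geom$motility == "segmentation")
  lam <- geom$wavelength; r0 <- geom$rest_radius
  zq <- seq(0, lam, length.out = n_quad + 1L)
  w <- simpson_weights(n_quad, lam / n_quad)
  vapply(t, function(ti) {
    h <- wall_radius(geom, zq, ti)
    if (!use_offset) h <- h - segmentation_offset(geom, ti)
    abs(sum(w * h^2) - r0^2 * lam) / (r0^2 * lam)
  }, numeric(1))
}

# composite Simpson weights for n (even) intervals of width dx
simpson_weights <- function(n, dx) {
  stopifnot(n %% 2 == 0)
  w <- rep(c(4, 2), length.out = n - 1L)
  c(1, w, 1) * dx / 3
}

#' Intensity presets for motility
#'
#' Motility intensity maps to segmentation period and peristaltic wave speed:
#' light (7 s, 0.5 cm/s), moderate (5 s, 1 cm/s), vigorous (3 s, 1.5 cm/s).
#'
#' @param intensity `"light"`, `"moderate"` or `"vigorous"`.
#' @return list with `period` (s) and `wave_speed` (cm/s).
#' @export
intensity_levels <- function(intensity = c("light", "moderate", "vigorous")) {
  intensity <- match.arg(intensity)
  switch(intensity,
    light    = list(period = 7, wave_speed = 0.5),
    moderate = list(period = 5, wave_speed = 1.0),
    vigorous = list(period = 3, wave_speed = 1.5)
  )
}

# default pocket volume <-> wavelength pairing
default_wavelength <- function(pocket_volume) {
  if (isTRUE(all.equal(pocket_volume, 2))) return(2.4)
  if (isTRUE(all.equal(pocket_volume, 10))) return(4.1)
  stop("no default wavelength for pocket_volume = ", pocket_volume,
       " mL; supply `wavelength` explicitly (defaults exist for 2 and 10 mL).")
}

#' Define a fully parameterised motility simulation case
#'
#' Bundles the wall geometry, intensity, fluid, species set, release position
#' and run length of one scenario. Pocket volumes of 2 and 10 mL default to
#' wavelengths of 2.4 and 4.1 cm respectively.
#'
#' @param motility `"segmentation"` or `"peristalsis"`.
#' @param intensity `"light"`, `"moderate"` or `"vigorous"`.
#' @param fluid a [fluid_model()] or the name of a registered fluid
#'   (`"water_37C"`, `"nutridrink_default"`).
#' @param pocket_volume pocket volume (mL).
#' @param occlusion_ratio minimum-to-rest radius ratio in (0, 1).
#' @param release `"most_occluded"` (pocket centre) or `"least_occluded"`
#'   (a quarter wavelength from the centre, on the centreline).
#' @param species list of [species_model()]s; default insulin (2 mM) + C10
#'   (100 mM).
#' @param n_periods number of motility periods to simulate (default 30).
#' @param wavelength override the default volume-wavelength pairing (cm).
#' @param include_offset see [derive_geometry()].
#' @return An object of class `motility_case`.
#' @examples
#' baseline_case <- motility_case("segmentation", "moderate", "nutridrink_default",
#'                                pocket_volume = 2, occlusion_ratio = 0.3)
#' @export
motility_case <- function(motility = c("segmentation", "peristalsis"),
                          intensity = c("moderate", "light", "vigorous"),
                          fluid = "nutridrink_default",
                          pocket_volume = 2, occlusion_ratio = 0.3,
                          release = c("most_occluded", "least_occluded"),
                          species = NULL, n_periods = 30L,
                          wavelength = NULL, include_offset = TRUE) {
  motility <- match.arg(motility)
  intensity <- match.arg(intensity)
  release <- match.arg(release)
  lev <- intensity_levels(intensity)
  if (is.null(wavelength)) wavelength <- default_wavelength(pocket_volume)
  geom <- derive_geometry(pocket_volume, wavelength, occlusion_ratio, motility,
                          period = lev$period, wave_speed = lev$wave_speed,
                          include_offset = include_offset)
  if (is.character(fluid)) fluid <- fluid_registry(fluid)
  if (is.null(species)) species <- list(species_registry("insulin"),
                                        species_registry("C10"))
  stopifnot(inherits(fluid, "fluid_model"),
            all(vapply(species, inherits, logical(1), "species_model")))
  structure(
    list(
      geometry = geom, motility = motility, intensity = intensity,
      fluid = fluid, pocket_volume = pocket_volume,
      occlusion_ratio = occlusion_ratio, release = release,
      species = species, n_periods = as.integer(n_periods)
    ),
    class = "motility_case"
  )
}

#' @export
print.motility_case <- function(x, ...) {
  cat(sprintf(
    "<motility_case> %s / %s / %s, V = %g mL, OR = %.2f, release = %s, %d periods\n",
    x$motility, x$intensity, x$fluid$name, x$pocket_volume,
    x$occlusion_ratio, x$release, x$n_periods
  ))
  print(x$geometry)
  invisible(x)
}

# axial centre of pocket k (1-based): z = (k - 1/2) * lambda
pocket_centre <- function(geom, k) (k - 0.5) * geom$wavelength

# Release axial position for a case. Segmentation: the pocket centre is the
# most occluded point of the contraction phase; least occluded is lambda/4
# away along the centreline. Peristalsis (wave frame, t = 0): most occluded
# is the wave trough at (k - 1/4) lambda, least the crest at (k - 3/4) lambda.
release_position <- function(case) {
  geom <- case$geometry
  lam <- geom$wavelength
  if (case$motility == "segmentation") {
    k <- ceiling(geom$n_pockets / 2)
    zc <- pocket_centre(geom, k)
    z <- if (case$release == "most_occluded") zc else zc + lam / 4
  } else {
    # near the wave-frame upstream (+z) end so backward-drifting fluid stays
    # inside the 30-pocket domain for the full run
    k <- geom$n_pockets - 2L
    z <- if (case$release == "most_occluded") (k - 0.25) * lam else (k - 0.75) * lam
  }
  list(pocket = k, z = z)
}
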