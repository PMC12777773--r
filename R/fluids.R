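#' Fluid rheology model
#'
#' Defines a luminal fluid: density plus either a Newtonian viscosity or a
#' shear-thinning power-law (consistency K, flow index n) with a shear-rate
#' clamp that regularises the singular zero-shear limit. All simulations run
#' at body temperature (37 degC); viscosities are apparent values at that
#' temperature.
#'
#' @param name fluid label.
#' @param density mass density (g/cm^3).
#' @param mu Newtonian viscosity (mPa*s); give either `mu` or (`K`, `n`).
#' @param K power-law consistency (mPa*s^n).
#' @param n power-law flow index in (0, 1]; n = 1 is the Newtonian limit.
#' @param shear_clamp two positive, ordered shear rates (1/s) to which the
#'   local shear rate is clamped when evaluating the power-law viscosity.
#' @param temperature temperature (degC), fixed at 37 for the shipped fluids.
#' @return An object of class `fluid_model`.
#' @export
fluid_model <- function(name, density, mu = NULL, K = NULL, n = NULL,
                        shear_clamp = c(1e-3, 1e3), temperature = 37) {
  stopifnot(density > 0)
  if (!is.null(mu)) {
    stopifnot(mu > 0)
    rheology <- list(type = "newtonian", mu = mu)
  } else {
    stopifnot(!is.null(K), !is.null(n), K > 0, n > 0, n <= 1)
    stopifnot(length(shear_clamp) == 2, all(shear_clamp > 0),
              shear_clamp[1] < shear_clamp[2])
    rheology <- list(type = "power_law", K = K, n = n,
                     shear_clamp = shear_clamp)
  }
  structure(list(name = name, density = density, rheology = rheology,
                 temperature = temperature),
            class = "fluid_model")
}

#' @export
print.fluid_model <- function(x, ...) {
  r <- x$rheology
  desc <- if (r$type == "newtonian") sprintf("Newtonian, mu = %.4g mPa*s", r$mu)
          else sprintf("power law, K = %.4g mPa*s^n, n = %.3f", r$K, r$n)
  cat(sprintf("<fluid_model> %s: rho = %.4g g/cm^3, %s\n", x$name, x$density, desc))
  invisible(x)
}

# viscosity of water at 37 degC (mPa*s), standard correlation value; used as
# the Stokes-Einstein reference solvent
MU_WATER_37 <- 0.6913

#' Bundled fluid registry
#'
#' `"water_37C"`: Newtonian water at body temperature (0.6913 mPa*s,
#' 0.9933 g/cm^3). `"nutridrink_default"`: documented stand-in power-law
#' parameters for a diluted nutritional drink (K = 6 mPa*s^n, n = 0.65,
#' rho = 1.05 g/cm^3). The consistency is calibrated once so the simulated
#' drink reproduces the reported drink-versus-water flow contrasts of the
#' motility study (about +19% peak luminal velocity and a roughly
#' 2.5-fold surface shear stress); the published study does not tabulate
#' its measured rheology, so these remain synthetic stand-ins that should
#' be overridden via [fluid_model()] when fitted parameters are available.
#'
#' @param name registered fluid name.
#' @return A [fluid_model()].
#' @export
fluid_registry <- function(name = c("water_37C", "nutridrink_default")) {
  name <- match.arg(name)
  switch(name,
    water_37C = fluid_model("water_37C", density = 0.9933, mu = MU_WATER_37),
    nutridrink_default = fluid_model("nutridrink_default", density = 1.05,
                                     K = 6, n = 0.65)
  )
}

#' Apparent viscosity at a given shear rate
#'
#' Newtonian fluids return their constant viscosity; power-law fluids return
#' \eqn{K \dot\gamma^{n-1}} with the shear rate clamped to the fluid's
#' regularisation window.
#'
#' @param fluid a [fluid_model()].
#' @param shear_rate shear rate magnitude (1/s), vectorised, >= 0.
#' @return apparent viscosity (mPa*s).
#' @export
effective_viscosity <- function(fluid, shear_rate) {
  stopifnot(inherits(fluid, "fluid_model"), all(shear_rate >= 0))
  r <- fluid$rheology
  if (r$type == "newtonian") {
    rep_len(r$mu, length(shear_rate))
  } else {
    g <- pmin(pmax(shear_rate, r$shear_clamp[1]), r$shear_clamp[2])
    r$K * g^(r$n - 1)
  }
}

#' Species transport model
#'
#' Defines a dissolved species: initial (released) concentration and a
#' diffusivity model in water at 37 degC, either constant or
#' concentration-dependent. Diffusivities in other fluids are obtained by
#' Stokes-Einstein rescaling with a single reference viscosity
#' (see [species_diffusivity()]).
#'
#' @param name species label.
#' @param initial_concentration released peak concentration c_i (mM).
#' @param D constant diffusivity in water at 37 degC (cm^2/s), or `NULL`
#'   when `D_fun` is given.
#' @param D_fun function of concentration (mM) returning the diffusivity in
#'   water at 37 degC (cm^2/s).
#' @return An object of class `species_model`.
#' @export
species_model <- function(name, initial_concentration, D = NULL, D_fun = NULL) {
  stopifnot(initial_concentration > 0)
  if (is.null(D_fun)) {
    stopifnot(!is.null(D), D > 0)
    D_fun <- function(c) rep_len(D, length(c))
  }
  structure(list(name = name, initial_concentration = initial_concentration,
                 D_fun = D_fun),
            class = "species_model")
}

# insulin diffusivity in water at 37 degC (cm^2/s)
D_INSULIN <- 1.11e-6

# C10 diffusivity anchors relative to insulin: 3.15x at 100 mM, 5.50x at 1 mM
C10_RATIO_100 <- 3.15
C10_RATIO_1 <- 5.50

# C10 diffusivity in water at 37 degC: linear in log10(concentration) between
# the 1 mM and 100 mM anchors, clamped outside [1, 100] mM. Two anchors only,
# so the log-linear form is the smooth monotone choice.
c10_diffusivity_water <- function(conc) {
  d1 <- C10_RATIO_1 * D_INSULIN
  d100 <- C10_RATIO_100 * D_INSULIN
  lc <- pmin(pmax(log10(pmax(conc, .Machine$double.xmin)), 0), 2)
  d1 + (d100 - d1) * lc / 2
}

#' Bundled species registry
#'
#' `"insulin"`: 2 mM initial concentration, constant diffusivity
#' 1.11e-6 cm^2/s in water at 37 degC. `"C10"` (sodium caprate): 100 mM
#' initial concentration with a concentration-dependent diffusivity
#' interpolated in log10(c) between 5.50x insulin at 1 mM and 3.15x insulin
#' at 100 mM (clamped outside 1-100 mM).
#'
#' @param name registered species name.
#' @return A [species_model()].
#' @export
species_registry <- function(name = c("insulin", "C10")) {
  name <- match.arg(name)
  switch(name,
    insulin = species_model("insulin", 2, D = D_INSULIN),
    C10 = species_model("C10", 100, D_fun = c10_diffusivity_water)
  )
}

#' Species diffusivity in a given fluid
#'
#' Evaluates the species' diffusivity in water at 37 degC at concentration
#' `conc`, then applies Stokes-Einstein viscosity scaling
#' \eqn{D_{fluid} = D_{water} \, \mu_{water,37} / \mu_{ref}} where
#' \eqn{\mu_{ref}} is the fluid's apparent viscosity at a single reference
#' shear rate (temperature is fixed at 37 degC). The scalar reference shear
#' rate represents the characteristic contraction shear
#' \eqn{(2\pi\delta/t_p)/r_0} of the driving motility; the scaling is a
#' scalar adjustment, not field-coupled.
#'
#' @param species a [species_model()].
#' @param conc local concentration (mM), vectorised, >= 0.
#' @param fluid a [fluid_model()]; default water (no rescaling).
#' @param reference_shear_rate shear rate (1/s) at which the fluid's
#'   apparent viscosity is taken for the Stokes-Einstein ratio.
#' @return diffusivity (cm^2/s).
#' @examples
#' ins <- species_registry("insulin")
#' species_diffusivity(ins, 2) # 1.11e-6
#' @export
species_diffusivity <- function(species, conc, fluid = fluid_registry("water_37C"),
                                reference_shear_rate = 1) {
  stopifnot(inherits(species, "species_model"))
  if (any(conc < 0)) stop("negative concentration passed to species_diffusivity()")
  d_water <- species$D_fun(conc)
  mu_ref <- effective_viscosity(fluid, reference_shear_rate)
  d_water * MU_WATER_37 / mu_ref
}

# characteristic contraction shear rate of a case: wall speed scale / r0
reference_shear_rate <- function(case) {
  geom <- case$geometry
  if (case$motility == "segmentation") {
    (two_pi * geom$amplitude / geom$period) / geom$rest_radius
  } else {
    (geom$wave_speed * two_pi * geom$amplitude / geom$wavelength) / geom$rest_radius
  }
}
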