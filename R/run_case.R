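# Orchestration of one motility case: flow + two-species transport +
# online delivery metrics.

#' Run one motility case end to end
#'
#' For segmentation: marches the moving-wall flow and the two-species
#' transport together on the 3-wavelength domain (periodic flow, open
#' scalar ends) over the case's periods, releasing the bolus at t = 0.
#' For peristalsis: solves the steady wave-frame flow over one wavelength,
#' tiles it over the case's 30-pocket domain, and advances transport in the
#' wave frame. Delivery metrics are sampled as the run progresses.
#'
#' @param case a [motility_case()].
#' @param resolution preset name or list, see [resolution_preset()].
#' @param n_periods override the case's period count.
#' @param sigma_b bolus standard deviation (cm); default r0/10.
#' @param sample_every metric sampling interval in flow steps.
#' @param extra_releases optional list of further [release_spec()]s whose
#'   species are transported in the same pass (cheap co-simulation of
#'   alternative release positions); results returned in `extras`.
#' @return an object of class `case_result`; see [tidy.case_result()],
#'   [glance.case_result()], [surface_concentration_stats()].
#' @export
run_case <- function(case, resolution = "coarse", n_periods = NULL,
                     sigma_b = NULL, sample_every = 2L,
                     extra_releases = NULL) {
  stopifnot(inherits(case, "motility_case"))
  if (case$motility == "segmentation") {
    run_case_segmentation(case, resolution, n_periods, sigma_b, sample_every,
                          extra_releases)
  } else {
    run_case_peristalsis(case, resolution, n_periods, sigma_b, sample_every)
  }
}

# collector for the online metrics of one transport state
new_metric_collector <- function(case, grid, release) {
  geom <- case$geometry
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$profiles <- list()
  e$layers <- c(D15 = 2 * geom$rest_radius / 15, D30 = 2 * geom$rest_radius / 30)
  e$zwin <- release$z_pocket_centre + c(-0.5, 0.5) * geom$wavelength
  e$peak <- lapply(case$species, function(s) list(c = 0, t = NA, z = NA, r = NA))
  names(e$peak) <- vapply(case$species, `[[`, "", "name")
  e$ci <- stats::setNames(
    vapply(case$species, `[[`, numeric(1), "initial_concentration"),
    names(e$peak))
  e
}

collect_metrics <- function(e, st, case, t, frame_shift = 0) {
  if (length(st$conc) < length(e$peak)) {
    e$peak <- e$peak[names(st$conc)]
    e$ci <- e$ci[match(names(st$conc), names(e$ci))]
  }
  nw15 <- near_wall_pct_state(st, e$layers["D15"])
  nw30 <- near_wall_pct_state(st, e$layers["D30"])
  esc <- escape_pct_state(st, e$zwin[1], e$zwin[2])
  tp <- case$geometry$period
  for (s in seq_along(st$conc)) {
    cw <- wall_concentration(st$grid, st$conc[[s]]) / e$ci[s]
    imax <- which.max(cw)
    cmax <- cw[imax]
    nm <- names(e$peak)[s]
    if (cmax > e$peak[[nm]]$c) {
      e$peak[[nm]] <- list(c = cmax, t = t,
                           z = st$grid$zc[imax] + frame_shift * t,
                           r = st$h[imax])
    }
    e$rows[[length(e$rows) + 1L]] <- list(
      t = t, period = t / tp, species = nm,
      nearwall_D15_pct = nw15[s], nearwall_D30_pct = nw30[s],
      escape_pct = esc[s], wall_cmax_norm = cmax
    )
  }
  invisible(e)
}

collect_profile <- function(e, st, t) {
  for (s in seq_along(st$conc)) {
    cw <- wall_concentration(st$grid, st$conc[[s]]) / e$ci[s]
    e$profiles[[length(e$profiles) + 1L]] <- tibble::tibble(
      t = t, species = names(e$peak)[s], z = st$grid$zc, c_norm = cw
    )
  }
  invisible(e)
}

finish_result <- function(case, e, tr, flow_summary, resolution, extras = NULL) {
  metrics <- dplyr::bind_rows(lapply(e$rows, tibble::as_tibble))
  peaks <- dplyr::bind_rows(lapply(names(e$peak), function(nm) {
    p <- e$peak[[nm]]
    tibble::tibble(species = nm, c_norm = p$c, t = p$t, z_lab = p$z,
                   r_wall = p$r)
  }))
  structure(list(
    case = case, resolution = resolution,
    metrics = metrics,
    profiles = dplyr::bind_rows(e$profiles),
    peaks = peaks,
    layers = e$layers,
    released = tr$released, escaped = tr$escaped,
    final_moles = total_moles(tr),
    final_state = tr,
    flow_summary = flow_summary,
    extras = extras
  ), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat("<case_result>\n")
  print(x$case)
  g <- glance.case_result(x)
  cat(sprintf("  peak |u| = %.3f cm/s, Re = %.2f, Pe = %.0f\n",
              g$umax, g$reynolds, g$peclet))
  for (i in seq_len(nrow(x$peaks))) {
    cat(sprintf("  %s: peak wall c/ci = %.4f at t = %.1f s\n",
                x$peaks$species[i], x$peaks$c_norm[i], x$peaks$t[i]))
  }
  invisible(x)
}

run_case_segmentation <- function(case, resolution, n_periods, sigma_b,
                                  sample_every, extra_releases) {
  geom <- case$geometry
  n_periods <- n_periods %||% case$n_periods
  res <- resolution_preset(resolution)
  # flow on one wavelength (the kinematics are lambda-periodic); transport
  # on a finer grid spanning the full pocket count, fed by exactly
  # conservative streamfunction-refined face fluxes
  prob <- segmentation_problem(case, res, n_wavelengths = 1L)
  gc <- prob$grid
  n_tile <- geom$n_pockets
  gf <- flow_grid(n_tile * geom$wavelength,
                  (res$scalar_nz_per_wavelength %||% res$nz_per_wavelength) *
                    n_tile,
                  res$scalar_nr %||% res$nr,
                  res$scalar_stretch %||% res$stretch)
  plan <- flux_refine_plan(gc, gf, n_tile)
  tp <- geom$period
  rel <- release_spec(case, sigma_b)
  rel$z_pocket_centre <- pocket_centre(geom, rel$pocket)
  h0f <- prob$hfun(gf$zc, 0)
  tr <- initialize_bolus(case, gf, h0f, rel)
  coll <- new_metric_collector(case, gf, rel)
  collect_metrics(coll, tr, case, 0)

  extra_states <- NULL
  extra_colls <- NULL
  if (!is.null(extra_releases)) {
    extra_states <- lapply(extra_releases, function(r) {
      stx <- initialize_bolus(case, gf, h0f, r)
      if (!is.null(r$species)) {         # transport a subset of the species
        stx$conc <- stx$conc[r$species]
        stx$species <- stx$species[r$species]
        stx$released <- stx$released[r$species]
        stx$escaped <- stx$escaped[r$species]
      }
      stx
    })
    extra_colls <- lapply(extra_releases, function(r) {
      r$z_pocket_centre <- r$z_pocket_centre %||% pocket_centre(geom, r$pocket)
      new_metric_collector(case, gf, r)
    })
    for (i in seq_along(extra_states)) {
      collect_metrics(extra_colls[[i]], extra_states[[i]], case, 0)
    }
  }

  ref_shear <- reference_shear_rate(case)
  umax_settled <- 0
  tau_samples <- c()
  st <- flow_initial_state(prob)
  dt <- prob$dt_max / 10
  t_end <- n_periods * tp
  next_profile <- tp
  kstep <- 0L
  # the scalar advances on time-averaged fluxes of `pack` flow steps
  # (PPM handles the larger sweep Courant numbers; halves transport cost)
  pack <- 2L
  acc <- NULL
  while (st$t < t_end - 1e-9) {
    dts <- min(dt, t_end - st$t)
    st1 <- flow_step(prob, st, dts)
    if (is.null(acc)) {
      acc <- list(Fz = st1$fluxZ * dts, t0 = st$t, n = 1L)
    } else {
      acc$Fz <- acc$Fz + st1$fluxZ * dts
      acc$n <- acc$n + 1L
    }
    flush_pack <- acc$n >= pack || st1$t >= t_end - 1e-9
    if (flush_pack) {
      dt_pack <- st1$t - acc$t0
      Fz_bar <- acc$Fz / dt_pack
      h0_f <- prob$hfun(gf$zc, acc$t0)
      h1_f <- prob$hfun(gf$zc, st1$t)
      hz_f <- prob$hzfun(gf$zc, (acc$t0 + st1$t) / 2)
      h0_c <- prob$hfun(gc$zc, acc$t0)
      h1_c <- prob$hfun(gc$zc, st1$t)
      gsq_c <- (h1_c^2 - h0_c^2) / dt_pack
      gsq_f <- (h1_f^2 - h0_f^2) / dt_pack
      fine <- refine_fluxes(plan, Fz_bar, gsq_c, gsq_f)
      Vol0f <- pi * outer(h0_f^2, diff(gf$etaf^2)) * gf$dz
      Vol1f <- pi * outer(h1_f^2, diff(gf$etaf^2)) * gf$dz
      step_scalar <- function(trs) {
        nsub <- scalar_substeps(trs, fine$Fz, fine$Fe, Vol0f, dt_pack)
        for (q in seq_len(nsub)) {
          frac0 <- (q - 1) / nsub; frac1 <- q / nsub
          V0 <- Vol0f + (Vol1f - Vol0f) * frac0
          V1 <- Vol0f + (Vol1f - Vol0f) * frac1
          trs <- scalar_step(trs, fine$Fz, fine$Fe, V0, V1,
                             h0_f, h1_f, hz_f, dt_pack / nsub,
                             case$fluid, ref_shear)
        }
        trs
      }
      tr <- step_scalar(tr)
      if (!is.null(extra_states)) {
        extra_states <- lapply(extra_states, step_scalar)
      }
      acc <- NULL
    }
    st <- st1
    kstep <- kstep + 1L
    if (st$t > min(tp, t_end / 2)) {
      umax_settled <- max(umax_settled, max(sqrt(st$uz^2 + st$ur^2)))
    }
    if (flush_pack &&
        (kstep %% sample_every == 0L || st$t >= t_end - 1e-9)) {
      collect_metrics(coll, tr, case, st$t)
      if (!is.null(extra_states)) {
        for (i in seq_along(extra_states)) {
          collect_metrics(extra_colls[[i]], extra_states[[i]], case, st$t)
        }
      }
    }
    if (flush_pack && st$t >= next_profile - 1e-9) {
      collect_profile(coll, tr, st$t)
      fs <- field_state(prob, st)
      tau_samples <- c(tau_samples, wall_shear_stress(fs)$average)
      next_profile <- next_profile + tp
    }
    dt <- next_dt(prob, st, dts)
  }
  umax <- umax_settled
  Dmin <- min(vapply(case$species, function(sp)
    min(species_diffusivity(sp, sp$initial_concentration, case$fluid,
                            ref_shear)), numeric(1)))
  flow_summary <- tibble::tibble(
    umax = umax,
    reynolds = reynolds_number(case, umax),
    peclet = umax * geom$rest_radius / Dmin,
    tau_avg_mPa = mean(tau_samples), tau_max_mPa = max(tau_samples)
  )
  extras <- NULL
  if (!is.null(extra_states)) {
    extras <- lapply(seq_along(extra_states), function(i) {
      finish_result(case, extra_colls[[i]], extra_states[[i]], flow_summary,
                    resolution)
    })
  }
  finish_result(case, coll, tr, flow_summary, resolution, extras)
}

#' Transport of the released bolus under steady peristaltic pumping
#'
#' Tiles the converged wave-frame flow of one wavelength across the case's
#' full pocket count and integrates the two-species transport in the wave
#' frame (static wall, steady velocity), with open axial ends. Errors if
#' the bolus reaches the downstream (wave-frame) end before the run is over.
#'
#' @param case a peristalsis [motility_case()].
#' @param wave_flow a wave-frame `field_state` from
#'   [solve_peristalsis_flow()] (carrying its face fluxes).
#' @param n_periods override the case's period count.
#' @param sigma_b bolus standard deviation (cm).
#' @param sample_every metric sampling interval in transport steps.
#' @param scalar_resolution list (`nz_per_wavelength`, `nr`, `stretch`) for
#'   the transport grid; the default doubles the wave-frame flow grid.
#' @param max_exit_fraction abort when this fraction of any species has left
#'   through the wave-frame downstream end (domain too short); the fast
#'   throat jet legitimately carries a tail of the bolus out of the
#'   30-pocket domain late in a 30-period run, which is accounted as
#'   escaped mass.
#' @return a `case_result`.
#' @export
peristalsis_transport <- function(case, wave_flow, n_periods = NULL,
                                  sigma_b = NULL, sample_every = 2L,
                                  scalar_resolution = NULL,
                                  max_exit_fraction = 0.15) {
  stopifnot(inherits(case, "motility_case"), case$motility == "peristalsis")
  geom <- case$geometry
  n_periods <- n_periods %||% case$n_periods
  gw <- wave_flow$grid
  n_tile <- geom$n_pockets
  sres <- scalar_resolution %||% list(
    nz_per_wavelength = 2L * gw$Nz, nr = 2L * gw$Nr, stretch = 1.6)
  g <- flow_grid(geom$wavelength * n_tile,
                 sres$nz_per_wavelength * n_tile, sres$nr, sres$stretch)
  plan <- flux_refine_plan(gw, g, n_tile)
  fine <- refine_fluxes(plan, wave_flow$fluxZ,
                        rep(0, gw$Nz), rep(0, g$Nz))  # static wall
  Fz <- fine$Fz
  Fe <- fine$Fe
  hfun1 <- function(z) geom$rest_radius +
    geom$amplitude * sin(2 * pi * z / geom$wavelength)
  h <- hfun1(g$zc)
  hz <- geom$amplitude * (2 * pi / geom$wavelength) *
    cos(2 * pi * g$zc / geom$wavelength)

  rel <- release_spec(case, sigma_b)
  rel$z_pocket_centre <- pocket_centre(geom, rel$pocket)
  tr <- initialize_bolus(case, g, h, rel)
  coll <- new_metric_collector(case, g, rel)
  collect_metrics(coll, tr, case, 0)

  tp <- geom$period                      # lambda / c
  t_end <- n_periods * tp
  Vol <- cell_volumes(g, h)
  ref_shear <- reference_shear_rate(case)
  nsub <- scalar_substeps(tr, Fz, Fe, Vol, tp)
  dt <- tp / nsub
  nstep <- ceiling(t_end / dt)
  dt <- t_end / nstep
  next_profile <- tp
  for (k in seq_len(nstep)) {
    tr <- scalar_step(tr, Fz, Fe, Vol, Vol, h, h, hz, dt,
                      case$fluid, ref_shear)
    t_now <- k * dt
    if (k %% sample_every == 0L || k == nstep) {
      collect_metrics(coll, tr, case, t_now, frame_shift = geom$wave_speed)
    }
    if (t_now >= next_profile - 1e-9) {
      collect_profile(coll, tr, t_now)
      next_profile <- next_profile + tp
      # the fast wave-frame jet carries a tail of the bolus toward the
      # downstream end; abort only if a substantial fraction leaves
      lost <- max(tr$escaped / tr$released)
      if (lost > max_exit_fraction) {
        stop("bolus is reaching the wave-frame downstream end of the ",
             n_tile, "-pocket domain before ", n_periods,
             " periods; extend the domain (more pockets).")
      }
    }
  }
  umax_lab <- max(sqrt((wave_flow$uz + geom$wave_speed)^2 + wave_flow$ur^2))
  Dmin <- min(vapply(case$species, function(sp)
    min(species_diffusivity(sp, sp$initial_concentration, case$fluid,
                            ref_shear)), numeric(1)))
  ws <- wall_shear_stress(wave_flow)
  flow_summary <- tibble::tibble(
    umax = umax_lab,
    reynolds = reynolds_number(case, umax_lab),
    peclet = umax_lab * geom$rest_radius / Dmin,
    tau_avg_mPa = ws$average, tau_max_mPa = ws$max
  )
  finish_result(case, coll, tr, flow_summary, resolution = "wave-frame")
}

run_case_peristalsis <- function(case, resolution, n_periods, sigma_b,
                                 sample_every) {
  wf <- solve_peristalsis_flow(case, resolution)
  peristalsis_transport(case, wf, n_periods, sigma_b, sample_every)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the delivery-metric time series of a case result
#' @param x a `case_result`.
#' @param ... unused.
#' @return tibble: one row per sample time and species.
#' @method tidy case_result
#' @export
tidy.case_result <- function(x, ...) x$metrics

#' One-row summary of a case result
#' @param x a `case_result`.
#' @param ... unused.
#' @return tibble with flow summary, per-species peak wall concentrations
#'   and final near-wall percentages.
#' @method glance case_result
#' @export
glance.case_result <- function(x, ...) {
  pk <- x$peaks
  out <- x$flow_summary
  for (i in seq_len(nrow(pk))) {
    out[[paste0("peak_cnorm_", pk$species[i])]] <- pk$c_norm[i]
    out[[paste0("peak_time_", pk$species[i])]] <- pk$t[i]
  }
  mb <- (sum(x$final_moles) + sum(x$escaped)) / sum(x$released) - 1
  out$mass_balance_error <- mb
  out
}
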