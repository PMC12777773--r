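# Configuration (YAML), output serialisation (CSV, VTK) and the thin
# command-line entry points.

#' Read and validate a run configuration
#'
#' A run configuration is a YAML document describing either a single case
#' (`case:`) or a sweep (`grid:`), plus run controls. All units are fixed:
#' cm, s, mL, mM, mPa*s. Unknown fields are rejected; missing required
#' fields are reported with their full path.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, where = path)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @param where label used in error messages.
#' @export
validate_run_config <- function(cfg, where = "config") {
  need <- function(x, field, parent) {
    if (is.null(x[[field]])) {
      stop(where, ": missing required field `", parent, field, "`",
           call. = FALSE)
    }
    x[[field]]
  }
  if (is.null(cfg$case) && is.null(cfg$grid)) {
    stop(where, ": need either `case:` or `grid:`", call. = FALSE)
  }
  check_case <- function(cs, parent) {
    motility <- need(cs, "motility", parent)
    if (!motility %in% c("segmentation", "peristalsis")) {
      stop(where, ": `", parent, "motility` must be segmentation|peristalsis",
           call. = FALSE)
    }
    need(cs, "intensity", parent)
    need(cs, "pocket_volume", parent)
    need(cs, "occlusion_ratio", parent)
    cs$fluid <- cs$fluid %||% "nutridrink_default"
    cs$release <- cs$release %||% "most_occluded"
    cs$n_periods <- cs$n_periods %||% 30L
    cs
  }
  if (!is.null(cfg$case)) cfg$case <- check_case(cfg$case, "case.")
  cfg$resolution <- cfg$resolution %||% "coarse"
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "lumenflow_out"
  cfg$snapshots_per_period <- cfg$snapshots_per_period %||% 0
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML (lossless round trip)
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

case_from_config <- function(cs) {
  motility_case(cs$motility, cs$intensity, cs$fluid %||% "nutridrink_default",
                cs$pocket_volume, cs$occlusion_ratio,
                cs$release %||% "most_occluded",
                n_periods = cs$n_periods %||% 30L,
                wavelength = cs$wavelength)
}

#' Write a field snapshot as a legacy-ASCII VTK structured grid
#'
#' Points are the physical (z, r) positions of the boundary-fitted cells
#' (swept surface written as a 2-D structured grid, third coordinate 0);
#' point data carry the velocity components, pressure and shear rate.
#'
#' @param state a `field_state`.
#' @param path output `.vtk` path.
#' @export
write_vtk <- function(state, path) {
  g <- state$grid
  Nz <- g$Nz; Nr <- g$Nr
  rmat <- g$eta_mat * matrix(state$h, Nz, Nr)
  zmat <- matrix(g$zc, Nz, Nr)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("lumenflow field t=%.6f", state$time)
  wl("ASCII")
  wl("DATASET STRUCTURED_GRID")
  wl("DIMENSIONS %d %d 1", Nz, Nr)
  wl("POINTS %d float", Nz * Nr)
  pts <- cbind(as.vector(zmat), as.vector(rmat), 0)
  utils::write.table(format(pts, digits = 7, scientific = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  wl("POINT_DATA %d", Nz * Nr)
  scalar <- function(name, m) {
    wl("SCALARS %s float 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(format(as.vector(m), digits = 7, scientific = TRUE), con)
  }
  scalar("uz", state$uz)
  scalar("ur", state$ur)
  scalar("p", state$p)
  scalar("shear_rate", state$shear_rate)
  invisible(path)
}

#' Write the tidy outputs of a case result
#'
#' `metrics.csv` (per-sample delivery metrics), `profiles.csv` (wall
#' concentration profiles), `summary.csv` (one-row glance).
#'
#' @param result a `case_result`.
#' @param dir output directory (created if needed).
#' @export
write_case_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(glance.case_result(result), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# ---- command-line entry points (used by inst/cli/lumenflow.R) ------------

#' Run one case from a configuration file
#' @param config_path YAML config with a `case:` block.
#' @return the `case_result`, invisibly; outputs land in the config's
#'   `output_dir`.
#' @export
cli_run_case <- function(config_path) {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$case)) stop("config has no `case:` block")
  case <- case_from_config(cfg$case)
  res <- run_case(case, cfg$resolution)
  write_case_outputs(res, cfg$output_dir)
  cfgout <- cfg
  cfgout$package_version <- as.character(utils::packageVersion("lumenflow"))
  write_run_config(cfgout, file.path(cfg$output_dir, "resolved_config.yaml"))
  message("case outputs written to ", cfg$output_dir)
  invisible(res)
}

#' Run a sweep from a configuration file
#' @param config_path YAML config with a `grid:` block (named lists of
#'   factor levels) and run controls.
#' @return the `sweep_result`, invisibly.
#' @export
cli_run_sweep <- function(config_path) {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$grid)) stop("config has no `grid:` block")
  gl <- cfg$grid
  grid <- do.call(sweep_grid, gl[intersect(names(gl),
    c("motility", "intensity", "fluid", "pocket_volume",
      "occlusion_ratio", "release"))])
  res <- run_sweep(grid, cfg$resolution,
                   n_periods = cfg$n_periods %||% 30L,
                   seed = cfg$seed, progress = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$table, file.path(cfg$output_dir, "sweep_table.csv"),
                   row.names = FALSE)
  message("sweep table written to ", cfg$output_dir)
  invisible(res)
}

#' Cluster and attribute an existing sweep table
#' @param table_path CSV written by [cli_run_sweep()] (or compatible).
#' @param seed RNG seed.
#' @param k clusters.
#' @param output_dir where to write `clusters.csv`, `attribution.csv`,
#'   `attribution_summary.json`.
#' @param train_on passed to [attribute_factors()].
#' @return the `attribution_result`, invisibly.
#' @export
cli_analyze <- function(table_path, seed = 1L, k = 4L,
                        output_dir = dirname(table_path),
                        train_on = "largest_cluster") {
  tab <- tibble::as_tibble(utils::read.csv(table_path,
                                           stringsAsFactors = FALSE))
  if (is.null(tab$cs)) stop("table has no `cs` column: ", table_path)
  cl <- cluster_cases(tab, k = k, seed = seed)
  at <- attribute_factors(tab, seed = seed, k = k, train_on = train_on)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cl$table, file.path(output_dir, "clusters.csv"),
                   row.names = FALSE)
  utils::write.csv(at$ranking, file.path(output_dir, "attribution.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = as.list(at$metrics), best_params = as.list(at$best_params),
         clusters = as.list(tidy.cluster_result(cl))),
    file.path(output_dir, "attribution_summary.json"), auto_unbox = TRUE
  )
  message("analysis outputs written to ", output_dir)
  invisible(at)
}

#' Run named verification fixtures
#' @param names fixture names among `poiseuille`, `diffusion`,
#'   `manufactured_solution`; `"all"` runs every one.
#' @return named list of fixture outputs, invisibly; prints a short report.
#' @export
cli_verify <- function(names = "all") {
  all_fx <- list(poiseuille = poiseuille_fixture(),
                 diffusion = diffusion_fixture(),
                 manufactured_solution = manufactured_solution_fixture())
  if (identical(names, "all")) names <- names(all_fx)
  out <- lapply(names, function(nm) {
    fx <- all_fx[[nm]]
    if (is.null(fx)) stop("unknown fixture: ", nm)
    r <- fx$run()
    message(nm, ": ", paste(names(r)[vapply(r, is.numeric, TRUE) &
                                       lengths(r) == 1],
                            signif(unlist(r[vapply(r, is.numeric, TRUE) &
                                              lengths(r) == 1]), 3),
                            sep = " = ", collapse = ", "))
    r
  })
  names(out) <- names
  invisible(out)
}
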