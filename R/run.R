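## Experiment runner and standard-format outputs: YAML run configs, TSV
## time-series tables, legacy-VTK unstructured-grid snapshots, JSON run
## manifests, and figure-style reproduction presets.

#' Read a run configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks `mesh` (arguments of [mesh_spec()]), `model` (fields
#' `gpcr_variant`, `legi_scheme`, `sten`, `gpcr`, `legi`, `sten_params`
#' overrides, `perturbation`), `stimulus` (`kind` = none | step |
#' staircase | pulses | gradient plus its arguments), `seeds` (`mesh`,
#' `cell`, `trajectory`), `t_end`, `record_dt`, `record_species`, `out`.
#'
#' @param path YAML file path, or a list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(mesh = list(), model = list(), stimulus = list(kind = "none"),
                   seeds = list(mesh = 1L, cell = 1L, trajectory = 1L),
                   t_end = 60, record_dt = 0.5,
                   record_species = NULL, out = "rdmecell_run")
  for (n in names(defaults))
    if (is.null(cfg[[n]])) cfg[[n]] <- defaults[[n]]
  if (cfg$record_dt <= 0) stop("record cadence must be > 0")
  for (s in names(cfg$seeds)) cfg$seeds[[s]] <- as.integer(cfg$seeds[[s]])
  structure(cfg, class = "run_config")
}

build_config_objects <- function(cfg) {
  spec <- do.call(mesh_spec, c(cfg$mesh, list(mesher_seed = cfg$seeds$mesh)))
  mesh <- build_shell_mesh(spec)
  m <- cfg$model
  variant <- if (is.null(m$gpcr_variant)) "full" else m$gpcr_variant
  scheme <- if (is.null(m$legi_scheme)) "implicit_difference" else m$legi_scheme
  gp <- do.call(gpcr_params, if (is.null(m$gpcr)) list() else m$gpcr)
  lg <- do.call(legi_params, c(list(scheme = scheme),
                               if (is.null(m$legi)) list() else m$legi))
  st <- NULL
  if (isTRUE(m$sten) || !is.null(m$sten_params)) {
    st <- do.call(sten_params,
                  if (is.null(m$sten_params)) list() else m$sten_params)
    if (!is.null(m$perturbation))
      st <- apply_threshold_perturbation(
        st, sten_perturbation(m$perturbation$kind,
                              unlist(m$perturbation$magnitude)))
  }
  if (cfg$seeds$cell > 1 || isTRUE(m$sample_cell)) {
    gp <- sample_cell_parameters(gp, cfg$seeds$cell)
    if (!is.null(st)) st <- sample_cell_parameters(st, cfg$seeds$cell + 1L)
  }
  modules <- if (is.null(m$modules)) NULL else m$modules
  model <- build_signaling_model(gp, lg, st, gpcr_variant = variant,
                                 modules = modules)
  stim <- config_stimulus(cfg$stimulus, gp, mesh)
  list(mesh = mesh, model = model, gpcr = gp, legi = lg, sten = st,
       stimulus = stim, variant = variant)
}

config_stimulus <- function(s, gp, mesh) {
  kind <- if (is.null(s$kind)) "none" else s$kind
  dose_of <- function(x) {
    ## doses given as "NN%" mean % receptor occupancy, numbers mean uM
    if (is.character(x) && grepl("%$", x))
      dose_response_map(gp)$inverse(as.numeric(sub("%$", "", x)))
    else as.numeric(x)
  }
  switch(kind,
    none = NULL,
    step = make_step_protocol(dose_of(s$dose), s$t_on %||% 0,
                              s$t_off %||% Inf),
    staircase = make_staircase_protocol(vapply(s$doses, dose_of, 0),
                                        as.numeric(s$times)),
    pulses = make_pulse_protocol(s$duration %||% 2, dose_of(s$dose),
                                 s$n_pulses %||% 1, s$delay,
                                 s$t_start %||% 0),
    gradient = {
      f <- calibrate_gradient(s$front %||% 99, s$back %||% 12, mesh,
                              params = gp)
      stimulus_protocol(list(list(t_start = s$t_on %||% 0,
                                  t_end = s$t_off %||% Inf, field = f)))
    },
    stop("unknown stimulus kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment
#'
#' Builds the mesh and model, equilibrates the initial state, simulates,
#' and writes (a) a JSON run manifest with all resolved parameters and
#' seeds, (b) whole-cell time series as a TSV table, (c) per-node snapshot
#' VTK files for the recorded species, and (d) a summary-statistics table.
#' Identical configuration and seeds give byte-identical tables.
#'
#' @param config path to a YAML config or a `run_config` list.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the trajectory and output paths.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  say <- function(...) if (!quiet) message(...)
  ob <- build_config_objects(cfg)
  say("mesh: ", nrow(ob$mesh$vertices), " nodes; model: ",
      length(ob$model$species), " species / ",
      length(ob$model$reactions), " reactions")
  init <- equilibrate_state(ob$model, ob$mesh, ob$gpcr, ob$legi, ob$sten,
                            seed = cfg$seeds$cell,
                            gpcr_variant = ob$variant)
  rec_sp <- cfg$record_species %||%
    intersect(c("RasGTP", "PIP2", "PKBs_star"), ob$model$species_names)
  say("simulating ", cfg$t_end, " s (seed ", cfg$seeds$trajectory, ") ...")
  traj <- simulate_nsm(ob$model, ob$mesh, init, t_end = cfg$t_end,
                       seed = cfg$seeds$trajectory, stimulus = ob$stimulus,
                       record = list(dt = cfg$record_dt, species = rec_sp))
  say("done: ", format(traj$n_events, big.mark = ","), " events")

  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ## manifest
  manifest <- list(package = "rdmecell",
                   version = as.character(utils::packageVersion("rdmecell")),
                   config = unclass(cfg),
                   n_nodes = nrow(ob$mesh$vertices),
                   n_tets = nrow(ob$mesh$tets),
                   n_events = traj$n_events)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ## whole-cell traces
  wc <- data.frame(time = traj$times, t(traj$wc), check.names = FALSE)
  utils::write.table(wc, file.path(out, "wholecell.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ## per-node VTK snapshots (at most 20, evenly spaced)
  snaps <- unique(round(seq(1, length(traj$times), length.out = 20)))
  for (i in snaps)
    write_vtk_snapshot(ob$mesh, traj, i,
                       file.path(out, sprintf("snapshot_%06.1fs.vtk",
                                              traj$times[i])))
  ## summary statistics over the last half of the run
  w <- c(mean(range(traj$times)), max(traj$times))
  stats_tab <- do.call(rbind, lapply(rec_sp, function(s) {
    ns <- noise_stats(traj, s, window = w)
    data.frame(species = s, mean_count = mean(ns$mean),
               mean_fano = ns$mean_fano, mean_cov = ns$mean_cov,
               internodal_fano = ns$internodal_fano_mean)
  }))
  utils::write.table(stats_tab, file.path(out, "summary_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(trajectory = traj, mesh = ob$mesh, out = out,
                 files = list.files(out, full.names = TRUE)))
}

#' Write a mesh (with optional point data) as legacy-VTK ASCII
#'
#' Unstructured-grid format readable by ParaView/VTK: tetrahedral cells
#' plus named per-node scalar arrays (e.g. species counts, node classes).
#'
#' @param mesh a `shell_mesh`.
#' @param path output file.
#' @param point_data named list of per-node numeric vectors.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  v <- mesh$vertices; tets <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rdmecell unstructured mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(tets), nrow(tets) * 5), con)
  utils::write.table(cbind(4L, tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(tets)), con)
  writeLines(as.character(rep(10L, nrow(tets))), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nmx in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nmx),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nmx]], digits = 9, trim = TRUE), con)
    }
  }
  invisible(path)
}

write_vtk_snapshot <- function(mesh, traj, i, path) {
  pd <- lapply(traj$node, function(X) X[, i])
  u <- one_molecule_uM(mesh$nodal_volumes)
  pd <- c(pd, stats::setNames(lapply(traj$node, function(X) X[, i] * u),
                              paste0(names(traj$node), "_uM")))
  pd$node_region <- as.integer(mesh$node_class$region)
  pd$node_side <- as.integer(mesh$node_class$side)
  write_vtk(mesh, path, pd)
}

#' Mesh summary as JSON-ready list
#' @param mesh a `shell_mesh`.
#' @export
mesh_summary <- function(mesh) {
  cls <- table(mesh$node_class$region, mesh$node_class$side)
  list(n_nodes = nrow(mesh$vertices), n_tets = nrow(mesh$tets),
       volume = mesh_volume(mesh),
       nodal_volume_mean = mean(mesh$nodal_volumes),
       nodal_volume_sd = stats::sd(mesh$nodal_volumes),
       membrane_basal = cls["membrane", "basal"],
       membrane_apical = cls["membrane", "apical"],
       cortex = sum(cls["cortex", ]),
       clamped_stiffness_entries = mesh$fem$clamped)
}

#' Reproduction presets
#'
#' Named run configurations reproducing the package's standard scenarios:
#' `fig2` (dose-response and receptor noise), `fig3` (staircase adaptation,
#' LEGI schemes), `fig4` (steep gradient), `fig5f` (global saturating
#' stimulus), `fig5h` (double pulse), `fig6` (gradient + global combined),
#' `fig7` (threshold perturbations), `s1` (mesh refinement). Scenario sizes
#' are desk-scale (coarse mesh, scaled totals) so a preset finishes in
#' minutes; see the methods vignette.
#'
#' @param name preset name.
#' @param out output directory.
#' @param seed trajectory seed.
#' @return a `run_config`.
#' @export
reproduce_preset <- function(name = c("fig2", "fig3", "fig4", "fig5f",
                                      "fig5h", "fig6", "fig7", "s1"),
                             out = file.path("runs", name), seed = 1L) {
  name <- match.arg(name)
  coarse <- list(h_min = 0.25, h_max = 0.75)
  scaled <- list(scale = 0.1)
  base <- list(mesh = coarse,
               seeds = list(mesh = 1L, cell = 1L, trajectory = seed),
               out = out)
  cfg <- switch(name,
    fig2 = c(base, list(
      model = list(modules = "gpcr"),
      stimulus = list(kind = "step", dose = "99%"),
      t_end = 240, record_dt = 1,
      record_species = list("HC", "LC", "SC", "PHC", "PLC"))),
    fig3 = c(base, list(
      model = list(legi_scheme = "explicit_difference"),
      stimulus = list(kind = "staircase", doses = list("0%", "4%", "99%"),
                      times = c(0, 120, 360, 600)),
      t_end = 600, record_dt = 1,
      record_species = list("Gbg", "Istar", "RR"))),
    fig4 = c(base, list(
      model = list(),
      stimulus = list(kind = "gradient", front = 99, back = 12, t_on = 60),
      t_end = 300, record_dt = 1,
      record_species = list("Gbg", "Istar"))),
    fig5f = c(base, list(
      model = list(sten = TRUE, sten_params = scaled),
      stimulus = list(kind = "step", dose = "99%", t_on = 60),
      t_end = 180, record_dt = 0.5,
      record_species = list("RasGTP", "PIP2", "PKBs_star"))),
    fig5h = c(base, list(
      model = list(sten = TRUE, sten_params = scaled),
      stimulus = list(kind = "pulses", dose = "99%", duration = 2,
                      n_pulses = 2, delay = 50, t_start = 60),
      t_end = 220, record_dt = 0.5,
      record_species = list("RasGTP", "PIP2", "PKBs_star"))),
    fig6 = c(base, list(
      model = list(sten = TRUE, sten_params = scaled),
      stimulus = list(kind = "gradient", front = 99, back = 12, t_on = 60),
      t_end = 240, record_dt = 0.5,
      record_species = list("RasGTP", "PIP2", "PKBs_star"))),
    fig7 = c(base, list(
      model = list(sten = TRUE, sten_params = scaled,
                   perturbation = list(kind = "pip2_depletion",
                                       magnitude = 0.5)),
      stimulus = list(kind = "none"),
      t_end = 240, record_dt = 0.5,
      record_species = list("RasGTP", "PIP2", "PKBs_star"))),
    s1 = c(base, list(
      model = list(modules = "gpcr"),
      stimulus = list(kind = "none"),
      t_end = 1, record_dt = 0.5,
      record_species = list("H"))))
  read_run_config(cfg)
}

#' Mesh-refinement study
#'
#' Rebuilds the shell mesh over a range of maximum node spacings and
#' reports node/element counts and the wall time of a 1-s diffusion-only
#' simulation, reproducing the refinement trend (node count grows as the
#' spacing shrinks).
#'
#' @param h_max_values maximum node spacings to test (um).
#' @param radius cell radius (um).
#' @return data.frame with `h_max`, `n_nodes`, `n_tets`, `sim_seconds`.
#' @export
mesh_refinement_study <- function(h_max_values = c(0.3, 0.45, 0.6, 0.9),
                                  radius = 5) {
  do.call(rbind, lapply(h_max_values, function(h) {
    mesh <- build_shell_mesh(mesh_spec(radius = radius, h_min = h / 3,
                                       h_max = h))
    mod <- rd_model(species("tracer", D = 1, localization = "all"),
                    reaction("none", "zeroth", k = 0, stoich = c(tracer = 1)))
    t0 <- Sys.time()
    simulate_nsm(mod, mesh, c(tracer = 5000), t_end = 1, seed = 1,
                 record = list(dt = 1))
    data.frame(h_max = h, n_nodes = nrow(mesh$vertices),
               n_tets = nrow(mesh$tets),
               sim_seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }))
}
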