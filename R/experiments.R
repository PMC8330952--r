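## Standard experiments: the runs behind the package's headline numbers.
## Each builds its own model and inputs, executes the method, and reduces
## the trajectory to the reported statistic. Stochastic experiments run at
## documented desk scales (see the methods vignette for the choices).

#' G-protein dissociation and reassociation half-times (mean-field)
#'
#' Integrates the G-protein reaction-rate equations with receptors fully
#' occupied at `t = 0` (dissociation) and then with occupancy set to zero
#' from the stimulated steady state (reassociation), and reports the
#' midpoint-crossing times of dissociated G_bg.
#'
#' @param params [legi_params()] (the `ratio` picks the rate set).
#' @param volumes compartment volumes (um^3) or a mesh.
#' @return list `t_half_dissociation`, `t_half_reassociation`,
#'   `g_basal`, `g_sat` (uM).
#' @export
gprotein_halftimes <- function(params = legi_params(),
                               volumes = default_volumes()) {
  if (inherits(volumes, c("shell_mesh", "voxel_graph")))
    volumes <- compartment_volumes(volumes)
  p <- params
  Vm <- volumes[["membrane"]]
  RL <- p$n_receptors / (MOLEC_PER_UM3_UM * Vm)
  GT <- p$G_total / (MOLEC_PER_UM3_UM * Vm)
  rhs <- function(t, y, parms)
    list((p$kE0 + p$kE * parms) * (GT - y[1]) - p$kmE * y[1]^2)
  gb <- sqrt(p$kE0 * GT / p$kmE)
  o1 <- deSolve::ode(c(g = gb), seq(0, 300, 0.01), rhs, RL)
  gss <- o1[nrow(o1), 2]
  t_d <- half_time(o1[, 1], o1[, 2], from = gb, to = gss)
  o2 <- deSolve::ode(c(g = gss), seq(0, 600, 0.01), rhs, 0)
  t_r <- half_time(o2[, 1], o2[, 2], direction = "decay",
                   from = gss, to = gb)
  list(t_half_dissociation = t_d, t_half_reassociation = t_r,
       g_basal = gb, g_sat = gss)
}

#' Receptor-noise experiment on the full-scale mesh
#'
#' Runs the receptor module alone on the full-scale mesh at the doses
#' giving 4% and ~100% receptor occupancy, from the corresponding
#' stationary initial split, and averages the per-node statistics of total
#' occupied receptors over replicates. Also runs the reduced two-state
#' variant at saturation for the model-order comparison.
#'
#' @param n_rep replicates (independent trajectory seeds).
#' @param window stationary window length, s (after a 30-s settling phase).
#' @param seed base seed.
#' @param mesh optionally a prebuilt full-scale mesh.
#' @return list of averaged statistics: `cov_low`, `cov_sat`,
#'   `fano_temporal`, `fano_internodal`, `sd_full`, `sd_reduced`,
#'   `mean_occupied_sat`.
#' @export
gpcr_noise_experiment <- function(n_rep = 5, window = 150, seed = 100,
                                  mesh = NULL) {
  gp <- gpcr_params(n_total_sd = 0)
  if (is.null(mesh)) mesh <- build_shell_mesh(mesh_spec())
  dr <- dose_response_map(gp)
  d4 <- dr$inverse(4); dsat <- dr$inverse(99)
  mem <- nodes_of(mesh, "membrane")
  t_end <- 30 + window
  one <- function(dose, variant, s) {
    mod <- build_gpcr_model(gp, variant)
    occ <- gpcr_occupied_names(variant)
    init <- equilibrate_receptors(gp, mesh, seed = s, variant = variant,
                                  camp_uM = dose)
    tr <- simulate_nsm(mod, mesh, init, t_end = t_end, seed = s,
                       stimulus = make_step_protocol(dose),
                       record = list(dt = 1, species = occ))
    noise_stats(tr, occ, window = c(30, t_end), nodes = mem)
  }
  acc <- list(cov_low = 0, cov_sat = 0, fano_temporal = 0,
              fano_internodal = 0, sd_full = 0, sd_reduced = 0,
              mean_occupied_sat = 0)
  for (r in seq_len(n_rep)) {
    s <- seed + 17L * r
    lo <- one(d4, "full", s)
    hi <- one(dsat, "full", s + 1L)
    rd <- one(dsat, "reduced", s + 2L)
    acc$cov_low <- acc$cov_low + lo$mean_cov
    acc$cov_sat <- acc$cov_sat + hi$mean_cov
    acc$fano_temporal <- acc$fano_temporal + hi$mean_fano
    acc$fano_internodal <- acc$fano_internodal + hi$internodal_fano_mean
    acc$sd_full <- acc$sd_full + hi$mean_sd
    acc$sd_reduced <- acc$sd_reduced + rd$mean_sd
    acc$mean_occupied_sat <- acc$mean_occupied_sat + mean(hi$mean)
  }
  lapply(acc, function(x) x / n_rep)
}

## Desk-scale configuration shared by the combined-model experiments:
## membrane-local, slow-diffusing inhibitor (valid for spatially uniform
## stimuli) at reduced copy numbers on a coarse mesh.
desk_config <- function(scale = 0.1, h = 1.2, D_I = 0.05,
                        scheme = "implicit_difference") {
  gp <- gpcr_params(scale = scale, n_total_sd = 0)
  lg <- suppressWarnings(legi_params(scheme = scheme, scale = scale,
                                     D_I = D_I,
                                     inhibitor_localization = "membrane",
                                     volume_ratio = 1))
  st <- sten_params(scale = scale)
  mesh <- build_shell_mesh(mesh_spec(h_min = h / 3, h_max = h))
  list(gp = gp, lg = lg, st = st, mesh = mesh,
       dsat = saturating_dose(gp))
}

#' Double-pulse refractory experiment at desk scale
#'
#' @param delays offset-to-onset delays, s.
#' @param seeds one run per seed; peak ratios are averaged.
#' @param scale copy-number scale.
#' @param h mesh spacing (um).
#' @return list: per-delay `curve` (mean second/first ratio) and the
#'   interpolated 50%-recovery delay `recovery50`.
#' @export
refractory_experiment <- function(delays = seq(10, 90, 10),
                                  seeds = c(5, 6, 7), scale = 0.1,
                                  h = 1.2) {
  cfg <- desk_config(scale = scale, h = h)
  mod <- build_signaling_model(cfg$gp, cfg$lg, cfg$st)
  pp <- NULL
  for (s in seeds) {
    init <- equilibrate_state(mod, cfg$mesh, cfg$gp, cfg$lg, cfg$st,
                              seed = s, fresh_receptors = TRUE)
    pp <- rbind(pp, double_pulse_peaks(mod, cfg$mesh, init, cfg$dsat,
                                       delays, seed = 1000 + s))
  }
  refractory_curve(pp)
}

#' LEGI scheme comparison under a staircase of uniform doses
#'
#' Runs the explicit difference, explicit ratio, and AIF response-regulator
#' realizations under the same staircase of uniform doses and reports the
#' nodal-mean steady-state RR and the internodal RR variance at each dose.
#' The explicit (molecular) RR species are used for all three schemes: their
#' means are linear in the transmitted signals, so mean adaptation is not
#' distorted by the zero-clamp of the algebraic readouts at small copy
#' numbers.
#'
#' @param seed trajectory seed.
#' @param scale copy-number scale.
#' @param stage_s seconds per staircase stage.
#' @return list: `doses_pct`, `rr_ss` (per scheme, one value per stage,
#'   nodal-mean counts), `rr_var` (matrix scheme x nonzero dose).
#' @export
legi_scheme_experiment <- function(seed = 7, scale = 0.1, stage_s = 120) {
  gp <- gpcr_params(scale = scale, n_total_sd = 0)
  mesh <- build_shell_mesh(mesh_spec(h_min = 0.4, h_max = 1.2))
  dr <- dose_response_map(gp)
  doses_pct <- c(0, 4, 50, 99)
  doses <- c(0, dr$inverse(c(4, 50, 99)))
  bounds <- cumsum(c(0, rep(stage_s, 4)))
  stair <- make_staircase_protocol(doses[-1], bounds[-1])
  t_end <- bounds[5]
  windows <- lapply(1:4, function(k) c(bounds[k + 1] - 50, bounds[k + 1]))
  mem <- nodes_of(mesh, "membrane")

  one_scheme <- function(scheme, extra = list()) {
    args <- c(list(scheme = scheme, scale = scale, D_I = 0.5,
                   inhibitor_localization = "membrane", volume_ratio = 1),
              extra)
    lg <- suppressWarnings(do.call(legi_params, args))
    mod <- build_signaling_model(gp, lg, NULL)
    init <- equilibrate_state(mod, mesh, gp, lg, NULL, seed = seed)
    tr <- simulate_nsm(mod, mesh, init, t_end = t_end, seed = seed,
                       stimulus = stair,
                       record = list(dt = 1, species = "RR"))
    ss <- numeric(4); vv <- numeric(4)
    for (k in 1:4) {
      sel <- which(tr$times >= windows[[k]][1] &
                     tr$times <= windows[[k]][2])
      X <- tr$node$RR[mem, sel, drop = FALSE]
      ss[k] <- mean(X)
      vv[k] <- mean(apply(X, 2, stats::var))
    }
    list(ss = ss, var = vv)
  }

  sd_ <- one_scheme("explicit_difference")
  sr_ <- one_scheme("explicit_ratio")
  ## the AIF annihilation-pair flux constant is reduced tenfold for the
  ## desk run: the integral-feedback setpoint kX/kY2 is invariant under
  ## joint scaling, while the event churn (proportional to kX [G_bg])
  ## drops to a tractable rate
  sa_ <- one_scheme("AIF", extra = list(kX = 2e1))

  rr_var <- rbind(difference = sd_$var[-1], ratio = sr_$var[-1],
                  AIF = sa_$var[-1])
  colnames(rr_var) <- doses_pct[-1]
  list(doses_pct = doses_pct,
       rr_ss = list(difference = sd_$ss, ratio = sr_$ss, AIF = sa_$ss),
       rr_var = rr_var)
}

#' Full-scale response peaks of the combined model (mean-field)
#'
#' The deterministic oracle run used to pin the excitable-network
#' calibration: rest relaxation followed by a saturating uniform step;
#' reports the whole-cell RasGTP and PKB*s peaks and the resting PIP2
#' areal density.
#'
#' @param volumes compartment volumes or a mesh.
#' @return list `rasgtp`, `pkbs` (molecules), `pip2_per_um2`.
#' @export
sten_peak_calibration <- function(volumes = default_volumes()) {
  if (inherits(volumes, c("shell_mesh", "voxel_graph")))
    volumes <- compartment_volumes(volumes)
  gp <- gpcr_params(n_total_sd = 0)
  lg <- legi_params()
  st <- sten_params()
  mod <- build_signaling_model(gp, lg, st)
  nm <- mod$species_names
  totals <- stats::setNames(numeric(length(nm)), nm)
  totals[gpcr_species_names()] <- gp$n_total * receptor_stationary(gp, 0)
  totals["Gabg"] <- lg$G_total; totals["I"] <- lg$I_total
  totals["RasGDP"] <- st$ras_total
  stim <- make_step_protocol(saturating_dose(gp), t_on = 400)
  mf <- simulate_meanfield(mod, totals, t_end = 450, volumes = volumes,
                           stimulus = stim, dt = 1)
  tt <- mf[, 1]
  Vm <- volumes[["membrane"]]; Va <- volumes[["all"]]
  win <- tt >= 400
  area <- 3 * pi * 5^2   # hemisphere dome + basal disk, R = 5 um
  list(rasgtp = max(mf[win, "RasGTP"]) * MOLEC_PER_UM3_UM * Vm,
       pkbs = max(mf[win, "PKBs_star"]) * MOLEC_PER_UM3_UM * Va,
       pip2_per_um2 = mf[tt == 395, "PIP2"] * MOLEC_PER_UM3_UM * Vm / area)
}

#' Seeded wave-collision experiment
#'
#' Seeds two supra-threshold RasGTP regions at opposite ends of the cell in
#' the excitable network (constant basal RR drive) and tracks the activity:
#' colliding fronts must merge/extinguish at the collision locus rather
#' than crossing.
#'
#' @param seed trajectory seed.
#' @param scale copy-number scale.
#' @return list: `events` (wave events), `collision_time`, `crossed`
#'   (whether activity persisted at the midline beyond the refractory
#'   window).
#' @export
wave_collision_experiment <- function(seed = 9, scale = 0.1) {
  cfg <- desk_config(scale = scale, h = 0.75)
  mesh <- cfg$mesh; st <- cfg$st
  mod <- rd_model(build_sten_model(st, ga2_coupling = FALSE,
                                   rr_const = cfg$lg$alpha0))
  init <- equilibrate_state(mod, mesh, cfg$gp, cfg$lg, st, seed = seed)
  ang <- node_angles(mesh)
  mem <- nodes_of(mesh, "membrane")
  for (sector in list(ang <= 25, ang >= 155)) {
    idx <- intersect(which(sector), mem)
    ## supra-threshold seeding: convert most local RasGDP, deplete PIP2
    flip <- pmin(init["RasGDP", idx],
                 as.integer(round(0.8 * init["RasGDP", idx])))
    init["RasGDP", idx] <- init["RasGDP", idx] - flip
    init["RasGTP", idx] <- init["RasGTP", idx] + flip
    init["PIP2", idx] <- 0L
  }
  tr <- simulate_nsm(mod, mesh, init, t_end = 40, seed = seed,
                     record = list(dt = 0.5,
                                   species = c("RasGTP", "PIP2")))
  ev <- detect_waves(tr, mesh)
  on <- rdmecell_active(tr)
  mid <- which(ang > 70 & ang < 110)
  mid_frac <- colSums(on[mid, , drop = FALSE]) / length(mid)
  touched <- which(mid_frac > 0.15)
  tc <- if (length(touched)) tr$times[touched[1]] else NA_real_
  crossed <- if (is.na(tc)) FALSE else {
    late <- tr$times > tc + 15
    any(mid_frac[late] > 0.15)
  }
  list(events = ev, collision_time = tc, crossed = crossed)
}

rdmecell_active <- function(tr) active_nodes(tr)

#' Gradient-sensing experiment: front/back response regulator
#'
#' Applies a calibrated micropipette gradient (front ~99%, back ~12%
#' receptor occupancy) to the receptor + G-protein + LEGI model with the
#' fast globally-diffusing inhibitor, and evaluates the implicit difference
#' readout on sector-pooled excitor/inhibitor concentrations (aggregating
#' counts over the front, back, and whole-membrane sectors before the
#' algebraic readout keeps the measurement clear of the single-molecule
#' zero-clamp at desk-scale counts).
#'
#' @param seed trajectory seed.
#' @param scale copy-number scale.
#' @param t_on gradient onset (s); the run ends 120 s later.
#' @return list `front_rr`, `back_rr`, `basal_rr` (readout, uM).
#' @export
gradient_rr_experiment <- function(seed = 11, scale = 0.02, t_on = 40) {
  gp <- gpcr_params(scale = scale, n_total_sd = 0)
  lg <- legi_params(scale = scale, D_I = 2)
  mesh <- build_shell_mesh(mesh_spec(h_min = 0.4, h_max = 1.2))
  mod <- build_signaling_model(gp, lg, NULL)
  f <- calibrate_gradient(99, 12, mesh, params = gp)
  stim <- stimulus_protocol(list(list(t_start = t_on, t_end = Inf,
                                      field = f)))
  init <- equilibrate_state(mod, mesh, gp, lg, NULL, seed = seed)
  t_end <- t_on + 120
  tr <- simulate_nsm(mod, mesh, init, t_end = t_end, seed = seed,
                     stimulus = stim,
                     record = list(dt = 1, species = c("Gbg", "Istar")))
  ro <- mod$rr_readout
  ang <- node_angles(mesh)
  mem <- nodes_of(mesh, "membrane")
  vol <- mesh$nodal_volumes
  sector_rr <- function(nodes, t0, t1) {
    sel <- which(tr$times >= t0 & tr$times <= t1)
    g <- mean(colSums(tr$node$Gbg[nodes, sel, drop = FALSE])) /
      (MOLEC_PER_UM3_UM * sum(vol[nodes]))
    i <- mean(colSums(tr$node$Istar[nodes, sel, drop = FALSE])) /
      (MOLEC_PER_UM3_UM * sum(vol[nodes]))
    max(0, ro$par[1] + ro$par[2] * (g - ro$par[3] * i))
  }
  front <- intersect(which(ang <= 30), mem)
  back <- intersect(which(ang >= 150), mem)
  list(front_rr = sector_rr(front, t_end - 50, t_end),
       back_rr = sector_rr(back, t_end - 50, t_end),
       basal_rr = sector_rr(mem, 10, t_on - 2))
}

#' Basal/apical threshold-asymmetry experiment
#'
#' Runs the unstimulated combined model with the PKB*s-mediated RasGTP
#' inhibition weakened on the basal membrane and strengthened apically, and
#' reports the fraction of detected wave initiations on the basal side.
#'
#' @param seed trajectory seed.
#' @param scale copy-number scale.
#' @param factors `c(basal =, apical =)` multipliers on the inhibition.
#' @param t_end simulated time, s.
#' @return list `frac_basal`, `n_initiations`, `events`.
#' @export
basal_asymmetry_experiment <- function(seed = 13, scale = 0.1,
                                       factors = c(basal = 0.4,
                                                   apical = 2.5),
                                       t_end = 100) {
  cfg <- desk_config(scale = scale, h = 0.75)
  st <- apply_threshold_perturbation(
    cfg$st, sten_perturbation("basal_apical_asymmetry", factors))
  mod <- build_signaling_model(cfg$gp, cfg$lg, st)
  init <- equilibrate_state(mod, cfg$mesh, cfg$gp, cfg$lg, st, seed = seed,
                            fresh_receptors = TRUE)
  tr <- simulate_nsm(mod, cfg$mesh, init, t_end = t_end, seed = seed,
                     record = list(dt = 0.5,
                                   species = c("RasGTP", "PIP2")))
  ev <- detect_waves(tr, cfg$mesh)
  ini <- ev[ev$kind == "initiation" & ev$time > 20, ]
  list(frac_basal = if (nrow(ini)) mean(ini$side == "basal") else NA_real_,
       n_initiations = nrow(ini), events = ev)
}
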