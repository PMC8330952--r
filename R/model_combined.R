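## Assembly of the full signaling model (receptors -> G protein -> LEGI ->
## excitable network) and deterministic equilibration of initial states.

#' Build the combined signaling model
#'
#' @param gpcr [gpcr_params()].
#' @param legi [legi_params()] (`NULL` to omit G-protein/LEGI).
#' @param sten [sten_params()] (`NULL` to omit the excitable network).
#' @param gpcr_variant `"full"` (10 species / 26 reactions) or `"reduced"`.
#' @param modules which fragments to include; defaults to all supplied.
#' @return an `rd_model`.
#' @export
build_signaling_model <- function(gpcr = gpcr_params(),
                                  legi = legi_params(),
                                  sten = NULL,
                                  gpcr_variant = c("full", "reduced"),
                                  modules = NULL) {
  gpcr_variant <- match.arg(gpcr_variant)
  if (is.null(modules))
    modules <- c("gpcr",
                 if (!is.null(legi)) c("gprotein", "legi"),
                 if (!is.null(sten)) "sten")
  frags <- list()
  if ("gpcr" %in% modules)
    frags <- c(frags, list(build_gpcr_model(gpcr, gpcr_variant)))
  if ("gprotein" %in% modules)
    frags <- c(frags, list(build_gprotein_model(legi, gpcr_variant)))
  if ("legi" %in% modules)
    frags <- c(frags, list(build_legi_model(legi, gpcr_variant)))
  if ("sten" %in% modules)
    frags <- c(frags, list(build_sten_model(sten)))
  rd_model(frags)
}

#' Deterministic equilibration of the initial state
#'
#' Draws the total receptor number from the cell-to-cell Gaussian, sets all
#' other pools to their module totals (all G-protein heterotrimeric, all
#' inhibitor inactive, all Ras in the GDP form, no PIP2 or PKB*s), relaxes
#' the mean-field model to its unstimulated resting point, and scatters the
#' resulting totals multinomially over each species' localization nodes
#' proportionally to nodal volume.
#'
#' @param model an `rd_model` from [build_signaling_model()].
#' @param mesh a `shell_mesh` or `voxel_graph`.
#' @param gpcr,legi,sten the parameter objects the model was built with.
#' @param seed integer seed (receptor total draw and multinomial scatter).
#' @param t_relax mean-field relaxation time, seconds.
#' @param gpcr_variant receptor variant.
#' @param fresh_receptors start receptors in the unphosphorylated
#'   zero-ligand equilibrium instead of the full stationary split.
#' @return integer counts matrix (species x voxel).
#' @export
equilibrate_state <- function(model, mesh, gpcr = gpcr_params(),
                              legi = NULL, sten = NULL, seed = 1L,
                              t_relax = 400,
                              gpcr_variant = c("full", "reduced"),
                              fresh_receptors = FALSE) {
  gpcr_variant <- match.arg(gpcr_variant)
  nm <- model$species_names
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_rec <- if (gpcr$n_total_sd > 0) {
    x <- -1
    while (x <= 0) x <- stats::rnorm(1, gpcr$n_total, gpcr$n_total_sd)
    round(x)
  } else round(gpcr$n_total)

  totals <- stats::setNames(numeric(length(nm)), nm)
  rec <- gpcr_species_names(gpcr_variant)
  pi <- receptor_proportions(gpcr, gpcr_variant, fresh_receptors)
  present <- rec %in% nm
  totals[rec[present]] <- (n_rec * pi)[present]
  if ("Gabg" %in% nm) {
    vols0 <- compartment_volumes(mesh)
    gb_count <- round(basal_gbg_conc(legi, vols0) *
                        MOLEC_PER_UM3_UM * vols0[["membrane"]])
    gb_count <- min(gb_count, legi$G_total %/% 2)
    totals[["Gabg"]] <- legi$G_total - 2 * gb_count
    totals[["Gbg"]] <- gb_count
    totals[["Ga2"]] <- gb_count
  }
  if ("I" %in% nm) {
    vols0 <- compartment_volumes(mesh)
    V_I <- if (legi$inhibitor_localization == "membrane")
      vols0[["membrane"]] else vols0[["all"]]
    ib_count <- round(legi$lambda * basal_gbg_conc(legi, vols0) *
                        MOLEC_PER_UM3_UM * V_I)
    ib_count <- min(ib_count, legi$I_total)
    totals[["I"]] <- legi$I_total - ib_count
    totals[["Istar"]] <- ib_count
  }
  if ("RasGDP" %in% nm) totals[["RasGDP"]] <- sten$ras_total

  mf <- simulate_meanfield(model, totals, t_end = t_relax, volumes = mesh,
                           dt = t_relax / 200)
  yf <- mf[nrow(mf), nm]
  loc <- vapply(model$species, `[[`, "", "localization")
  vols <- compartment_volumes(mesh)
  Vsp <- unname(vols[ifelse(loc == "membrane", "membrane", "all")])
  tot_f <- pmax(0, round(yf * MOLEC_PER_UM3_UM * Vsp))
  names(tot_f) <- nm
  if (fresh_receptors) {
    ## keep the receptor pool unphosphorylated: the relaxation (which the
    ## other modules need) would otherwise walk it toward the slow
    ## phosphorylation equilibrium
    tot_f[rec[present]] <- round((n_rec * pi)[present])
  }

  counts <- matrix(0L, length(nm), length(mesh$nodal_volumes),
                   dimnames = list(nm, NULL))
  for (i in seq_along(nm)) {
    if (tot_f[i] == 0) next
    idx <- nodes_of(mesh, loc[i])
    w <- mesh$nodal_volumes[idx]
    counts[i, idx] <- as.integer(stats::rmultinom(1, tot_f[i], w / sum(w)))
  }
  counts
}

## Receptor state proportions at zero ligand: either the full stationary
## split (phosphorylation included) or the unphosphorylated H/L equilibrium.
receptor_proportions <- function(gpcr, variant, fresh = FALSE) {
  if (variant == "reduced")
    return(stats::setNames(c(1, 0), gpcr_species_names("reduced")))
  if (!fresh) return(receptor_stationary(gpcr, 0))
  pi <- stats::setNames(numeric(10), gpcr_species_names("full"))
  pi["H"] <- gpcr$kmHL / (gpcr$kHL + gpcr$kmHL)
  pi["L"] <- gpcr$kHL / (gpcr$kHL + gpcr$kmHL)
  pi
}

#' Whole-cell occupied-receptor count trace
#' @param traj an `rd_trajectory`.
#' @param variant receptor variant.
#' @export
occupied_receptor_trace <- function(traj, variant = "full") {
  wc_trace(traj, gpcr_occupied_names(variant))
}

#' Double-pulse refractory experiment
#'
#' Applies a first short saturating pulse, then re-simulates the second
#' pulse from the stored state at each delay (offset-to-onset), so all
#' delays of one seed share the first-response history. Returns the
#' basal-subtracted whole-cell RasGTP peaks of both responses per delay.
#'
#' @param model,mesh combined model (with STEN) and mesh.
#' @param init equilibrated initial counts.
#' @param dose pulse concentration (uM), normally the saturating dose.
#' @param delays offset-to-onset delays, seconds.
#' @param seed trajectory seed.
#' @param duration pulse duration (s, default 2).
#' @param t_first onset of the first pulse (burn-in before it).
#' @param t_tail recording time after the second pulse (s).
#' @return data.frame: `delay`, `first`, `second`, `basal_sd`.
#' @export
double_pulse_peaks <- function(model, mesh, init, dose, delays, seed = 1L,
                               duration = 2, t_first = 30, t_tail = 40) {
  delays <- sort(delays)
  rec <- list(dt = 0.5, species = character(0))
  p1_end <- t_first + duration
  ## base run through the first pulse and out to the longest delay
  base_end <- p1_end + max(delays)
  stim1 <- make_pulse_protocol(duration, dose, 1, t_start = t_first)
  base <- simulate_nsm(model, mesh, init, t_end = base_end, seed = seed,
                       stimulus = stim1, record = rec)
  y <- wc_trace(base, "RasGTP")
  tb <- base$times < t_first
  basal <- mean(y[tb]); basal_sd <- stats::sd(y[tb])
  w1 <- base$times >= t_first & base$times <= p1_end + 25
  first_pk <- max(y[w1]) - basal
  ## walk the base state forward delay by delay, forking the second pulse
  seg <- simulate_nsm(model, mesh, init, t_end = p1_end + delays[1],
                      seed = seed, stimulus = stim1, record = rec)
  out <- vector("list", length(delays))
  for (q in seq_along(delays)) {
    d <- delays[q]
    t2 <- p1_end + d
    pulse2 <- stimulus_protocol(list(list(t_start = t2, t_end = t2 + duration,
                                          field = uniform_field(dose))))
    fork <- simulate_nsm(model, mesh, seg$final, t_end = t2 + duration + t_tail,
                         seed = seed + 7919L * q, stimulus = pulse2,
                         record = list(dt = 0.5, species = character(0)),
                         t0 = t2)
    y2 <- wc_trace(fork, "RasGTP")
    w2 <- fork$times >= t2
    ## a distinct second response must rise above its own onset level;
    ## the decaying tail of the first response does not count
    onset <- y2[which(fork$times >= t2)[1]]
    second_pk <- max(0, max(y2[w2]) - max(onset, basal))
    out[[q]] <- data.frame(delay = d, first = first_pk,
                           second = second_pk, basal_sd = basal_sd)
    if (q < length(delays)) {
      seg <- simulate_nsm(model, mesh, seg$final,
                          t_end = p1_end + delays[q + 1], seed = seed + q,
                          stimulus = NULL, record = rec, t0 = t2)
    }
  }
  do.call(rbind, out)
}
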