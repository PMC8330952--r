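## Model containers: species, reactions, and their assembly into an rd_model.
## Counts are molecules per voxel; macroscopic rate constants carry uM-based
## units and are converted per voxel via the one-molecule concentration
## u(V) = 1 / (N_A * V), expressed in uM for V in um^3.

#' Molecules per micromolar-micrometre-cubed
#'
#' `1 uM x 1 um^3` corresponds to this many molecules; its reciprocal per
#' voxel volume is the concentration increment of a single molecule.
#' @export
MOLEC_PER_UM3_UM <- 602.214076

#' One-molecule concentration of a voxel
#' @param volume voxel volume(s), micrometres cubed.
#' @return concentration (uM) that a single molecule represents in the voxel.
#' @export
one_molecule_uM <- function(volume) 1 / (MOLEC_PER_UM3_UM * volume)

#' Define a species
#'
#' @param name species name.
#' @param D diffusion constant, um^2/s (`>= 0`).
#' @param localization node classes where the species may reside:
#'   `"all"` (membrane + cortex) or `"membrane"`.
#' @export
species <- function(name, D = 0, localization = c("all", "membrane")) {
  localization <- match.arg(localization)
  if (D < 0) stop("diffusion_constant must be >= 0")
  structure(list(name = name, D = D, localization = localization),
            class = "rd_species")
}

#' Define a reaction
#'
#' The propensity specification is either mass-action (`zeroth`, `first`,
#' `second`, `second_self`) with a macroscopic rate constant, or one of two
#' special forms: `pool_second` (activation drawing on an unmodelled
#' per-voxel pool, propensity `k * (n_T - n1) * n2` with bimolecular volume
#' conversion) and `sten_r3` (the rational Ras activation propensity
#' `(a30 + a3 [RR]) / (a4^2 [PIP2]([PIP2]-1) u(V)^2 + 1) * n_RasGDP`).
#' Second-order self-interactions use the combinatorial count `n (n - 1)`
#' with no symmetry factor.
#'
#' @param name reaction label.
#' @param type propensity type.
#' @param k rate constant in macroscopic units: `uM/s` (zeroth), `s^-1`
#'   (first), `1/(uM s)` (second, second_self, pool_second). Ignored for
#'   `sten_r3`, which takes `a30` (s^-1), `a3` (1/(uM s)) and `a4` (1/uM).
#' @param reactants character vector of reactant species entering the
#'   propensity (1 for first/second_self, 2 for second; for `pool_second`
#'   the pool-limited species then the catalyst; for `sten_r3` RasGDP then
#'   PIP2).
#' @param stoich named integer vector of species count changes when the
#'   reaction fires.
#' @param locale node classes where the reaction may fire.
#' @param camp if `TRUE` the propensity is additionally multiplied by the
#'   extracellular cAMP concentration (uM) at the voxel; cAMP is treated as
#'   a buffered external field and never depleted.
#' @param pool_total for `pool_second`: total pool size (molecules),
#'   distributed over the locale's voxels proportionally to volume.
#' @param a30,a3,a4 parameters of the `sten_r3` rational propensity.
#' @param side_scale optional `c(basal =, apical =)` multiplicative factors
#'   applied to the rate on basal vs apical nodes (threshold asymmetry).
#' @export
reaction <- function(name, type = c("first", "second", "zeroth",
                                    "second_self", "pool_second", "sten_r3",
                                    "cat_gated"),
                     k = NULL, reactants = character(), stoich,
                     locale = c("membrane", "all"), camp = FALSE,
                     pool_total = NULL, a30 = NULL, a3 = NULL, a4 = NULL,
                     side_scale = NULL) {
  type <- match.arg(type)
  locale <- match.arg(locale)
  need <- c(zeroth = 0L, first = 1L, second = 2L, second_self = 1L,
            pool_second = 2L, sten_r3 = 2L, cat_gated = 2L)[[type]]
  if (length(reactants) != need)
    stop(sprintf("reaction '%s': type '%s' needs %d reactant(s)",
                 name, type, need))
  if (type == "sten_r3") {
    if (is.null(a30) || is.null(a3) || is.null(a4))
      stop("sten_r3 needs a30, a3, a4")
  } else if (is.null(k) || k < 0) {
    stop(sprintf("reaction '%s': rate constant k must be >= 0", name))
  }
  stoich <- stoich[stoich != 0]
  structure(list(name = name, type = type, k = k, reactants = reactants,
                 stoich = stoich, locale = locale, camp = isTRUE(camp),
                 pool_total = pool_total, a30 = a30, a3 = a3, a4 = a4,
                 side_scale = side_scale),
            class = "rd_reaction")
}

#' Assemble a reaction-diffusion model
#'
#' Collects species and reactions (possibly from several module builders)
#' into a single model. Fragments produced by [build_gpcr_model()],
#' [build_gprotein_model()], [build_legi_model()] and [build_sten_model()]
#' can be concatenated here; duplicate species definitions must agree.
#'
#' @param ... `rd_species`, `rd_reaction`, or `rd_model` fragments.
#' @param rr_readout optional implicit response-regulator readout created by
#'   [rr_readout_spec()]; required when an `sten_r3` reaction names no
#'   explicit RR species.
#' @param partial if `TRUE` the fragment may reference species defined in
#'   other fragments; the final (non-partial) assembly validates them.
#' @return an object of class `rd_model`.
#' @export
rd_model <- function(..., rr_readout = NULL, partial = FALSE) {
  parts <- list(...)
  sp <- list(); rx <- list()
  add <- function(x) {
    if (inherits(x, "rd_species")) sp[[length(sp) + 1L]] <<- x
    else if (inherits(x, "rd_reaction")) rx[[length(rx) + 1L]] <<- x
    else if (inherits(x, "rd_model")) {
      for (s in x$species) sp[[length(sp) + 1L]] <<- s
      for (r in x$reactions) rx[[length(rx) + 1L]] <<- r
      if (!is.null(x$rr_readout)) rr_readout <<- x$rr_readout
    } else if (is.list(x)) lapply(x, add)
    else stop("rd_model: unsupported component")
  }
  lapply(parts, add)
  nm <- vapply(sp, `[[`, "", "name")
  keep <- !duplicated(nm)
  for (i in which(duplicated(nm))) {
    j <- match(nm[i], nm)
    if (!identical(sp[[i]], sp[[j]]))
      stop(sprintf("conflicting definitions of species '%s'", nm[i]))
  }
  sp <- sp[keep]; nm <- nm[keep]
  if (!partial) {
    for (r in rx) {
      unknown <- setdiff(c(r$reactants, names(r$stoich)), nm)
      if (length(unknown))
        stop(sprintf("reaction '%s' is missing coupling species: %s",
                     r$name, paste(unknown, collapse = ", ")))
    }
  }
  structure(list(species = sp, reactions = rx,
                 species_names = nm, rr_readout = rr_readout),
            class = "rd_model")
}

#' Implicit response-regulator readout
#'
#' The implicit LEGI schemes do not simulate RR as a species; instead a
#' per-voxel algebraic readout of the local excitor and inhibitor
#' concentrations is evaluated wherever RR enters a propensity:
#' difference: `RR = max(0, alpha0 + alpha1 * (g - beta * i))`;
#' ratio: `RR = rho * (a + g) / (b + i)`, with `g`, `i` the local
#' concentrations (uM) of the excitor and active inhibitor.
#'
#' @param mode `"difference"` or `"ratio"`.
#' @param g,i species names of the excitor (G_bg) and active inhibitor (I*).
#' @param par parameters: `c(alpha0, alpha1, beta)` or `c(rho, a, b)`.
#' @export
rr_readout_spec <- function(mode = c("difference", "ratio"), g, i, par) {
  mode <- match.arg(mode)
  stopifnot(length(par) == 3)
  structure(list(mode = mode, g = g, i = i, par = as.numeric(par)),
            class = "rr_readout")
}

#' Evaluate the implicit RR readout
#'
#' @param g_count,i_count local excitor / inhibitor molecule counts.
#' @param readout an [rr_readout_spec()].
#' @param volume voxel volume (um^3).
#' @return RR concentration (uM), clamped at zero for the difference form.
#' @export
rr_implicit_readout <- function(g_count, i_count, readout, volume) {
  u <- one_molecule_uM(volume)
  g <- g_count * u; i <- i_count * u
  if (readout$mode == "difference")
    pmax(0, readout$par[1] + readout$par[2] * (g - readout$par[3] * i))
  else
    readout$par[1] * (readout$par[2] + g) / (readout$par[3] + i)
}

#' @export
print.rd_model <- function(x, ...) {
  cat(sprintf("Reaction-diffusion model: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (s in x$species)
    cat(sprintf("  %-10s D = %-8g %s\n", s$name, s$D, s$localization))
  if (!is.null(x$rr_readout))
    cat(sprintf("  implicit RR readout: %s scheme\n", x$rr_readout$mode))
  invisible(x)
}

#' Per-voxel mesoscopic rate parameters
#'
#' Converts a macroscopic propensity specification to the per-voxel rate
#' parameter used by the stochastic engine: first-order rates are unchanged;
#' bimolecular rates `k` in `1/(uM s)` become `k * u(V)` per reactant pair;
#' zeroth-order rates `r` in `uM/s` become `r / u(V)` molecules per second.
#'
#' @param propensity_spec an `rd_reaction` (or a list with `type` and `k`).
#' @param voxel_volume voxel volume(s), um^3.
#' @return numeric vector of per-voxel rate parameters.
#' @export
mesoscopic_rate <- function(propensity_spec, voxel_volume) {
  if (any(voxel_volume <= 0)) stop("voxel_volume must be > 0")
  u <- one_molecule_uM(voxel_volume)
  k <- propensity_spec$k
  switch(propensity_spec$type,
         zeroth = k / u,
         first = rep_len(k, length(u)),
         second = k * u,
         second_self = k * u,
         pool_second = k * u,
         cat_gated = rep_len(k, length(u)),
         sten_r3 = rep_len(1, length(u)),
         stop("unsupported propensity units/type: ", propensity_spec$type))
}

## ---- engine input assembly --------------------------------------------------

## Build the list consumed by the compiled NSM core.
nsm_prepare <- function(model, mesh, stimulus = NULL, t_end = Inf) {
  vol <- mesh$nodal_volumes
  N <- length(vol)
  uV <- one_molecule_uM(vol)
  nm <- model$species_names
  S <- length(nm)

  locale_nodes <- list(all = seq_len(N),
                       membrane = nodes_of(mesh, "membrane"))
  graph_of <- c(all = 0L, membrane = 1L)
  graphs <- lapply(names(graph_of), function(lc) {
    g <- jump_graph(mesh, if (lc == "all") NULL else locale_nodes[[lc]])
    list(ptr = g$ptr, idx = g$idx - 1L, w = g$w, wsum = g$wsum)
  })

  sp_graph <- vapply(model$species, function(s)
    graph_of[[s$localization]], 0L)
  sp_D <- vapply(model$species, `[[`, 0, "D")

  rr <- NULL
  if (!is.null(model$rr_readout)) {
    ro <- model$rr_readout
    rr <- list(mode = if (ro$mode == "difference") 1L else 2L,
               sp = -1L, g = match(ro$g, nm) - 1L,
               i = match(ro$i, nm) - 1L, par = ro$par)
  }

  reactions <- lapply(model$reactions, function(r) {
    mask <- numeric(N)
    mask[locale_nodes[[r$locale]]] <- 1
    if (!is.null(r$side_scale)) {
      side <- mesh$node_class$side
      mask <- mask * ifelse(side == "basal", r$side_scale[["basal"]],
                            r$side_scale[["apical"]])
    }
    rate <- if (r$type == "sten_r3") mask else mesoscopic_rate(r, vol) * mask
    pool <- NULL
    if (r$type == "pool_second") {
      pool <- numeric(N)
      idx <- locale_nodes[[r$locale]]
      pool[idx] <- r$pool_total * vol[idx] / sum(vol[idx])
    }
    out <- list(type = c(zeroth = 0L, first = 1L, second = 2L,
                         second_self = 3L, pool_second = 4L,
                         sten_r3 = 5L, cat_gated = 6L)[[r$type]],
                s1 = if (length(r$reactants) >= 1)
                       match(r$reactants[1], nm) - 1L else -1L,
                s2 = if (length(r$reactants) >= 2)
                       match(r$reactants[2], nm) - 1L else -1L,
                camp = as.integer(r$camp), rate = rate, pool = pool,
                st_sp = match(names(r$stoich), nm) - 1L,
                st_dl = as.integer(r$stoich))
    if (r$type == "sten_r3") {
      out$a30 <- r$a30; out$a3 <- r$a3; out$a4 <- r$a4
      out$pip2 <- match(r$reactants[2], nm) - 1L
      if (is.null(rr)) {
        rr_sp <- match("RR", nm)
        if (is.na(rr_sp)) stop("sten_r3 reaction needs an RR species or an implicit rr_readout")
        rr <<- list(mode = 0L, sp = rr_sp - 1L, g = -1L, i = -1L, par = 0)
      }
    }
    out
  })

  stim <- NULL
  if (!is.null(stimulus)) {
    coords <- mesh$vertices
    if (is.null(coords)) coords <- matrix(0, N, 3)  # abstract voxel graphs
    seg <- protocol_segments(stimulus, coords, t_end)
    stim <- list(start = seg$start, conc = seg$conc)
  }

  list(uV = uV, graphs = graphs, sp_graph = sp_graph, sp_D = sp_D,
       reactions = reactions, rr = rr, stim = stim,
       species_names = nm, volumes = vol)
}

#' Simulate the model with the Next Sub-volume Method
#'
#' Draws an exact-in-distribution sample of the reaction-diffusion master
#' equation on the mesh. One next-event time per voxel is kept in an indexed
#' binary min-heap; the channel within the firing voxel is chosen by
#' Gillespie's direct method over the voxel's reaction propensities and
#' per-species outbound diffusion rates. Identical `(model, init, seed)`
#' give bit-identical trajectories.
#'
#' @param model an [rd_model()].
#' @param mesh a `shell_mesh` or `voxel_graph`.
#' @param init initial counts: species x voxel integer matrix (rows in
#'   `model$species_names` order), or a named vector of total molecule
#'   counts scattered over each species' localization proportionally to
#'   voxel volume (deterministic largest-remainder rounding).
#' @param t_end end time, seconds (simulation starts at `t0`).
#' @param seed integer seed of the simulation's random stream.
#' @param stimulus optional [stimulus_protocol()] evaluated per node;
#'   protocols are piecewise-constant in time, which keeps the sampler
#'   exact across changepoints.
#' @param record snapshot specification: `list(dt = 0.5, species = ...)`
#'   or an explicit vector of times via `list(times = ...)`; `species`
#'   names which species get per-node recording (all species always get
#'   whole-cell totals).
#' @param t0 start time (default 0).
#' @return an `rd_trajectory`: `times`, whole-cell count matrix `wc`
#'   (species x time), per-node arrays `node[[species]]` (voxel x time),
#'   final state, and event counters.
#' @export
simulate_nsm <- function(model, mesh, init, t_end, seed = 1L,
                         stimulus = NULL, record = list(dt = 0.5),
                         t0 = 0) {
  prep <- nsm_prepare(model, mesh, stimulus, t_end)
  init <- init_counts(model, mesh, init)
  storage.mode(init) <- "integer"
  times <- record$times
  if (is.null(times)) {
    dt <- if (is.null(record$dt)) 0.5 else record$dt
    times <- seq(t0, t_end, by = dt)
  }
  rec_sp <- match(record$species, prep$species_names) - 1L
  if (anyNA(rec_sp)) stop("record$species contains unknown species")
  out <- .nsm_run(prep, init, t0, t_end, as.numeric(seed),
                  as.numeric(times), as.integer(rec_sp))
  node <- NULL
  if (length(rec_sp)) {
    K <- length(rec_sp); N <- ncol(init); T <- length(times)
    arr <- array(out$node_rec, dim = c(N, K, T))
    node <- lapply(seq_len(K), function(k) arr[, k, , drop = TRUE])
    names(node) <- record$species
  }
  rownames(out$wc) <- prep$species_names
  rownames(out$final) <- prep$species_names
  structure(list(times = times, wc = out$wc, node = node,
                 final = out$final, n_events = out$n_events,
                 rxn_count = stats::setNames(out$rxn_count,
                   vapply(model$reactions, `[[`, "", "name")),
                 dif_count = stats::setNames(out$dif_count,
                                             prep$species_names),
                 species = prep$species_names,
                 volumes = prep$volumes, seed = seed),
            class = "rd_trajectory")
}

## Scatter named total counts over localization nodes proportional to volume
## (largest-remainder rounding, deterministic), or validate a full matrix.
init_counts <- function(model, mesh, init) {
  nm <- model$species_names
  N <- length(mesh$nodal_volumes)
  if (is.matrix(init)) {
    if (nrow(init) != length(nm) || ncol(init) != N)
      stop("init matrix must be species x voxel")
    rownames(init) <- nm
    for (i in seq_along(model$species)) {
      sp <- model$species[[i]]
      if (sp$localization != "all") {
        off <- setdiff(seq_len(N), nodes_of(mesh, sp$localization))
        if (any(init[i, off] != 0))
          stop(sprintf("species '%s' initialized outside its localization",
                       sp$name))
      }
    }
    return(init)
  }
  m <- matrix(0L, length(nm), N, dimnames = list(nm, NULL))
  for (s in names(init)) {
    i <- match(s, nm)
    if (is.na(i)) stop("unknown species in init: ", s)
    idx <- nodes_of(mesh, model$species[[i]]$localization)
    m[i, idx] <- largest_remainder(init[[s]],
                                   mesh$nodal_volumes[idx])
  }
  m
}

## Apportion `total` integer units over weights, exactly.
largest_remainder <- function(total, w) {
  q <- total * w / sum(w)
  f <- floor(q)
  r <- total - sum(f)
  if (r > 0) {
    o <- order(q - f, decreasing = TRUE)[seq_len(r)]
    f[o] <- f[o] + 1
  }
  as.integer(f)
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf(paste0(
    "NSM trajectory: %d species, %d voxels, t in [%g, %g] s\n",
    "  %s snapshots, %.3g events (seed %s)\n"),
    nrow(x$wc), length(x$volumes), min(x$times), max(x$times),
    length(x$times), x$n_events, format(x$seed)))
  cat("  final whole-cell counts:\n")
  print(x$wc[, ncol(x$wc)])
  invisible(x)
}

#' Whole-cell trace of a species or pooled species set
#' @param traj an `rd_trajectory`.
#' @param species species name(s); pooled by summation.
#' @export
wc_trace <- function(traj, species) {
  i <- match(species, rownames(traj$wc))
  if (anyNA(i)) stop("unknown species")
  colSums(traj$wc[i, , drop = FALSE])
}
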