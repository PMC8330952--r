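## G-protein-coupled receptor (cAR1) module. Unoccupied receptors exist in
## high (H), low (L) and slow (S) cAMP-binding-affinity states; occupied
## counterparts are H:C, L:C, S:C. Phosphorylation (desensitization) adds
## PH, PL and their occupied forms. cAMP is an external buffered field;
## inorganic phosphate is buffered at a fixed concentration folded into
## pseudo-first-order phosphorylation rates.

#' GPCR module parameters
#'
#' Nominal rate constants and their cell-to-cell standard deviations for the
#' 10-species / 26-reaction receptor network, plus the 2-state reduced
#' variant. Binding constants are `1/(uM s)`, conformational and unbinding
#' rates `1/s`; `kHCP`, `kPH`, `kLCP`, `kPL` are phosphorylation rates per
#' uM of buffered phosphate.
#'
#' @param ... overrides of the defaults, e.g. `kH = 7.5`, `n_total = 70000`.
#' @param phosphate_uM buffered inorganic phosphate concentration. The
#'   default is a calibration constant fixed once so that the pooled
#'   phosphorylated-state half-time after a saturating step is ~198 s.
#' @param scale copy-number scale factor for desk-scale runs: the receptor
#'   total is multiplied by `scale`. Because ligand binding is driven by the
#'   external (unscaled) cAMP field and all other receptor reactions are
#'   first order, per-receptor kinetics are scale-invariant.
#' @return object of class `gpcr_params`.
#' @export
gpcr_params <- function(..., phosphate_uM = GPCR_PHOSPHATE_UM, scale = 1) {
  p <- list(
    kH = 7.5, kmH = 0.45, kL = 2.2, kmL = 1, kS = 4.0, kmS = 0.05,
    kHL = 8.0e-2, kmHL = 5.36e-2, kHLC = 8.0e-2, kmHLC = 7.1e-3,
    kHCP = 5.3e-4, kmHCP = 8.0e-4, kPHC = 4e-2, kmPHC = 2.42e-3,
    kPH = 5.3e-4, kmPH = 8.0e-4, kLCP = 5.3e-4, kmLCP = 8.0e-4,
    kPLC = 5, kmPLC = 1.5, kPL = 5.3e-4, kmPL = 8.0e-4,
    kPHL = 4.3e-4, kmPHL = 2.9e-4, kPHLC = 4.3e-4, kmPHLC = 3.8e-5,
    kRC = 8.85e-1, kmRC = 5.24e-1,
    D_receptor = 2.7e-2, n_total = 70000, n_total_sd = 5000,
    phosphate_uM = phosphate_uM)
  p$sd <- list(
    kH = 3.0, kmH = 0.18, kL = 0.88, kmL = 0.4, kS = 1.6, kmS = 0.02,
    kHL = 3.2e-2, kmHL = 2.14e-2, kHLC = 3.2e-2, kmHLC = 2.8e-3,
    kHCP = 2.1e-4, kmHCP = 2.3e-4, kPHC = 1.6e-2, kmPHC = 1.0e-3,
    kPH = 2.1e-4, kmPH = 3.2e-4, kLCP = 2.1e-4, kmLCP = 3.2e-4,
    kPLC = 1.5, kmPLC = 0.3, kPL = 2.1e-4, kmPL = 3.2e-4,
    kPHL = 1.7e-4, kmPHL = 1.2e-4, kPHLC = 1.7e-4, kmPHLC = 1.5e-5,
    D_receptor = 0.2 * 2.7e-2)
  ov <- list(...)
  for (n in names(ov)) {
    if (!n %in% names(p)) stop("unknown GPCR parameter: ", n)
    p[[n]] <- ov[[n]]
  }
  if (any(unlist(p[GPCR_RATE_NAMES]) < 0)) stop("rates must be >= 0")
  if (p$n_total <= 0) stop("n_total_receptors must be > 0")
  p$scale <- scale
  p$n_total <- p$n_total * scale
  p$n_total_sd <- p$n_total_sd * scale
  structure(p, class = "gpcr_params")
}

GPCR_RATE_NAMES <- c("kH", "kmH", "kL", "kmL", "kS", "kmS", "kHL", "kmHL",
                     "kHLC", "kmHLC", "kHCP", "kmHCP", "kPHC", "kmPHC",
                     "kPH", "kmPH", "kLCP", "kmLCP", "kPLC", "kmPLC",
                     "kPL", "kmPL", "kPHL", "kmPHL", "kPHLC", "kmPHLC")

#' Buffered phosphate concentration (uM), calibrated once so the pooled
#' phosphorylated receptor states reach half their saturating-step plateau
#' in about 198 s, then frozen.
#' @export
GPCR_PHOSPHATE_UM <- 5.073

#' Receptor species names
#' @param variant `"full"` or `"reduced"`.
#' @export
gpcr_species_names <- function(variant = "full") {
  if (variant == "reduced") c("R", "RC")
  else c("H", "L", "S", "HC", "LC", "SC", "PH", "PHC", "PL", "PLC")
}

#' Occupied-receptor states
#' @param variant `"full"` or `"reduced"`.
#' @export
gpcr_occupied_names <- function(variant = "full") {
  if (variant == "reduced") "RC" else c("HC", "LC", "SC", "PHC", "PLC")
}

#' Build the receptor model fragment
#'
#' Full variant: 26 reactions over 10 receptor species; reduced variant: a
#' single unoccupied (R) / occupied (R:C) pair whose rates were fit to the
#' full model's response. All receptor species are membrane-localized with
#' a common diffusion constant. cAMP enters binding propensities as an
#' external non-depleted field.
#'
#' @param params [gpcr_params()].
#' @param variant `"full"` or `"reduced"`.
#' @return an `rd_model` fragment.
#' @export
build_gpcr_model <- function(params = gpcr_params(),
                             variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  p <- params
  P <- p$phosphate_uM
  sp <- lapply(gpcr_species_names(variant), species,
               D = p$D_receptor, localization = "membrane")
  if (variant == "reduced") {
    rx <- list(
      reaction("R_bind", "first", k = p$kRC, reactants = "R",
               stoich = c(R = -1, RC = +1), camp = TRUE),
      reaction("R_unbind", "first", k = p$kmRC, reactants = "RC",
               stoich = c(RC = -1, R = +1)))
    return(rd_model(sp, rx))
  }
  r1 <- function(nm, k, from, to, camp = FALSE) {
    st <- c(-1, 1); names(st) <- c(from, to)
    reaction(nm, "first", k = k, reactants = from, stoich = st, camp = camp)
  }
  rx <- list(
    r1("H_bind", p$kH, "H", "HC", camp = TRUE),        # 1
    r1("H_unbind", p$kmH, "HC", "H"),                  # 2
    r1("L_bind", p$kL, "L", "LC", camp = TRUE),        # 3
    r1("L_unbind", p$kmL, "LC", "L"),                  # 4
    r1("S_bind", p$kS, "S", "SC", camp = TRUE),        # 5
    r1("S_unbind", p$kmS, "SC", "S"),                  # 6
    r1("H_to_L", p$kHL, "H", "L"),                     # 7
    r1("L_to_H", p$kmHL, "L", "H"),                    # 8
    r1("HC_to_LC", p$kHLC, "HC", "LC"),                # 9
    r1("LC_to_HC", p$kmHLC, "LC", "HC"),               # 10
    r1("HC_phos", p$kHCP * P, "HC", "PHC"),            # 11
    r1("PHC_dephos", p$kmHCP, "PHC", "HC"),            # 12
    r1("PH_bind", p$kPHC, "PH", "PHC", camp = TRUE),   # 13
    r1("PHC_unbind", p$kmPHC, "PHC", "PH"),            # 14
    r1("H_phos", p$kPH * P, "H", "PH"),                # 15
    r1("PH_dephos", p$kmPH, "PH", "H"),                # 16
    r1("LC_phos", p$kLCP * P, "LC", "PLC"),            # 17
    r1("PLC_dephos", p$kmLCP, "PLC", "LC"),            # 18
    r1("PL_bind", p$kPLC, "PL", "PLC", camp = TRUE),   # 19
    r1("PLC_unbind", p$kmPLC, "PLC", "PL"),            # 20
    r1("L_phos", p$kPL * P, "L", "PL"),                # 21
    r1("PL_dephos", p$kmPL, "PL", "L"),                # 22
    r1("PH_to_PL", p$kPHL, "PH", "PL"),                # 23
    r1("PL_to_PH", p$kmPHL, "PL", "PH"),               # 24
    r1("PHC_to_PLC", p$kPHLC, "PHC", "PLC"),           # 25
    r1("PLC_to_PHC", p$kmPHLC, "PLC", "PHC"))          # 26
  rd_model(sp, rx)
}

## Per-receptor continuous-time Markov generator at cAMP concentration C.
## Rows/cols in gpcr_species_names() order; all channels are (pseudo-)
## first-order, so receptor statistics follow this single-molecule chain.
receptor_generator <- function(params, camp_uM, variant = "full") {
  p <- params
  P <- p$phosphate_uM
  C <- camp_uM
  nm <- gpcr_species_names(variant)
  Q <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  add <- function(from, to, rate) Q[from, to] <<- Q[from, to] + rate
  if (variant == "reduced") {
    add("R", "RC", p$kRC * C); add("RC", "R", p$kmRC)
  } else {
    add("H", "HC", p$kH * C); add("HC", "H", p$kmH)
    add("L", "LC", p$kL * C); add("LC", "L", p$kmL)
    add("S", "SC", p$kS * C); add("SC", "S", p$kmS)
    add("H", "L", p$kHL); add("L", "H", p$kmHL)
    add("HC", "LC", p$kHLC); add("LC", "HC", p$kmHLC)
    add("HC", "PHC", p$kHCP * P); add("PHC", "HC", p$kmHCP)
    add("PH", "PHC", p$kPHC * C); add("PHC", "PH", p$kmPHC)
    add("H", "PH", p$kPH * P); add("PH", "H", p$kmPH)
    add("LC", "PLC", p$kLCP * P); add("PLC", "LC", p$kmLCP)
    add("PL", "PLC", p$kPLC * C); add("PLC", "PL", p$kmPLC)
    add("L", "PL", p$kPL * P); add("PL", "L", p$kmPL)
    add("PH", "PL", p$kPHL); add("PL", "PH", p$kmPHL)
    add("PHC", "PLC", p$kPHLC); add("PLC", "PHC", p$kmPHLC)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Stationary distribution of the per-receptor chain at cAMP C. States not
## connected to H (the slow S pool has no zero-ligand interconversion) keep
## zero weight at C = 0.
receptor_stationary <- function(params, camp_uM, variant = "full") {
  Q <- receptor_generator(params, camp_uM, variant)
  n <- nrow(Q)
  reach <- reachable_states(Q, 1L)
  pi <- numeric(n); names(pi) <- rownames(Q)
  Qr <- Q[reach, reach, drop = FALSE]
  A <- rbind(t(Qr), rep(1, length(reach)))
  b <- c(numeric(length(reach)), 1)
  pi[reach] <- pmax(0, qr.solve(A, b))
  pi / sum(pi)
}

reachable_states <- function(Q, start) {
  n <- nrow(Q)
  seen <- logical(n); seen[start] <- TRUE
  repeat {
    new <- seen
    for (i in which(seen)) new <- new | (Q[i, ] > 0) | (Q[, i] > 0)
    if (all(new == seen)) break
    seen <- new
  }
  which(seen)
}

#' Steady-state receptor occupancy versus cAMP dose
#'
#' Mean-field (per-receptor Markov chain) stationary occupancy. Returns the
#' percentage of receptors in ligand-bound states at each dose; monotone
#' non-decreasing in the dose.
#'
#' @param params [gpcr_params()].
#' @param doses cAMP concentrations, uM (`>= 0`).
#' @param variant `"full"` or `"reduced"`.
#' @return data.frame with columns `dose` and `RO` (percent).
#' @export
dose_response <- function(params = gpcr_params(), doses,
                          variant = "full") {
  if (any(doses < 0)) stop("doses must be >= 0")
  occ <- gpcr_occupied_names(variant)
  ro <- vapply(doses, function(C)
    100 * sum(receptor_stationary(params, C, variant)[occ]), 0)
  data.frame(dose = doses, RO = ro)
}

#' Dose-response map with inverse
#'
#' @param params [gpcr_params()].
#' @param variant `"full"` or `"reduced"`.
#' @return list with `ro(dose)` (percent), `inverse(ro_pct)` (uM, by
#'   bisection; errors when the target exceeds the asymptote), and the
#'   saturating dose.
#' @export
dose_response_map <- function(params = gpcr_params(), variant = "full") {
  occ <- gpcr_occupied_names(variant)
  ro <- function(dose) vapply(dose, function(C)
    100 * sum(receptor_stationary(params, C, variant)[occ]), 0)
  inverse <- function(target) {
    vapply(target, function(tg) {
      if (tg <= 0) return(0)
      if (tg >= 100) stop("unreachable target R.O. (asymptote is 100%)")
      hi <- 1
      while (ro(hi) < tg) {
        hi <- hi * 10
        if (hi > 1e8) stop("unreachable target R.O.")
      }
      stats::uniroot(function(C) ro(C) - tg, c(0, hi),
                     tol = 1e-10)$root
    }, 0)
  }
  list(ro = ro, inverse = inverse,
       saturating = function(pct = 99) inverse(pct))
}

#' Saturating cAMP dose
#'
#' The dose at which steady-state receptor occupancy reaches `pct` percent
#' (default 99); used as the "100% R.O." stimulus level.
#' @param params [gpcr_params()].
#' @param pct target occupancy percentage.
#' @param variant receptor model variant.
#' @export
saturating_dose <- function(params = gpcr_params(), pct = 99,
                            variant = "full") {
  dose_response_map(params, variant)$inverse(pct)
}

#' Initialize receptors on the membrane
#'
#' Draws the total receptor number from the (zero-truncated) Gaussian
#' cell-to-cell distribution, scatters it multinomially over membrane nodes
#' proportional to nodal volume, and partitions each node's receptors among
#' the free states at the zero-cAMP deterministic equilibrium.
#'
#' @param params [gpcr_params()].
#' @param mesh a `shell_mesh` or `voxel_graph`.
#' @param seed integer seed.
#' @param variant receptor model variant.
#' @param camp_uM equilibrate at this (default zero) ambient dose.
#' @return integer matrix: receptor species x all mesh nodes.
#' @export
equilibrate_receptors <- function(params = gpcr_params(), mesh, seed = 1L,
                                  variant = "full", camp_uM = 0) {
  mem <- nodes_of(mesh, "membrane")
  if (!length(mem)) stop("mesh has no membrane nodes")
  nm <- gpcr_species_names(variant)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  total <- if (params$n_total_sd > 0) {
    x <- -1
    while (x <= 0) x <- stats::rnorm(1, params$n_total, params$n_total_sd)
    round(x)
  } else round(params$n_total)
  w <- mesh$nodal_volumes[mem]
  pernode <- as.integer(stats::rmultinom(1, total, w / sum(w)))
  pi <- receptor_stationary(params, camp_uM, variant)
  counts <- matrix(0L, length(nm), length(mesh$nodal_volumes),
                   dimnames = list(nm, NULL))
  for (q in seq_along(mem)) {
    if (pernode[q] == 0) next
    counts[, mem[q]] <- as.integer(stats::rmultinom(1, pernode[q], pi))
  }
  counts
}

#' Sample cell-to-cell parameter variation
#'
#' Independent Gaussian draws around the nominal values with the tabulated
#' standard deviations, truncated at zero by resampling; parameters are
#' homogeneous within a cell and vary across cells.
#'
#' @param nominal a parameter object ([gpcr_params()], [legi_params()] or
#'   [sten_params()]) carrying an `sd` list.
#' @param seed integer seed.
#' @return object of the same class with perturbed values.
#' @export
sample_cell_parameters <- function(nominal, seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- nominal
  for (n in names(p$sd)) {
    s <- p$sd[[n]]
    if (is.null(s) || s <= 0) next
    x <- -1
    while (x < 0) x <- stats::rnorm(1, nominal[[n]], s)
    p[[n]] <- x
  }
  if (!is.null(p$n_total_sd) && p$n_total_sd > 0) {
    x <- -1
    while (x <= 0) x <- stats::rnorm(1, nominal$n_total, p$n_total_sd)
    p$n_total <- round(x)
  }
  p
}

#' Half-times of the receptor response to a saturating step
#'
#' Runs the mean-field (per-receptor master equation) from the
#' unphosphorylated zero-ligand equilibrium under a cAMP step and measures
#' (a) the half-time of the pooled phosphorylated states (PH + PH:C + PL +
#' PL:C) approaching their plateau -- the slow, phosphate-driven
#' desensitization -- and (b) the half-time of the redistribution within the
#' occupied unphosphorylated class, measured on the H:C share of
#' H:C + L:C + S:C, which isolates the interconversion kinetics from both
#' the millisecond binding step and the slow phosphorylation drain.
#'
#' @param params [gpcr_params()].
#' @param dose cAMP step concentration (uM); default the saturating dose.
#' @param t_end integration horizon, s.
#' @return list `t_half_phospho`, `t_half_unphospho` (seconds).
#' @export
gpcr_step_halftimes <- function(params = gpcr_params(), dose = NULL,
                                t_end = 2000) {
  if (is.null(dose)) dose <- saturating_dose(params)
  Q <- receptor_generator(params, dose)
  nm <- gpcr_species_names()
  y0 <- stats::setNames(numeric(10), nm)
  y0["H"] <- params$kmHL / (params$kHL + params$kmHL)
  y0["L"] <- 1 - y0["H"]
  rhs <- function(t, y, p) list(as.numeric(t(Q) %*% y))
  tt <- c(seq(0, 30, 0.01), seq(30.1, t_end, 0.5))
  o <- deSolve::ode(y0, tt, rhs, NULL)
  phospho <- rowSums(o[, c("PH", "PHC", "PL", "PLC")])
  occ_unph <- rowSums(o[, c("HC", "LC", "SC")])
  hc_share <- o[, "HC"] / pmax(occ_unph, 1e-12)
  ## ignore the sub-50-ms binding transient when measuring the share decay
  i0 <- which(o[, 1] >= 0.05)
  list(t_half_phospho = half_time(o[, 1], phospho),
       t_half_unphospho = half_time(o[i0, 1], hc_share[i0],
                                    direction = "decay"))
}
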