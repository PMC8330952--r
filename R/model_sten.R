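## Signal transduction excitable network (STEN): RasGTP is the activator,
## PIP2 the mutually-inhibitory fast species (positive feedback loop through
## double inhibition), and activated PKB substrates (PKB*s) the slower
## negative feedback. The Ras activation propensity is rational: basal plus
## RR-driven drive divided by a PIP2-squared gate, so depleting PIP2 releases
## the brake (threshold lowering).
##
## The full-scale copy-number targets pin the calibration: at rest a
## membrane node holds ~60 PIP2, ~40 PKB*s and ~1 RasGTP molecule; a
## saturating uniform stimulus converts most of the Ras pool (whole-cell
## peak ~165,000 RasGTP, ~275,000 PKB*s). Rate-constant magnitudes were
## fixed once against those targets (see the methods vignette) and frozen.

#' STEN module parameters
#'
#' @param ... overrides of the defaults (`a1`, `a2`, `a30`, `a3`, `a4`,
#'   `a5`, `b1`, `b2`, `b3`, `b4`, `c1`, `c2`, diffusion constants,
#'   `ras_total`, `pkbs_pool`).
#' @param scale copy-number scale factor: molecule totals and the PIP2
#'   synthesis flux are multiplied by `scale`, bimolecular constants and the
#'   concentration-gate constants divided by it. The deterministic dynamics
#'   are preserved exactly; relative noise grows by `1/sqrt(scale)`.
#' @return object of class `sten_params`.
#' @export
sten_params <- function(..., scale = 1) {
  p <- list(
    a1 = 0.73,      # RasGTP basal deactivation, s^-1
    a2 = 4,         # PKB*s-mediated RasGTP deactivation, 1/(uM s)
    a30 = 0.5,      # basal Ras activation drive, s^-1
    a3 = 0.5,       # RR-driven activation drive, 1/(uM s); the
                    # product a3 * RR is what matters and the RR unit
                    # puts tens of molecules per node at basal
    a4 = 0.77,      # PIP2 gate strength, 1/uM
    a5 = 0.026,     # ungated RasGDP->RasGTP leak, s^-1
    b1 = 48.1,      # PIP2 synthesis, uM/s
    b2 = 0.481,     # PIP2 basal turnover, s^-1
    b3 = 19.2,      # RasGTP-driven PIP2 hydrolysis, 1/(uM s)
    b4 = 0.77,      # G_a2 (PLC)-driven PIP2 hydrolysis, 1/(uM s)
    c1 = 0.027,     # PKB*s deactivation, s^-1 (slow negative feedback)
    c2 = 0.2,       # RasGTP-driven PKBs activation, 1/(uM s)
    D_ras = 0.05, D_pip2 = 0.05, D_pkb = 0.4,
    ras_total = 365000,   # calibration: saturating peak RasGTP ~ 165,000
    pkbs_pool = 140000,   # calibration: saturating peak PKB*s ~ 275,000
    perturbation = NULL)
  p$sd <- lapply(p[c("a1", "a2", "a30", "a3", "a4", "a5", "b1", "b2",
                     "b3", "b4", "c1", "c2",
                     "D_ras", "D_pip2", "D_pkb")],
                 function(x) 0.1 * x)
  ov <- list(...)
  for (n in names(ov)) {
    if (!n %in% names(p)) stop("unknown STEN parameter: ", n)
    p[[n]] <- ov[[n]]
  }
  num <- unlist(p[c("a1", "a2", "a30", "a3", "a4", "a5", "b1", "b2", "b3",
                    "b4", "c1", "c2", "D_ras", "D_pip2", "D_pkb")])
  if (any(num < 0)) stop("STEN parameters must be >= 0")
  p$scale <- scale
  if (scale != 1) {
    for (n in c("a2", "a3", "a4", "b3", "b4", "c2")) p[[n]] <- p[[n]] / scale
    p$b1 <- p$b1 * scale
  }
  p$ras_total <- round(p$ras_total * scale)
  p$pkbs_pool <- round(p$pkbs_pool * scale)
  p$sd <- lapply(p[c("a1", "a2", "a30", "a3", "a4", "a5", "b1", "b2",
                     "b3", "b4", "c1", "c2",
                     "D_ras", "D_pip2", "D_pkb")],
                 function(x) 0.1 * x)
  structure(p, class = "sten_params")
}

#' Threshold perturbation specification
#'
#' @param kind `"pip2_depletion"` (extra first-order PIP2 degradation,
#'   magnitude in s^-1, applied everywhere), `"pkbs_attenuation"`
#'   (multiplicative factor on the PKBs activation rate `c2`), or
#'   `"basal_apical_asymmetry"` (multiplicative factors on the PKB*s-mediated
#'   RasGTP inhibition `a2` per membrane side; magnitude =
#'   `c(basal =, apical =)`).
#' @param magnitude see `kind`; must be `>= 0`.
#' @export
sten_perturbation <- function(kind = c("pip2_depletion", "pkbs_attenuation",
                                       "basal_apical_asymmetry"),
                              magnitude) {
  kind <- match.arg(kind)
  if (any(magnitude < 0)) stop("perturbation magnitudes must be >= 0")
  if (kind == "basal_apical_asymmetry" && length(magnitude) != 2)
    stop("basal_apical_asymmetry needs c(basal=, apical=) factors")
  structure(list(kind = kind, magnitude = magnitude),
            class = "sten_perturbation")
}

#' Apply a threshold perturbation to STEN parameters
#'
#' A zero-magnitude perturbation leaves the model unchanged.
#'
#' @param params [sten_params()].
#' @param perturbation a [sten_perturbation()].
#' @export
apply_threshold_perturbation <- function(params, perturbation) {
  stopifnot(inherits(params, "sten_params"))
  if (!inherits(perturbation, "sten_perturbation"))
    stop("unknown perturbation kind")
  params$perturbation <- perturbation
  params
}

#' Build the excitable-network fragment
#'
#' RasGDP/RasGTP/PIP2 live on membrane nodes; PKB*s on membrane and cortex
#' (its high diffusivity stands in for cytosolic shuttling). The Ras
#' activation reaction reads the response regulator (explicit species or the
#' registered implicit readout) and `G_a2` enters the PLC-mediated PIP2
#' hydrolysis, so the fragment must be assembled together with the
#' G-protein/LEGI fragments (or with `ga2_coupling = FALSE` and a fixed
#' `rr_const` for isolated use).
#'
#' @param params [sten_params()].
#' @param ga2_coupling include the `G_a2`-driven PIP2 hydrolysis reaction.
#' @param rr_const if non-`NULL`, drive Ras activation with this constant RR
#'   concentration (uM) instead of a LEGI readout (standalone STEN runs).
#' @return `rd_model` fragment (partial: expects `Ga2` and an RR source from
#'   the other fragments unless disabled here).
#' @export
build_sten_model <- function(params = sten_params(), ga2_coupling = TRUE,
                             rr_const = NULL) {
  p <- params
  pert <- p$perturbation
  c2 <- p$c2
  a2_side <- NULL
  if (!is.null(pert)) {
    if (pert$kind == "pkbs_attenuation") c2 <- c2 * pert$magnitude
    if (pert$kind == "basal_apical_asymmetry") a2_side <- pert$magnitude
  }
  sp <- list(species("RasGDP", D = p$D_ras, localization = "membrane"),
             species("RasGTP", D = p$D_ras, localization = "membrane"),
             species("PIP2", D = p$D_pip2, localization = "membrane"),
             species("PKBs_star", D = p$D_pkb, localization = "all"))
  rx <- list(
    reaction("ras_deact_basal", "first", k = p$a1, reactants = "RasGTP",
             stoich = c(RasGTP = -1, RasGDP = +1)),                    # 1
    reaction("ras_deact_pkb", "second", k = p$a2,
             reactants = c("RasGTP", "PKBs_star"),
             stoich = c(RasGTP = -1, RasGDP = +1),
             side_scale = a2_side),                                    # 2
    reaction("ras_act_gated", "sten_r3", a30 = p$a30, a3 = p$a3,
             a4 = p$a4, reactants = c("RasGDP", "PIP2"),
             stoich = c(RasGDP = -1, RasGTP = +1)),                    # 3
    reaction("ras_act_leak", "first", k = p$a5, reactants = "RasGDP",
             stoich = c(RasGDP = -1, RasGTP = +1)),                    # 4
    reaction("pip2_synth", "zeroth", k = p$b1, stoich = c(PIP2 = +1)), # 5
    reaction("pip2_decay", "first", k = p$b2, reactants = "PIP2",
             stoich = c(PIP2 = -1)),                                   # 6
    reaction("pip2_hydrolysis_ras", "second", k = p$b3,
             reactants = c("PIP2", "RasGTP"), stoich = c(PIP2 = -1)),  # 7
    reaction("pkb_deact", "first", k = p$c1, reactants = "PKBs_star",
             stoich = c(PKBs_star = -1), locale = "all"),              # 9
    reaction("pkb_act", "pool_second", k = c2, pool_total = p$pkbs_pool,
             reactants = c("PKBs_star", "RasGTP"),
             stoich = c(PKBs_star = +1)))                              # 10
  if (ga2_coupling)
    rx[[length(rx) + 1L]] <-
      reaction("pip2_hydrolysis_plc", "second", k = p$b4,
               reactants = c("PIP2", "Ga2"), stoich = c(PIP2 = -1))    # 8
  if (!is.null(pert) && pert$kind == "pip2_depletion" &&
      pert$magnitude > 0)
    rx[[length(rx) + 1L]] <-
      reaction("pip2_depletion", "first", k = pert$magnitude,
               reactants = "PIP2", stoich = c(PIP2 = -1))
  ro <- NULL
  if (!is.null(rr_const))
    ro <- rr_readout_spec("difference", g = "RasGDP", i = "RasGDP",
                          par = c(rr_const, 0, 0))
  rd_model(sp, rx, rr_readout = ro, partial = TRUE)
}
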