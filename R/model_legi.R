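## LEGI (local excitation - global inhibition) module. The excitation process
## is heterotrimeric G-protein dissociation driven by occupied receptors (RL);
## the inhibition process is a fast-diffusing inhibitor I/I* activated by the
## same RL. Their comparison sets a response regulator RR, realized five ways:
## explicit or implicit difference, explicit or implicit ratio, and antithetic
## integral feedback (AIF).
##
## The inhibitor rate constants are proportional to the G-protein ones
## (kI0/kI matches kE0/kE to 0.6%), so with activation and deactivation both
## firing at the membrane the I* steady state tracks the G_bg steady state:
## i_ss = lambda * g_ss at every uniform dose, lambda = (kI/kE)(k-E/k-I).
## Choosing the inhibitor total as lambda times the G-protein total makes the
## proportionality exact, which is what gives the difference scheme perfect
## mean adaptation; beta = 1/lambda in the implicit difference readout.

#' Table of G-protein rate constants by G-protein:receptor ratio
#'
#' Rates fitted per total-G-protein ratio; `kE0` in s^-1, `kE` and `kmE`
#' in 1/(uM s).
#' @export
GPROTEIN_RATE_TABLE <- data.frame(
  ratio = c(0.1, 0.2, 0.5, 1, 2, 3, 4, 5),
  kE0 = c(7.56, 6.11, 4.36, 3.63, 2.91, 2.18, 2.02, 1.77) * 1e-7,
  kE  = c(2.8, 2.3, 1.6, 1.3, 1.1, 0.81, 0.75, 0.66) * 1e-2,
  kmE = c(14.6, 11.8, 8.4, 5.0, 3.5, 3.0, 2.8, 2.75) * 1e-2)

#' Basal response-regulator concentration (uM)
#'
#' Common basal RR level of all LEGI schemes, a calibration constant of the
#' package chosen together with the STEN threshold (the product of this
#' level and the RR-driven activation gain sets the resting drive). The
#' absolute RR unit is fixed so that a node holds tens of RR molecules at
#' basal -- the scale at which the molecular difference/ratio/AIF schemes
#' operate away from the zero-count boundary.
#' @export
LEGI_RR_BASAL <- 2

#' Response-regulator gain (uM RR per uM of excitor-inhibitor imbalance)
#'
#' Sets how strongly a transient G_bg / I* imbalance raises RR; calibrated
#' once (jointly with [LEGI_RR_BASAL] and the excitable network's RR-driven
#' activation gain) so that a saturating uniform step drives the activation
#' numerator ~50-fold above rest, enough to fire the network cell-wide.
#' @export
LEGI_RR_GAIN <- 25

#' LEGI module parameters
#'
#' @param ratio total G-protein : total receptor ratio (a value from
#'   [GPROTEIN_RATE_TABLE]; default 3).
#' @param scheme response-regulator realization.
#' @param n_receptors total receptors (sets G-protein and inhibitor totals).
#' @param volume_ratio shell-to-membrane volume ratio of the mesh the model
#'   will run on (V_all / V_membrane, ~1.97 for the default geometry). The
#'   inhibitor total is `lambda * G_total * volume_ratio` so that the I*
#'   concentration tracks the G_bg concentration exactly at every uniform
#'   dose, which is what makes mean adaptation perfect.
#' @param ... overrides: `kE0`, `kE`, `kmE` (required if `ratio` is not
#'   tabulated), `kI0`, `kI`, `kmI`, `D_G`, `D_I`, `alpha0`, `alpha1`,
#'   `rr_relax`, AIF rates `kX0`, `kX`, `kmX`, `kmXY`, `kY0`, `kY`, `kmY`,
#'   `kRR`, `kmRR`, `D_X`, `D_RR`, `I_total`, `G_total`.
#' @param inhibitor_localization `"all"` (membrane + cortex, the default)
#'   or `"membrane"`. The membrane-local configuration (together with
#'   `volume_ratio = 1` and a small `D_I`) is the cheap desk-scale setting
#'   for spatially uniform stimuli, where inhibitor diffusivity only
#'   averages fluctuations; gradient runs need the default.
#' @param scale copy-number scale factor for desk-scale runs: all molecule
#'   totals are multiplied by `scale` and all bimolecular rate constants
#'   divided by it, which preserves the deterministic (concentration)
#'   dynamics exactly while reducing the event rate and raising relative
#'   noise by `1/sqrt(scale)`.
#' @return object of class `legi_params`.
#' @export
legi_params <- function(ratio = 3,
                        scheme = c("implicit_difference", "implicit_ratio",
                                   "explicit_difference", "explicit_ratio",
                                   "AIF"),
                        n_receptors = 70000, volume_ratio = 1.97,
                        inhibitor_localization = c("all", "membrane"),
                        scale = 1, ...) {
  scheme <- match.arg(scheme)
  inhibitor_localization <- match.arg(inhibitor_localization)
  ov <- list(...)
  row <- match(ratio, GPROTEIN_RATE_TABLE$ratio)
  if (is.na(row) &&
      !all(c("kE0", "kE", "kmE") %in% names(ov)))
    stop("unknown G-protein ratio ", ratio,
         "; supply kE0, kE, kmE explicitly")
  p <- list(
    ratio = ratio, scheme = scheme, n_receptors = n_receptors,
    volume_ratio = volume_ratio,
    inhibitor_localization = inhibitor_localization,
    kE0 = GPROTEIN_RATE_TABLE$kE0[row],
    kE = GPROTEIN_RATE_TABLE$kE[row],
    kmE = GPROTEIN_RATE_TABLE$kmE[row],
    kI0 = 0.65e-7, kI = 0.24e-2, kmI = 0.90e-2,
    D_G = 0.2, D_I = 20, D_X = 0.2, D_RR = 0.1,
    ## implicit/explicit difference & ratio readout constants
    alpha0 = LEGI_RR_BASAL, alpha1 = LEGI_RR_GAIN,
    rr_relax = 0.5,            # explicit-scheme RR relaxation rate, s^-1
    ratio_frac = 0.2,          # a = ratio_frac * basal g in the ratio form
    ## AIF: kY2 (the I*-and-RR-driven annihilation partner production) is
    ## solved at build time so the integral-feedback steady state sits at
    ## the common basal RR, accounting for the X/Y decay leaks
    kX0 = 1e-6, kX = 2e2, kmX = 1, kmXY = 20,
    kY0 = 10, kY = 2e2, kmY = 1, kRR = 10, kmRR = 1,
    G_total = NULL, I_total = NULL)
  p$sd <- list(kE0 = 0.87e-7, kE = 0.32e-2, kmE = 1.2e-2,
               kI0 = 0.26e-7, kI = 0.07e-2, kmI = 0.36e-2,
               D_G = 0.04, D_I = 4, D_X = 0.04, D_RR = 0.02,
               kX = 0.8e2, kmX = 0.4, kmXY = 8, kY0 = 4, kY = 0.8e2,
               kmY = 0.4, kRR = 4, kmRR = 0.4)
  for (n in names(ov)) {
    if (!n %in% names(p)) stop("unknown LEGI parameter: ", n)
    p[[n]] <- ov[[n]]
  }
  if (p$D_I < p$D_G)
    warning("gradient sensing requires the inhibitor to diffuse at least ",
            "as fast as G_bg; use a reduced D_I only for spatially ",
            "uniform protocols")
  if (any(unlist(p[c("kE0", "kE", "kmE", "kI0", "kI", "kmI")]) < 0))
    stop("rates must be >= 0")
  p$scale <- scale
  if (scale != 1) {
    for (n in c("kE", "kmE", "kI", "kmI", "kmXY")) {
      p[[n]] <- p[[n]] / scale
      if (!is.null(p$sd[[n]])) p$sd[[n]] <- p$sd[[n]] / scale
    }
    p$alpha0 <- p$alpha0 * scale
    p$n_receptors <- n_receptors * scale
    p$kX0 <- p$kX0 * scale
  }
  if (is.null(p$G_total)) p$G_total <- round(ratio * p$n_receptors)
  p$lambda <- (p$kI / p$kE) * (p$kmE / p$kmI)
  if (is.null(p$I_total))
    p$I_total <- round(p$lambda * p$G_total * volume_ratio)
  structure(p, class = "legi_params")
}

## Occupied-receptor species of the coupled receptor variant.
rl_species <- function(gpcr_variant) gpcr_occupied_names(gpcr_variant)

#' Build the G-protein dynamics fragment
#'
#' Heterotrimer `G_abg` dissociates into `G_bg` + `G_a2` (basal and
#' RL-catalyzed) and reassociates bimolecularly; all three species are
#' membrane-bound. `G_a2` is tracked explicitly (the excitable network reads
#' it) and is produced/consumed 1:1 with `G_bg`, so `G_abg + G_bg` is
#' conserved.
#'
#' @param params [legi_params()].
#' @param gpcr_variant which receptor variant supplies the occupied states.
#' @return `rd_model` fragment.
#' @export
build_gprotein_model <- function(params = legi_params(),
                                 gpcr_variant = "full") {
  p <- params
  sp <- list(species("Gabg", D = p$D_G, localization = "membrane"),
             species("Gbg", D = p$D_G, localization = "membrane"),
             species("Ga2", D = p$D_G, localization = "membrane"))
  rx <- list(
    reaction("G_diss_basal", "first", k = p$kE0, reactants = "Gabg",
             stoich = c(Gabg = -1, Gbg = +1, Ga2 = +1)),
    reaction("G_reass", "second", k = p$kmE, reactants = c("Ga2", "Gbg"),
             stoich = c(Ga2 = -1, Gbg = -1, Gabg = +1)))
  for (s in rl_species(gpcr_variant))
    rx[[length(rx) + 1L]] <-
      reaction(paste0("G_diss_", s), "second", k = p$kE,
               reactants = c("Gabg", s),
               stoich = c(Gabg = -1, Gbg = +1, Ga2 = +1))
  rd_model(sp, rx, partial = TRUE)
}

#' Build the LEGI fragment (inhibitor + response regulator scheme)
#'
#' Adds the diffusive inhibitor pair I/I* (activation basal and RL-driven at
#' the membrane, deactivation with the combinatorial `[I*][I*-1]` propensity)
#' and the chosen response-regulator realization. Implicit schemes register
#' a per-voxel algebraic readout instead of simulated RR species.
#'
#' @param params [legi_params()].
#' @param gpcr_variant receptor variant supplying RL.
#' @return `rd_model` fragment (with `rr_readout` set for implicit schemes).
#' @export
build_legi_model <- function(params = legi_params(),
                             gpcr_variant = "full") {
  p <- params
  sp <- list(species("I", D = p$D_I,
                     localization = p$inhibitor_localization),
             species("Istar", D = p$D_I,
                     localization = p$inhibitor_localization))
  rx <- list(
    reaction("I_act_basal", "first", k = p$kI0, reactants = "I",
             stoich = c(I = -1, Istar = +1)),
    reaction("I_deact", "second_self", k = p$kmI, reactants = "Istar",
             stoich = c(Istar = -1, I = +1)))
  for (s in rl_species(gpcr_variant))
    rx[[length(rx) + 1L]] <-
      reaction(paste0("I_act_", s), "second", k = p$kI,
               reactants = c("I", s),
               stoich = c(I = -1, Istar = +1))

  a0 <- p$alpha0; a1 <- p$alpha1; beta <- 1 / p$lambda
  gb <- basal_gbg_conc(p)
  ib <- p$lambda * gb
  scheme <- p$scheme

  if (scheme == "implicit_difference") {
    return(rd_model(sp, rx, partial = TRUE, rr_readout = rr_readout_spec(
      "difference", g = "Gbg", i = "Istar", par = c(a0, a1, beta))))
  }
  if (scheme == "implicit_ratio") {
    a <- p$ratio_frac * gb; b <- p$lambda * a
    rho <- a0 * p$lambda
    return(rd_model(sp, rx, partial = TRUE, rr_readout = rr_readout_spec(
      "ratio", g = "Gbg", i = "Istar", par = c(rho, a, b))))
  }

  if (scheme == "explicit_difference") {
    ## RR: basal + G_bg-driven production, first-order leak, and I*-set
    ## zero-order (saturated, X-mediated) degradation; quasi-steady state is
    ## exactly max(0, a0 + a1 (g - beta i)).
    d <- p$rr_relax
    kxd <- 2
    sp2 <- c(sp, list(species("RR", D = p$D_RR, localization = "membrane"),
                      species("Xd", D = p$D_X, localization = "membrane")))
    rx2 <- c(rx, list(
      reaction("RR_basal", "zeroth", k = a0 * d, stoich = c(RR = +1)),
      reaction("RR_prod_g", "first", k = a1 * d, reactants = "Gbg",
               stoich = c(RR = +1)),
      reaction("RR_leak", "first", k = d, reactants = "RR",
               stoich = c(RR = -1)),
      reaction("Xd_prod", "first", k = kxd, reactants = "Istar",
               stoich = c(Xd = +1)),
      reaction("Xd_decay", "first", k = kxd, reactants = "Xd",
               stoich = c(Xd = -1)),
      reaction("RR_deg_X", "cat_gated", k = a1 * beta * d,
               reactants = c("Xd", "RR"), stoich = c(RR = -1))))
    return(rd_model(sp2, rx2, partial = TRUE))
  }
  if (scheme == "explicit_ratio") {
    ## production rho s (a + g); removal s (b + i) RR: qss rho (a+g)/(b+i)
    s0 <- p$rr_relax
    a <- p$ratio_frac * gb; b <- p$lambda * a
    rho <- a0 * p$lambda
    sp2 <- c(sp, list(species("RR", D = p$D_RR, localization = "membrane")))
    rx2 <- c(rx, list(
      reaction("RR_basal", "zeroth", k = rho * a * s0, stoich = c(RR = +1)),
      reaction("RR_prod_g", "first", k = rho * s0, reactants = "Gbg",
               stoich = c(RR = +1)),
      reaction("RR_decay_basal", "first", k = b * s0, reactants = "RR",
               stoich = c(RR = -1)),
      reaction("RR_decay_i", "second", k = s0, reactants = c("RR", "Istar"),
               stoich = c(RR = -1))))
    return(rd_model(sp2, rx2, partial = TRUE))
  }
  ## AIF: the excitor and inhibitor drive intermediates that annihilate
  ## pairwise, with RR inside the feedback loop: X is produced from G_bg
  ## and activates RR; Y is produced jointly by I* and RR and annihilates
  ## X. The annihilation enforces kX [G_bg] = kY2 [I*][RR] on average, so
  ## RR_ss = (kX / kY2) [G_bg]/[I*] -- an integral-feedback ratio
  ## comparison that is independent of the absolute signal levels and
  ## returns to the common basal at every uniform dose.
  kY2 <- aif_setpoint_kY2(p, gb, ib)
  sp2 <- c(sp, list(species("X", D = p$D_X, localization = "membrane"),
                    species("Y", D = p$D_X, localization = "membrane"),
                    species("RR", D = p$D_RR, localization = "membrane")))
  rx2 <- c(rx, list(
    reaction("X_basal", "zeroth", k = p$kX0, stoich = c(X = +1)),
    reaction("X_prod_g", "first", k = p$kX, reactants = "Gbg",
             stoich = c(X = +1)),
    reaction("X_decay", "first", k = p$kmX, reactants = "X",
             stoich = c(X = -1)),
    reaction("XY_annihilate", "second", k = p$kmXY, reactants = c("X", "Y"),
             stoich = c(X = -1, Y = -1)),
    reaction("Y_basal", "zeroth", k = p$kX0, stoich = c(Y = +1)),
    reaction("Y_prod_i_rr", "second", k = kY2, reactants = c("Istar", "RR"),
             stoich = c(Y = +1)),
    reaction("Y_decay", "first", k = p$kmY, reactants = "Y",
             stoich = c(Y = -1)),
    reaction("RR_prod_x", "first", k = p$kRR, reactants = "X",
             stoich = c(RR = +1)),
    reaction("RR_decay", "first", k = p$kmRR, reactants = "RR",
             stoich = c(RR = -1))))
  rd_model(sp2, rx2, partial = TRUE)
}

## Basal dissociated G_bg concentration (uM over the membrane compartment).
basal_gbg_conc <- function(p, volumes = default_volumes()) {
  if (inherits(volumes, c("shell_mesh", "voxel_graph")))
    volumes <- compartment_volumes(volumes)
  GT <- p$G_total / (MOLEC_PER_UM3_UM * volumes[["membrane"]])
  sqrt(p$kE0 * GT / p$kmE)
}

## Solve for the AIF annihilation-partner production constant kY2 such
## that the well-mixed steady state has RR = alpha0 at the basal excitor /
## inhibitor levels, X/Y decay leaks included.
aif_setpoint_kY2 <- function(p, gb, ib) {
  rr_ss <- function(kY2) {
    resid <- function(X) {
      RR <- p$kRR * X / p$kmRR
      Y <- (kY2 * ib * RR + p$kX0) / (p$kmY + p$kmXY * X)
      X * (p$kmX + p$kmXY * Y) - (p$kX0 + p$kX * gb)
    }
    X <- stats::uniroot(resid, c(1e-12, 1e4), tol = 1e-12)$root
    p$kRR * X / p$kmRR
  }
  stats::uniroot(function(k) rr_ss(k) - p$alpha0,
                 c(1e-8, 1e8), tol = 1e-10, extendInt = "downX")$root
}

#' Normalized G-protein dose curve and its half-maximum occupancy
#'
#' Steady-state dissociated G_bg versus receptor occupancy on the mean-field
#' (well-mixed membrane) model, normalized to its value at 100% occupancy.
#' Because of spare receptors the normalized curve is independent of the
#' total G-protein count; its half-maximum sits near 23% R.O.
#'
#' @param params [legi_params()] (the `ratio` selects the rate set).
#' @param ro_grid receptor occupancy grid, percent.
#' @param volumes compartment volumes (um^3) or a mesh.
#' @return list: data.frame `curve` (`RO`, `gbg`, `normalized`), scalar
#'   `half_max_RO` (percent), and the dissociated fraction at saturation.
#' @export
gprotein_dose_curve <- function(params = legi_params(),
                                ro_grid = seq(0, 100, 0.5),
                                volumes = default_volumes()) {
  if (inherits(volumes, c("shell_mesh", "voxel_graph")))
    volumes <- compartment_volumes(volumes)
  p <- params
  Vm <- volumes[["membrane"]]
  RT <- p$n_receptors / (MOLEC_PER_UM3_UM * Vm)
  GT <- p$G_total / (MOLEC_PER_UM3_UM * Vm)
  gss <- function(RL) {
    a <- p$kE0 + p$kE * RL
    (-a + sqrt(a^2 + 4 * p$kmE * a * GT)) / (2 * p$kmE)
  }
  g <- vapply(ro_grid / 100 * RT, gss, 0)
  gn <- g / gss(RT)
  hm <- stats::approx(gn, ro_grid, xout = 0.5, ties = "ordered")$y
  list(curve = data.frame(RO = ro_grid, gbg = g, normalized = gn),
       half_max_RO = hm, dissociated_fraction_sat = gss(RT) / GT)
}
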