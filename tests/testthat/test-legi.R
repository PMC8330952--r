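test_that("G-protein dissociation is negligible without stimulus", {
  lg <- legi_params(scale = 0.1)
  mod <- rd_model(build_gprotein_model(lg, "reduced"),
                  species("RC", D = 0, localization = "membrane"))
  g <- unit_voxel(22.2)
  init <- c(Gabg = lg$G_total, RC = 0)
  tr <- simulate_nsm(mod, g, init, t_end = 100, seed = 2,
                     record = list(dt = 1))
  # basal dissociation rate is ~1e-7/s: essentially all G heterotrimeric
  expect_gt(min(wc_trace(tr, "Gabg")), 0.99 * lg$G_total)
  # G_abg + G_bg conserved
  expect_true(all(wc_trace(tr, "Gabg") + wc_trace(tr, "Gbg") ==
                    lg$G_total))
})

test_that("G-protein steady state solves the algebraic balance", {
  lg <- legi_params()
  dc <- gprotein_dose_curve(lg)
  g100 <- dc$curve$gbg[nrow(dc$curve)]
  # kE0 G + kE G RL = k-E Ga2 Gbg at steady state (Ga2 = Gbg)
  Vm <- 22.2
  RL <- lg$n_receptors / (602.214076 * Vm)
  GT <- lg$G_total / (602.214076 * Vm)
  lhs <- (lg$kE0 + lg$kE * RL) * (GT - g100)
  expect_equal(lhs, lg$kmE * g100^2, tolerance = 1e-6)
})

test_that("normalized G-protein dose curves show spare-receptor behavior", {
  d3 <- gprotein_dose_curve(legi_params(ratio = 3))
  expect_lt(abs(d3$half_max_RO - 23), 5)
  expect_lt(d3$curve$normalized[1], 0.01)
  # normalized curves for ratios 1 and 5 coincide
  d1 <- gprotein_dose_curve(legi_params(ratio = 1))
  d5 <- gprotein_dose_curve(legi_params(ratio = 5))
  expect_lt(max(abs(d1$curve$normalized - d5$curve$normalized)), 0.05)
  # but the dissociated fraction itself decreases with total G-protein
  expect_gt(d1$dissociated_fraction_sat, d5$dissociated_fraction_sat)
})

test_that("implicit readout forms behave algebraically", {
  ro_d <- rr_readout_spec("difference", "Gbg", "Istar",
                          par = c(0.02, 0.25, 2))
  expect_equal(rr_implicit_readout(0, 0, ro_d, 8e-3), 0.02)
  # affine in the difference: raising g and beta*i by equal amounts is flat
  u <- one_molecule_uM(8e-3)
  r1 <- rr_implicit_readout(100, 10, ro_d, 8e-3)
  r2 <- rr_implicit_readout(100 + 50, 10 + 25, ro_d, 8e-3)  # beta = 2
  expect_equal(r1, r2)
  # clamped at zero
  expect_equal(rr_implicit_readout(0, 1000, ro_d, 8e-3), 0)
  ro_r <- rr_readout_spec("ratio", "Gbg", "Istar", par = c(0.05, 0.2, 0.3))
  expect_equal(rr_implicit_readout(0, 0, ro_r, 8e-3), 0.05 * 0.2 / 0.3)
  # scaling both inputs approaches the pure ratio limit
  lam <- 1e5
  expect_equal(rr_implicit_readout(lam * 30, lam * 20, ro_r, 8e-3),
               0.05 * 30 / 20, tolerance = 1e-3)
})

test_that("AIF fragment adds the nine integral-feedback reactions", {
  frag <- build_legi_model(legi_params(scheme = "AIF"), "reduced")
  base <- build_legi_model(legi_params(scheme = "implicit_difference"),
                           "reduced")
  expect_equal(length(frag$reactions) - length(base$reactions), 9)
  expect_true(all(c("X", "Y", "RR") %in% frag$species_names))
  ann <- Filter(function(r) identical(unname(r$stoich), c(-1, -1)) &&
                  setequal(names(r$stoich), c("X", "Y")), frag$reactions)
  expect_length(ann, 1)
})

test_that("all schemes share the same basal RR and adapt in the mean field", {
  gp <- gpcr_params(n_total_sd = 0)
  vols <- c(membrane = 22.2, all = 43.7)
  doses <- dose_response_map(gp)$inverse(c(10, 50, 90))
  for (scheme in c("implicit_difference", "implicit_ratio", "AIF")) {
    lg <- legi_params(scheme = scheme,
                      volume_ratio = vols[["all"]] / vols[["membrane"]])
    mod <- build_signaling_model(gp, lg, NULL)
    nm <- mod$species_names
    totals <- setNames(numeric(length(nm)), nm)
    totals[gpcr_species_names()] <- 70000 *
      rdmecell:::receptor_stationary(gp, 0)
    # seed the basal dissociated/active levels (their basal turnover is far
    # too slow to establish during a run)
    gb <- rdmecell:::basal_gbg_conc(lg, vols) * 602.214076
    totals["Gbg"] <- totals["Ga2"] <- gb * vols[["membrane"]]
    totals["Gabg"] <- lg$G_total - 2 * totals[["Gbg"]]
    totals["Istar"] <- lg$lambda * gb * vols[["all"]]
    totals["I"] <- lg$I_total - totals[["Istar"]]
    rr_of <- function(y) {
      ro <- mod$rr_readout
      if (!is.null(ro)) {
        g <- y[[ro$g]]; i <- y[[ro$i]]
        if (ro$mode == "difference")
          max(0, ro$par[1] + ro$par[2] * (g - ro$par[3] * i))
        else ro$par[1] * (ro$par[2] + g) / (ro$par[3] + i)
      } else y[["RR"]]
    }
    rr_ss <- vapply(c(0, doses), function(d) {
      mf <- simulate_meanfield(mod, totals, t_end = 900, volumes = vols,
                               stimulus = if (d > 0) make_step_protocol(d)
                                          else NULL, dt = 3)
      rr_of(mf[nrow(mf), ])
    }, 0)
    # common basal and perfect mean adaptation: steady-state RR returns to
    # the basal level at every uniform dose
    expect_equal(rr_ss[1], lg$alpha0, tolerance = 0.1)
    expect_lt(max(abs(rr_ss - rr_ss[1])), 0.15 * lg$alpha0 + 2e-3)
  }
})

test_that("explicit difference scheme has the implicit form as quasi-steady
           state", {
  gp <- gpcr_params(n_total_sd = 0)
  lg <- legi_params(scheme = "explicit_difference")
  mod <- build_signaling_model(gp, lg, NULL)
  nm <- mod$species_names
  vols <- c(membrane = 22.2, all = 43.7)
  totals <- setNames(numeric(length(nm)), nm)
  totals[gpcr_species_names()] <- 70000 *
    rdmecell:::receptor_stationary(gp, 0)
  gb <- rdmecell:::basal_gbg_conc(lg, vols) * 602.214076
  totals["Gbg"] <- totals["Ga2"] <- gb * vols[["membrane"]]
  totals["Gabg"] <- lg$G_total - 2 * totals[["Gbg"]]
  totals["Istar"] <- lg$lambda * gb * vols[["all"]]
  totals["I"] <- lg$I_total - totals[["Istar"]]
  d <- dose_response_map(gp)$inverse(50)
  mf <- simulate_meanfield(mod, totals, t_end = 250, volumes = vols,
                           stimulus = make_step_protocol(d), dt = 1)
  y <- mf[nrow(mf), ]
  rr_implicit <- max(0, lg$alpha0 + lg$alpha1 *
                          (y[["Gbg"]] - (1 / lg$lambda) * y[["Istar"]]))
  expect_equal(y[["RR"]], rr_implicit, tolerance = 0.15)
})

test_that("adaptation metrics read peaks and steady states correctly", {
  tt <- seq(0, 120, 0.5)
  # constant trace: no peak, steady state at basal
  m0 <- adaptation_metrics(tt, rep(3, length(tt)), t_step = 10)
  expect_equal(m0$RR_peak, 0)
  expect_equal(m0$RR_ss, 3)
  # synthetic pulse with known peak at t_step + 7
  y <- 1 + 5 * exp(-((tt - 17)^2) / 8) * (tt >= 10)
  m1 <- adaptation_metrics(tt, y, t_step = 10)
  expect_equal(m1$T_peak, 7, tolerance = 0.51)
  expect_equal(m1$RR_peak, 5, tolerance = 0.1)
  expect_lt(m1$T_adaptation, 40)
})
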