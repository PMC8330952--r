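test_that("the rational Ras activation propensity has the printed limits", {
  # with PIP2 = 0 and RR = 0 the denominator is 1 and the propensity is
  # a30 * n_RasGDP: count firings of an isolated activation channel against
  # the Poisson law
  st <- sten_params()
  mod <- rd_model(
    species("RasGDP", D = 0, localization = "membrane"),
    species("RasGTP", D = 0, localization = "membrane"),
    species("PIP2", D = 0, localization = "membrane"),
    reaction("act", "sten_r3", a30 = st$a30, a3 = st$a3, a4 = st$a4,
             reactants = c("RasGDP", "PIP2"),
             stoich = c(RasGTP = +1)),   # catalytic: leave RasGDP constant
    rr_readout = rr_readout_spec("difference", "RasGDP", "RasGDP",
                                 par = c(0, 0, 0)))
  g <- unit_voxel(8e-3)
  init <- c(RasGDP = 100, RasGTP = 0, PIP2 = 0)
  tr <- simulate_nsm(mod, g, init, t_end = 4, seed = 3,
                     record = list(dt = 4))
  n <- unname(tr$final["RasGTP", 1])
  lambda <- st$a30 * 100 * 4
  expect_gt(n, qpois(0.0005, lambda))
  expect_lt(n, qpois(0.9995, lambda))
  # a high PIP2 count suppresses the propensity by the squared gate
  init2 <- c(RasGDP = 100, RasGTP = 0, PIP2 = 300)
  tr2 <- simulate_nsm(mod, g, init2, t_end = 4, seed = 3,
                      record = list(dt = 4))
  u <- one_molecule_uM(8e-3)
  den <- st$a4^2 * u^2 * 300 * 299 + 1
  expect_lt(tr2$final["RasGTP", 1], qpois(0.9995, lambda / den) + 1)
})

test_that("Ras pool is conserved and PKB*s never exceeds its voxel pool", {
  st <- sten_params(scale = 0.02)
  mod <- build_sten_model(st, ga2_coupling = FALSE, rr_const = 0.02 * 0.02)
  mesh <- coarse_mesh()
  init <- init_totals <- c(RasGDP = st$ras_total, RasGTP = 0,
                           PIP2 = round(st$ras_total / 3), PKBs_star = 0)
  tr <- simulate_nsm(rd_model(mod), mesh, init, t_end = 40, seed = 8,
                     record = list(dt = 1, species = "PKBs_star"))
  ras <- wc_trace(tr, "RasGDP") + wc_trace(tr, "RasGTP")
  expect_true(all(ras == st$ras_total))
  expect_true(all(tr$wc >= 0))
  # per-voxel pool bound: membrane nodes cannot exceed their share + influx;
  # the whole-cell count stays below the pool ceiling
  expect_true(max(wc_trace(tr, "PKBs_star")) <= st$pkbs_pool)
})

test_that("the excitable network has an all-or-nothing threshold in its
           drive", {
  # the response-regulator drive is the excitability axis: below threshold
  # the Ras response stays a graded few-percent excursion, just above it
  # the network converts a large fraction of the Ras pool
  st <- sten_params()
  vols <- c(membrane = 22.2, all = 43.7)
  mod0 <- rd_model(build_sten_model(st, ga2_coupling = FALSE,
                                    rr_const = LEGI_RR_BASAL))
  tot0 <- c(RasGDP = st$ras_total, PIP2 = 0, PKBs_star = 0)
  base <- simulate_meanfield(mod0, tot0, t_end = 400, volumes = vols, dt = 2)
  rest <- base[nrow(base), -1]
  rest_counts <- setNames(pmax(0, rest * 602.214076 *
                                 c(22.2, 22.2, 22.2, 43.7)), names(rest))
  peak_at <- function(rr) {
    mod <- rd_model(build_sten_model(st, ga2_coupling = FALSE,
                                     rr_const = rr))
    mf <- simulate_meanfield(mod, rest_counts, t_end = 30, volumes = vols,
                             dt = 0.2)
    max(mf[, "RasGTP"]) * 602.214076 * 22.2
  }
  sub <- peak_at(4 * LEGI_RR_BASAL)
  supra <- peak_at(8 * LEGI_RR_BASAL)
  expect_lt(sub, 0.02 * st$ras_total)
  expect_gt(supra, 0.25 * st$ras_total)
  # disproportionate gain: doubling the drive multiplies the response
  # many-fold across the threshold
  expect_gt(supra / sub, 10)
  # and the excursion is a pulse: back at the basal drive the system
  # returns to rest rather than locking high
  mod1 <- rd_model(build_sten_model(st, ga2_coupling = FALSE,
                                    rr_const = LEGI_RR_BASAL))
  fired <- rest_counts
  flip <- round(0.6 * st$ras_total)
  fired[["RasGTP"]] <- fired[["RasGTP"]] + flip
  fired[["RasGDP"]] <- max(0, fired[["RasGDP"]] - flip)
  fired[["PIP2"]] <- 0
  mf <- simulate_meanfield(mod1, fired, t_end = 300, volumes = vols, dt = 1)
  expect_lt(mf[nrow(mf), "RasGTP"] * 602.214076 * 22.2,
            2 * rest_counts[["RasGTP"]] + 2000)
})

test_that("threshold perturbations modify the model as specified", {
  st <- sten_params()
  # zero-magnitude depletion leaves the reaction set unchanged
  st0 <- apply_threshold_perturbation(
    st, sten_perturbation("pip2_depletion", 0))
  m0 <- build_sten_model(st0, ga2_coupling = FALSE, rr_const = 0.02)
  m <- build_sten_model(st, ga2_coupling = FALSE, rr_const = 0.02)
  expect_equal(length(m0$reactions), length(m$reactions))
  # positive depletion adds the extra first-order PIP2 sink
  st1 <- apply_threshold_perturbation(
    st, sten_perturbation("pip2_depletion", 0.5))
  m1 <- build_sten_model(st1, ga2_coupling = FALSE, rr_const = 0.02)
  expect_equal(length(m1$reactions), length(m$reactions) + 1)
  # attenuation scales the PKBs activation rate
  st2 <- apply_threshold_perturbation(
    st, sten_perturbation("pkbs_attenuation", 0.5))
  m2 <- build_sten_model(st2, ga2_coupling = FALSE, rr_const = 0.02)
  k2 <- Filter(function(r) r$name == "pkb_act", m2$reactions)[[1]]$k
  expect_equal(k2, 0.5 * st$c2)
  expect_error(apply_threshold_perturbation(st, list(kind = "nope")),
               "unknown perturbation")
  expect_error(sten_perturbation("basal_apical_asymmetry", 1))
})

test_that("PIP2 depletion raises time-averaged RasGTP (matched seeds)", {
  s <- 0.05
  gp <- gpcr_params(scale = s, n_total_sd = 0)
  lg <- suppressWarnings(legi_params(scale = s, D_I = 0.05,
          inhibitor_localization = "membrane", volume_ratio = 1))
  st <- sten_params(scale = s)
  stp <- apply_threshold_perturbation(
    st, sten_perturbation("pip2_depletion", st$b2))
  mesh <- coarse_mesh()
  run_mean_rt <- function(sten, seed) {
    mod <- build_signaling_model(gp, lg, sten)
    init <- equilibrate_state(mod, mesh, gp, lg, sten, seed = seed,
                              fresh_receptors = TRUE)
    tr <- simulate_nsm(mod, mesh, init, t_end = 60, seed = seed,
                       record = list(dt = 1))
    mean(wc_trace(tr, "RasGTP")[tr$times > 20])
  }
  seeds <- c(11, 12, 13)
  base <- vapply(seeds, function(s) run_mean_rt(st, s), 0)
  pert <- vapply(seeds, function(s) run_mean_rt(stp, s), 0)
  expect_true(all(pert > base))
})

test_that("RasGTP and PIP2 are mutually exclusive at a node", {
  s <- 0.1
  gp <- gpcr_params(scale = s, n_total_sd = 0)
  lg <- suppressWarnings(legi_params(scale = s, D_I = 0.05,
          inhibitor_localization = "membrane", volume_ratio = 1))
  st <- sten_params(scale = s)
  mesh <- coarse_mesh()
  mod <- build_signaling_model(gp, lg, st)
  init <- equilibrate_state(mod, mesh, gp, lg, st, seed = 2,
                            fresh_receptors = TRUE)
  tr <- simulate_nsm(mod, mesh, init, t_end = 90, seed = 31,
                     record = list(dt = 0.5, species = c("RasGTP", "PIP2")))
  mem <- nodes_of(mesh, "membrane")
  keep <- tr$times > 10
  rt <- as.vector(tr$node$RasGTP[mem, keep])
  p2 <- as.vector(tr$node$PIP2[mem, keep])
  hi_rt <- rt > stats::median(rt)
  frac <- mean(p2[hi_rt] <= stats::median(p2))
  expect_gt(frac, 0.6)
})
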