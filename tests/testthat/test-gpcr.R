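test_that("full receptor model has 10 species and 26 reactions", {
  mod <- build_gpcr_model(gpcr_params(), "full")
  expect_length(mod$species, 10)
  expect_length(mod$reactions, 26)
  expect_setequal(mod$species_names, gpcr_species_names("full"))
  # every reaction conserves the receptor pool (stoichiometry over receptor
  # species sums to zero; cAMP and phosphate are buffered externals)
  for (r in mod$reactions)
    expect_equal(sum(r$stoich[names(r$stoich) %in%
                                gpcr_species_names("full")]), 0)
  expect_error(build_gpcr_model(gpcr_params(), "weird"))
})

test_that("reduced variant is frozen at zero cAMP", {
  mod <- build_gpcr_model(gpcr_params(), "reduced")
  expect_length(mod$species, 2)
  g <- unit_voxel(8e-3)
  tr <- simulate_nsm(mod, g, c(R = 500), t_end = 20, seed = 1)
  expect_equal(unname(tr$final["R", 1]), 500L)
  expect_equal(unname(tr$final["RC", 1]), 0L)
})

test_that("dose response is monotone, zero at zero, saturating at 100%", {
  p <- gpcr_params()
  dr <- dose_response(p, c(0, 0.01, 0.1, 1, 10, 100))
  expect_equal(dr$RO[1], 0)
  expect_true(all(diff(dr$RO) > 0))
  expect_gt(dr$RO[6], 99)
  m <- dose_response_map(p)
  expect_error(m$inverse(100), "unreachable")
  # inverse map round-trips
  for (tg in c(4, 50, 99))
    expect_equal(m$ro(m$inverse(tg)), tg, tolerance = 1e-6)
})

test_that("single-site occupancy matches the closed form when only H binds", {
  # disable interconversion, phosphorylation and the other binding states:
  # occupancy must be C / (C + Kd) with Kd = k-H / kH
  p <- gpcr_params(kL = 0, kmL = 0, kS = 0, kmS = 0, kHL = 0, kmHL = 0,
                   kHLC = 0, kmHLC = 0, kHCP = 0, kmHCP = 0, kPHC = 0,
                   kmPHC = 0, kPH = 0, kmPH = 0, kLCP = 0, kmLCP = 0,
                   kPLC = 0, kmPLC = 0, kPL = 0, kmPL = 0, kPHL = 0,
                   kmPHL = 0, kPHLC = 0, kmPHLC = 0)
  m <- dose_response_map(p)
  Kd <- p$kmH / p$kH
  for (C in c(0.01, 0.06, 0.5, 5))
    expect_equal(m$ro(C), 100 * C / (C + Kd), tolerance = 1e-6)
})

test_that("receptor initialization hits totals and the zero-ligand null space", {
  p0 <- gpcr_params(n_total_sd = 0)
  g <- unit_voxel(8e-3)
  counts <- equilibrate_receptors(p0, g, seed = 1)
  expect_equal(sum(counts), 70000)
  # no occupied receptors without ligand
  expect_equal(sum(counts[gpcr_occupied_names(), ]), 0)
  # free-state proportions match the stationary vector of the zero-ligand
  # interconversion network, computed independently from the generator
  Q <- rdmecell:::receptor_generator(p0, 0)
  live <- c("H", "L", "PH", "PL")
  A <- rbind(t(Q[live, live]), 1)
  pi_oracle <- qr.solve(A, c(0, 0, 0, 0, 1))
  frac <- rowSums(counts)[live] / 70000
  expect_equal(unname(frac), unname(pi_oracle), tolerance = 0.02)
  # the disconnected slow state stays empty
  expect_equal(sum(counts["S", ]), 0)
  expect_error(equilibrate_receptors(p0, structure(list(
    nodal_volumes = 1, node_class = data.frame(
      region = factor("cortex", levels = c("membrane", "cortex")),
      side = factor("basal", levels = c("basal", "apical")))),
    class = "voxel_graph"), seed = 1), "membrane")
})

test_that("cell-to-cell parameter sampling is truncated Gaussian", {
  p <- gpcr_params()
  p0 <- p; p0$sd <- lapply(p0$sd, function(x) 0); p0$n_total_sd <- 0
  expect_equal(sample_cell_parameters(p0, seed = 1)$kH, p$kH)
  draws <- vapply(1:400, function(s)
    sample_cell_parameters(p, seed = s)$kH, 0)
  expect_true(all(draws >= 0))
  se <- p$sd$kH / sqrt(length(draws))
  expect_lt(abs(mean(draws) - p$kH), 4 * se + 0.1)
  # truncation biases kmS (sd/mean = 0.4) upward but never below zero
  dk <- vapply(1:200, function(s) sample_cell_parameters(p, seed = s)$kmS, 0)
  expect_true(all(dk >= 0))
})

test_that("receptor count is conserved to the integer under stimulation", {
  p <- gpcr_params(n_total_sd = 0, scale = 0.1)
  mesh <- coarse_mesh()
  mod <- build_gpcr_model(p, "full")
  init <- equilibrate_receptors(p, mesh, seed = 4)
  tr <- simulate_nsm(mod, mesh, init, t_end = 30, seed = 5,
                     stimulus = make_step_protocol(1.0, t_on = 5),
                     record = list(dt = 0.5))
  expect_true(all(colSums(tr$wc) == sum(init)))
})

test_that("saturating-step half-times separate phosphorylated and
           unphosphorylated kinetics", {
  ht <- gpcr_step_halftimes()
  # pooled phosphorylated states approach equilibrium slowly (the phosphate
  # default is calibrated to ~198 s); occupied-state redistribution is two
  # orders of magnitude faster
  expect_gt(ht$t_half_phospho, 150)
  expect_lt(ht$t_half_phospho, 250)
  expect_lt(ht$t_half_unphospho, 15)
  expect_gt(ht$t_half_phospho / ht$t_half_unphospho, 10)
})

test_that("copy-number scaling preserves per-receptor kinetics", {
  p1 <- gpcr_params(n_total_sd = 0)
  p2 <- gpcr_params(n_total_sd = 0, scale = 0.1)
  expect_equal(p2$n_total, 7000)
  expect_equal(dose_response_map(p1)$inverse(50),
               dose_response_map(p2)$inverse(50))
})
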