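test_that("field evaluation follows the definitions", {
  co <- rbind(c(0, 0, 0), c(1, 2, 0), c(100, 100, 100))
  p <- make_step_protocol(2.5, t_on = 1, t_off = 10)
  expect_equal(camp_at(p, co, 0.5), rep(0, 3))
  expect_equal(camp_at(p, co, 5), rep(2.5, 3))
  expect_equal(camp_at(p, co, 12), rep(0, 3))
  g <- gaussian_field(center = c(1, 2, 0), amplitude = 4, widths = 1.5)
  pg <- stimulus_protocol(list(list(t_start = 0, t_end = Inf, field = g)))
  v <- camp_at(pg, co, 1)
  expect_equal(v[2], 4)          # at the centre: the amplitude
  expect_lt(v[3], 1e-12)         # far away: zero
  expect_error(uniform_field(-1), ">= 0")
  expect_error(stimulus_protocol(list(
    list(t_start = 0, t_end = 5, field = uniform_field(1)),
    list(t_start = 3, t_end = 8, field = uniform_field(2)))), "overlap")
})

test_that("pulse trains use offset-to-onset delays", {
  p <- make_pulse_protocol(2, 1, n_pulses = 2, delay_s = 50, t_start = 10)
  s <- p$segments
  expect_length(s, 2)
  expect_equal(s[[1]]$t_start, 10); expect_equal(s[[1]]$t_end, 12)
  expect_equal(s[[2]]$t_start, 62)  # end of first (12) + delay (50)
  expect_error(make_pulse_protocol(0, 1), "duration")
  expect_error(make_pulse_protocol(2, 1, n_pulses = 2), "delay")
  # a zero-dose pulse is indistinguishable from no stimulus
  g1 <- voxel_chain(1)
  mod <- rd_model(species("A", D = 0),
                  reaction("bind", "first", k = 1, reactants = "A",
                           stoich = c(A = -1), camp = TRUE))
  tr <- simulate_nsm(mod, g1, c(A = 50), t_end = 10, seed = 2,
                     stimulus = make_pulse_protocol(2, 0, 1, t_start = 3))
  expect_equal(unname(tr$final["A", 1]), 50L)
})

test_that("the staircase maps receptor-occupancy stages to doses", {
  gp <- gpcr_params()
  d4 <- dose_response_map(gp)$inverse(4)
  p <- make_staircase_protocol(c(0, d4, 30), c(0, 120, 480, 720))
  co <- matrix(0, 1, 3)
  expect_equal(camp_at(p, co, 60), 0)
  expect_equal(camp_at(p, co, 300), d4)
  expect_equal(camp_at(p, co, 500), 30)
})

test_that("gradient calibration hits front/back occupancy targets", {
  gp <- gpcr_params()
  mesh <- coarse_mesh()
  f <- calibrate_gradient(80, 12, mesh, params = gp)
  expect_s3_class(f, "camp_field")
  dr <- dose_response_map(gp)
  R <- mesh$spec$radius
  front <- matrix(c(R, 0, 0), 1)
  back <- matrix(c(-R, 0, 0), 1)
  co <- rbind(front, back)
  doses <- rdmecell:::eval_field(f, co)
  expect_equal(dr$ro(doses[1]), 80, tolerance = 2)    # within 2% R.O.
  expect_equal(dr$ro(doses[2]), 12, tolerance = 2)
  # occupancy decreases monotonically along the basal diameter
  xs <- seq(R, -R, length.out = 21)
  dd <- rdmecell:::eval_field(f, cbind(xs, 0, 0))
  expect_true(all(diff(dd) < 0))
  # degenerate case: equal targets give a uniform saturating field
  fu <- calibrate_gradient(100, 100, mesh, params = gp)
  expect_equal(fu$kind, "uniform")
  expect_error(calibrate_gradient(50, 80, mesh, params = gp))
})

test_that("stimulus changepoints preserve engine exactness", {
  # a binding channel driven by a piecewise-constant dose reaches the
  # matching equilibria in both stages
  g1 <- voxel_chain(1, volumes = 8e-3)
  mod <- rd_model(
    species("Rf", D = 0), species("Rb", D = 0),
    reaction("on", "first", k = 2, reactants = "Rf",
             stoich = c(Rf = -1, Rb = +1), camp = TRUE),
    reaction("off", "first", k = 1, reactants = "Rb",
             stoich = c(Rb = -1, Rf = +1)))
  p <- make_staircase_protocol(c(0.25, 4), c(0, 150, 400))
  tr <- simulate_nsm(mod, g1, c(Rf = 4000), t_end = 400, seed = 6,
                     stimulus = p, record = list(dt = 0.5))
  rb <- wc_trace(tr, "Rb")
  occ1 <- mean(rb[tr$times > 50 & tr$times < 150]) / 4000
  occ2 <- mean(rb[tr$times > 250]) / 4000
  expect_equal(occ1, 0.5 / 1.5, tolerance = 0.05)
  expect_equal(occ2, 8 / 9, tolerance = 0.02)
})
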