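test_that("mesoscopic rate conversion follows the one-molecule concentration", {
  V <- 8.01e-3
  u <- one_molecule_uM(V)
  expect_equal(u, 1 / (602.214076 * V))
  # first-order rates are volume-invariant
  r1 <- reaction("r", "first", k = 1, reactants = "A", stoich = c(A = -1))
  expect_equal(mesoscopic_rate(r1, c(0.1, 1, 10)), rep(1, 3))
  # bimolecular: k [1/(uM s)] -> k * u(V) per pair
  r2 <- reaction("b", "second", k = 2.2, reactants = c("A", "B"),
                 stoich = c(A = -1))
  expect_equal(mesoscopic_rate(r2, V), 2.2 * u, tolerance = 1e-12)
  expect_equal(mesoscopic_rate(r2, V), 0.456, tolerance = 0.01)
  # zeroth order: r [uM/s] -> r / u(V) molecules/s
  r0 <- reaction("z", "zeroth", k = 48.1, stoich = c(A = 1))
  expect_equal(mesoscopic_rate(r0, V), 48.1 / u, tolerance = 1e-12)
  expect_equal(mesoscopic_rate(r0, V), 232, tolerance = 0.01)
  expect_error(mesoscopic_rate(list(type = "weird", k = 1), V),
               "unsupported")
})

test_that("birth-death process has Poisson stationary statistics", {
  mod <- birth_death_model(50)
  tr <- simulate_nsm(mod, unit_voxel(), c(A = 0), t_end = 2500, seed = 7,
                     record = list(dt = 0.25))
  x <- wc_trace(tr, "A")[tr$times > 100]
  expect_equal(mean(x), 50, tolerance = 0.05)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
})

test_that("pure diffusion on a symmetric 3-voxel chain equilibrates evenly", {
  g3 <- voxel_chain(3)
  mod <- rd_model(species("B", D = 1))
  init <- matrix(c(300L, 0L, 0L), 1, 3)
  tr <- simulate_nsm(mod, g3, init, t_end = 150, seed = 3,
                     record = list(dt = 1, species = "B"))
  occ <- rowMeans(tr$node$B[, tr$times > 50])
  chi2 <- sum((occ - 100)^2 / 100)
  expect_gt(pchisq(chi2, 2, lower.tail = FALSE), 0.01)
  expect_equal(sum(tr$final), 300)
})

test_that("NSM agrees with the direct-SSA oracle on a 2-voxel 2-species toy", {
  g2 <- voxel_chain(2)
  mod <- toy_ab_model()
  init <- matrix(as.integer(c(12, 0, 0, 5)), 2, 2)  # A=12 in v1, B=5 in v2
  nrep <- 800
  a_nsm <- vapply(seq_len(nrep), function(r) {
    tr <- simulate_nsm(mod, g2, init, t_end = 1, seed = 1000 + r,
                       record = list(times = 1))
    tr$final["A", 1]
  }, 0L)
  a_ssa <- vapply(seq_len(nrep), function(r) {
    tr <- simulate_direct_ssa(mod, g2, init, t_end = 1, seed = 5000 + r,
                              record = list(times = 1))
    tr$final["A", 1]
  }, 0L)
  expect_lt(ks_distance(a_nsm, a_ssa), 0.08)
  expect_equal(mean(a_nsm), mean(a_ssa), tolerance = 0.15)
})

test_that("zero propensities leave the state unchanged", {
  g <- unit_voxel()
  mod <- rd_model(species("A", D = 0),
                  reaction("r", "first", k = 0, reactants = "A",
                           stoich = c(A = -1)))
  tr <- simulate_direct_ssa(mod, g, c(A = 17), t_end = 5, seed = 1)
  expect_equal(unname(tr$final["A", 1]), 17L)
  tr2 <- simulate_nsm(mod, g, c(A = 17), t_end = 5, seed = 1)
  expect_equal(unname(tr2$final["A", 1]), 17L)
})

test_that("identical config and seed give bit-identical trajectories", {
  g2 <- voxel_chain(2)
  mod <- toy_ab_model()
  init <- matrix(as.integer(c(40, 3, 9, 25)), 2, 2)
  run <- function() simulate_nsm(mod, g2, init, t_end = 10, seed = 77,
                                 record = list(dt = 0.5,
                                               species = c("A", "B")))
  t1 <- run(); t2 <- run()
  expect_identical(t1$wc, t2$wc)
  expect_identical(t1$final, t2$final)
  expect_identical(t1$node, t2$node)
  # a different seed changes the path
  t3 <- simulate_nsm(mod, g2, init, t_end = 10, seed = 78,
                     record = list(dt = 0.5, species = c("A", "B")))
  expect_false(identical(t1$wc, t3$wc))
})

test_that("counts stay non-negative and conserved pools exact over a run", {
  g2 <- voxel_chain(2)
  mod <- toy_ab_model()
  init <- matrix(as.integer(c(30, 0, 0, 30)), 2, 2)
  tr <- simulate_nsm(mod, g2, init, t_end = 50, seed = 5,
                     record = list(dt = 0.1, species = c("A", "B")))
  expect_true(all(tr$wc >= 0))
  expect_true(all(colSums(tr$wc) == 60))
  expect_true(all(tr$node$A >= 0) && all(tr$node$B >= 0))
})

test_that("mean-field oracle reproduces first-order closed forms", {
  mod <- rd_model(species("A", D = 0), species("B", D = 0),
                  reaction("ab", "first", k = 0.3, reactants = "A",
                           stoich = c(A = -1, B = +1)))
  mf <- simulate_meanfield(mod, c(A = 1000), t_end = 20,
                           volumes = c(membrane = 1, all = 1), dt = 0.01)
  a <- mf[, "A"]
  expect_equal(a, a[1] * exp(-0.3 * mf[, "time"]), tolerance = 1e-3)
  expect_equal(half_time(mf[, "time"], a), log(2) / 0.3, tolerance = 5e-3)
})

test_that("mean-field matches the NSM whole-cell mean at high copy number", {
  g <- unit_voxel(5)
  mod <- birth_death_model(2000, volume = 5, decay = 0.5)
  nrep <- 10
  traces <- vapply(seq_len(nrep), function(r)
    wc_trace(simulate_nsm(mod, g, c(A = 0), t_end = 8, seed = 100 + r,
                          record = list(dt = 0.5)), "A"),
    numeric(17))
  mf <- simulate_meanfield(mod, c(A = 0), t_end = 8,
                           volumes = c(membrane = 5, all = 5),
                           times = seq(0, 8, 0.5))
  mf_counts <- mf[, "A"] * 602.214076 * 5
  m <- rowMeans(traces)
  se <- apply(traces, 1, sd) / sqrt(nrep)
  ok <- se > 0
  expect_true(all(abs(m[ok] - mf_counts[ok]) <= 3 * se[ok] + 1))
})

test_that("half_time handles ramps and decays", {
  expect_equal(half_time(0:10, seq(0, 1, 0.1)), 5)
  tt <- seq(0, 10, 0.01)
  expect_equal(half_time(tt, 100 * exp(-0.7 * tt), direction = "decay"),
               log(2) / 0.7, tolerance = 5e-3)
})
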