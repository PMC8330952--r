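test_that("mesh spec invariants are enforced", {
  expect_error(mesh_spec(shell_thickness = 6), "shell_thickness")
  expect_error(mesh_spec(h_min = 0.5, h_max = 0.3), "h_min")
  expect_error(mesh_spec(membrane_depth = 0.5), "membrane_depth")
  expect_error(mesh_spec(membrane_depth = 0), "membrane_depth")
})

test_that("default mesh matches the reference scale within tolerance bands", {
  m <- full_mesh()
  # node/element counts are mesher-dependent; assert the +-25% band around
  # the reference cell discretization (5,500 nodes / 16,469 tets)
  expect_gt(nrow(m$vertices), 5500 * 0.75)
  expect_lt(nrow(m$vertices), 5500 * 1.25)
  expect_gt(nrow(m$tets), 16469 * 0.75)
  expect_lt(nrow(m$tets), 16469 * 1.25)
  # mean dual volume ~ 8.0e-3 um^3 within +-20%
  expect_gt(mean(m$nodal_volumes), 8.0e-3 * 0.8)
  expect_lt(mean(m$nodal_volumes), 8.0e-3 * 1.2)
  # total volume within 10% of the closed-form shell volume
  va <- shell_volume_analytic(m$spec)
  expect_lt(abs(mesh_volume(m) - va) / va, 0.10)
})

test_that("dual volumes partition the mesh volume", {
  for (m in list(coarse_mesh(), full_mesh())) {
    v <- dual_volumes(m)
    expect_true(all(v > 0))
    expect_equal(sum(v), sum(abs(tet_volumes(m$vertices, m$tets))),
                 tolerance = 1e-9)
  }
})

test_that("a single regular tetrahedron gives V/4 per vertex", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  vol <- abs(tet_volumes(verts, matrix(1:4, 1)))
  dv <- rdmecell:::dual_volumes_impl(matrix(1:4, 1), vol, 4L)
  expect_equal(dv, rep(vol / 4, 4))
})

test_that("node classification follows depth and side rules", {
  m <- full_mesh()
  spec <- m$spec
  # synthetic points: 10 nm under the dome -> membrane/apical;
  # 150 nm deep -> cortex; on the basal plane -> basal
  verts <- rbind(c(0, 0, spec$radius - 0.010),
                 c(0, 0, spec$radius - 0.150),
                 c(1, 0, 0))
  cls <- rdmecell:::classify_nodes_impl(verts, spec)
  expect_equal(as.character(cls$region), c("membrane", "cortex", "membrane"))
  expect_equal(as.character(cls$side), c("apical", "apical", "basal"))

  # membrane and cortex nodal volumes are statistically comparable in
  # location: their means agree within a few percent and well within the
  # overall spread. (The extruded-layer mesher gives the two layers
  # slightly different distribution *shapes* -- see the methods vignette --
  # so distribution-identity tests are not asserted.)
  v <- m$nodal_volumes
  mem <- v[nodes_of(m, "membrane")]
  cx <- v[nodes_of(m, "cortex")]
  expect_lt(abs(mean(mem) - mean(cx)) / mean(v), 0.06)
  expect_lt(abs(mean(mem) - mean(cx)), 0.5 * stats::sd(v))
  expect_lt(abs(median(mem) - median(cx)) / median(v), 0.10)
})

test_that("jump rates scale with D and vanish at D = 0", {
  m <- coarse_mesh()
  op0 <- diffusion_jump_rates(m, 0)
  expect_true(all(op0$rate == 0))
  op1 <- diffusion_jump_rates(m, 1)
  op3 <- diffusion_jump_rates(m, 3)
  expect_equal(op3$rate, 3 * op1$rate)
  expect_true(all(op1$rate >= 0))
  expect_error(diffusion_jump_rates(m, -1), "non-negative")
})

test_that("jump construction satisfies detailed balance wrt nodal volumes", {
  m <- coarse_mesh()
  op <- diffusion_jump_rates(m, 1)
  Q <- jump_generator(op)
  # pi_i q_ij = pi_j q_ji with pi proportional to volumes
  v <- m$nodal_volumes
  F <- Matrix::Diagonal(x = v) %*% Q
  expect_lt(max(abs(F - Matrix::t(F))), 1e-8 * max(abs(F)))
  # generator rows sum to zero
  expect_lt(max(abs(Matrix::rowSums(Q))), 1e-10)
})

test_that("structured two-voxel pair reproduces the finite-volume hop rate", {
  # closed form D * A / (h * V) on the voxel-chain fixture
  g <- voxel_chain(2, volumes = c(2, 3), area = 1.5, h = 0.5)
  op <- diffusion_jump_rates(g, D = 4)
  # rate 1 -> 2: 4 * 1.5 / (0.5 * 2) = 6 ; rate 2 -> 1: 4 * 1.5/(0.5*3) = 4
  expect_equal(op$rate_sum, c(6, 4))
})

test_that("diffusion-only occupancy converges to the volume-weighted law", {
  m <- coarse_mesh()
  mod <- rd_model(species("T", D = 5, localization = "all"))
  n <- 20000
  tr <- simulate_nsm(mod, m, c(T = n), t_end = 30, seed = 42,
                     record = list(dt = 30, species = "T"))
  occ <- tr$final["T", ]
  expected <- n * m$nodal_volumes / sum(m$nodal_volumes)
  # chi-square against the stationary distribution (eigen-measure of the
  # jump chain equals the volume weights by detailed balance)
  keep <- expected > 5
  chi2 <- sum((occ[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("tracer mean-square displacement grows like 6 D t", {
  m <- full_mesh()
  D <- 0.5
  mod <- rd_model(species("T", D = D, localization = "all"))
  # release tracers at one apical node, far from boundaries of the node set
  start <- which.max(m$vertices[, 3])
  init <- matrix(0L, 1, nrow(m$vertices))
  init[1, start] <- 400L
  tt <- 0.4
  tr <- simulate_nsm(mod, m, init, t_end = tt, seed = 9,
                     record = list(dt = tt, species = "T"))
  d2 <- rowSums(sweep(m$vertices, 2, m$vertices[start, ])^2)
  msd <- sum(tr$final["T", ] * d2) / 400
  # the shell is quasi-2D at 200 nm thickness: radial equilibration is
  # immediate, so lateral spreading dominates; accept 4Dt..6Dt within 15%
  expect_gt(msd, 4 * D * tt * 0.85)
  expect_lt(msd, 6 * D * tt * 1.15)
})

test_that("node count grows monotonically under mesh refinement", {
  hs <- c(1.2, 0.8, 0.5)
  counts <- vapply(hs, function(h)
    nrow(build_shell_mesh(mesh_spec(h_min = h / 3, h_max = h))$vertices), 0)
  expect_true(all(diff(counts) > 0))
})
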