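test_that("noise statistics recover Poisson laws on synthetic counts", {
  set.seed(42)
  N <- 120; T <- 400
  X <- matrix(rpois(N * T, 10), N, T)
  traj <- structure(list(times = seq_len(T), node = list(A = X),
                         wc = matrix(colSums(X), 1,
                                     dimnames = list("A", NULL))),
                    class = "rd_trajectory")
  ns <- noise_stats(traj, "A")
  expect_equal(ns$mean_fano, 1, tolerance = 0.05)
  expect_equal(ns$mean_cov, 1 / sqrt(10), tolerance = 0.05)
  expect_equal(ns$internodal_fano_inst, 1, tolerance = 0.1)
  # a constant trace has zero variance and COV
  Xc <- matrix(7L, 10, 50)
  tc <- structure(list(times = 1:50, node = list(A = Xc)),
                  class = "rd_trajectory")
  nc <- noise_stats(tc, "A")
  expect_true(all(nc$var == 0))
  expect_equal(nc$mean_cov, 0)
})

test_that("refractory curve interpolates the 50% recovery delay", {
  pp <- data.frame(delay = rep(c(10, 30, 50, 70, 90), each = 2),
                   first = 100,
                   second = rep(c(1, 20, 48, 75, 95), each = 2),
                   basal_sd = 1)
  rc <- refractory_curve(pp)
  expect_equal(nrow(rc$curve), 5)
  # crossing between 30 (0.2) and 50 (0.48) and 70 (0.75): interpolated
  expect_gt(rc$recovery50, 50)
  expect_lt(rc$recovery50, 60)
  # a tiny second response counts as no distinct peak
  pp2 <- pp; pp2$second <- 2; pp2$basal_sd <- 0.5
  expect_equal(unique(refractory_curve(pp2)$curve$ratio), 0.02)
  pp3 <- pp; pp3$second <- 0.5
  expect_true(all(refractory_curve(pp3)$curve$ratio == 0))
})

test_that("wave detection is quiet on quiescent data and tracks a moving
           disk at the right speed", {
  mesh <- coarse_mesh()
  mem <- nodes_of(mesh, "membrane")
  N <- nrow(mesh$vertices)
  times <- seq(0, 40, 0.5)
  quiet <- structure(list(
    times = times,
    node = list(RasGTP = matrix(0L, N, length(times)),
                PIP2 = matrix(10L, N, length(times)))),
    class = "rd_trajectory")
  expect_equal(nrow(detect_waves(quiet, mesh)), 0)

  # synthetic disk of activity moving along the basal diameter at 0.1 um/s
  speed <- 0.1
  ras <- matrix(0L, N, length(times))
  pip <- matrix(10L, N, length(times))
  for (i in seq_along(times)) {
    cx <- -2 + speed * times[i]
    inside <- abs(mesh$vertices[, 1] - cx) < 0.9 &
      mesh$vertices[, 3] < 0.4 & abs(mesh$vertices[, 2]) < 1.2
    inside[-mem] <- FALSE
    ras[inside, i] <- 30L
    pip[inside, i] <- 0L
  }
  mv <- structure(list(times = times,
                       node = list(RasGTP = ras, PIP2 = pip)),
                  class = "rd_trajectory")
  ev <- detect_waves(mv, mesh)
  expect_equal(sum(ev$kind == "initiation"), 1)
  expect_equal(ev$side[ev$kind == "initiation"], "basal")
  # node discreteness makes per-frame displacements jumpy; their mean is
  # total displacement over total time
  sp <- mean(ev$speed[ev$kind == "front"], na.rm = TRUE)
  expect_equal(sp, speed, tolerance = 0.1)
  # cadence check
  coarse_t <- structure(list(times = c(0, 5, 10),
                             node = list(RasGTP = ras[, 1:3],
                                         PIP2 = pip[, 1:3])),
                        class = "rd_trajectory")
  expect_error(detect_waves(coarse_t, mesh), "cadence")
})

test_that("two seeded counter-propagating fronts merge exactly once and
           never cross", {
  # deterministic geometric fixture: two arcs closing on each other along
  # the basal ring; on collision they merge (annihilation check) and no
  # active region persists past the collision locus
  mesh <- coarse_mesh()
  mem <- nodes_of(mesh, "membrane")
  N <- nrow(mesh$vertices)
  ang <- node_angles(mesh)   # 0..180 from +x
  times <- seq(0, 30, 0.5)
  ras <- matrix(0L, N, length(times)); pip <- matrix(10L, N, length(times))
  for (i in seq_along(times)) {
    lead <- 6 * times[i]     # degrees per second toward 90
    a_front <- ang >= 0 & ang <= pmin(lead, 88)
    b_front <- ang <= 180 & ang >= pmax(180 - lead, 92)
    on <- (a_front | b_front) &
      (abs(lead - ang) < 15 | abs(ang - (180 - lead)) < 15)
    if (lead >= 95) on[] <- FALSE   # mutual annihilation: both fronts die
    on[-mem] <- FALSE
    ras[on, i] <- 25L; pip[on, i] <- 0L
  }
  tr <- structure(list(times = times,
                       node = list(RasGTP = ras, PIP2 = pip)),
                  class = "rd_trajectory")
  ev <- detect_waves(tr, mesh)
  expect_gte(sum(ev$kind == "annihilation"), 1)
  # no active nodes beyond the collision time
  post <- times > 17
  expect_true(all(ras[, post] == 0))
})

test_that("kymographs bin the arc and use maximal projection", {
  mesh <- coarse_mesh()
  N <- nrow(mesh$vertices)
  times <- 0:5
  X <- matrix(0L, N, length(times))
  ang <- node_angles(mesh)
  X[ang < 20, ] <- 7L
  tr <- structure(list(times = times, node = list(S = X)),
                  class = "rd_trajectory")
  ky <- kymograph(tr, mesh, "S", bin_deg = 10)
  expect_equal(dim(ky), c(18, length(times)))
  expect_true(all(ky[1:2, ] == 7))
  expect_true(all(ky[5:18, ] == 0, na.rm = TRUE))
})

test_that("front-back profiles are symmetric under uniform conditions", {
  mesh <- coarse_mesh()
  N <- nrow(mesh$vertices)
  set.seed(1)
  times <- 1:30
  X <- matrix(rpois(N * 30, 6), N)
  tr <- structure(list(times = times, node = list(S = X)),
                  class = "rd_trajectory")
  fb <- front_back_profiles(tr, mesh, "S")
  expect_lt(abs(mean(fb$difference)), 0.5)
  expect_equal(length(fb$angle), 36)
})
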