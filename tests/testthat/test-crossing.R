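test_that("joint moments match the nested-information correlation structure", {
  m1 <- joint_moments(info_schedule(4), theta = 0)
  expect_equal(m1$mean, 0)
  expect_equal(m1$cov, matrix(1, 1, 1))

  m2 <- joint_moments(info_schedule(c(2, 4)), theta = 0)
  expect_equal(m2$cov[1, 2], sqrt(2 / 4), tolerance = 1e-12)
  expect_equal(m2$cov, t(m2$cov))

  m5 <- joint_moments(sched5(), theta = 1)
  expect_equal(m5$mean, sqrt(c(2, 4, 6, 8, 10)), tolerance = 1e-12)
  expect_true(all(eigen(m5$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("invalid schedules and mismatched boundaries are rejected", {
  expect_error(info_schedule(c(2, 2, 4)), class = "seqbayes_error_invalid_schedule")
  expect_error(info_schedule(c(3, 1)), class = "seqbayes_error_invalid_schedule")
  expect_error(info_schedule(c(-1, 2)), class = "seqbayes_error_invalid_schedule")
  expect_error(crossing_probabilities(sched5(), c(2, 2)),
               class = "seqbayes_error_dimension")
  expect_error(crossing_probabilities(sched5(), c(2, 2, 2, 2, -Inf)),
               class = "seqbayes_error_input")
})

test_that("single-look crossing reduces to the normal tail", {
  for (u in c(-1, 0, 1.95996, 3)) {
    for (theta in c(0, 0.7)) {
      cr <- crossing_probabilities(info_schedule(4), u, theta)
      expect_equal(cr$cumulative, pnorm(u - theta * 2, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("five-look constant boundary reproduces the tabulated spending", {
  # at the 2-dp boundary 2.41 the spend matches the tabulated vector to the
  # resolution the boundary rounding permits; at the exactly calibrated
  # constant it matches to one unit in the fourth decimal
  cr <- crossing_probabilities(sched5(), rep(2.41, 5), theta = 0)
  expect_lte(max(abs(cr$cumulative -
                       c(0.0079, 0.0138, 0.0183, 0.0219, 0.0250))), 2.5e-4)
  c_exact <- pocock_design(sched5(), 0.025)$bounds
  cr2 <- crossing_probabilities(sched5(), c_exact, theta = 0)
  expect_lte(max(abs(cr2$cumulative -
                       c(0.0079, 0.0138, 0.0183, 0.0219, 0.0250))), 1.05e-4)
})

test_that("recursion agrees with multivariate-normal rectangle probabilities", {
  set.seed(11)
  for (i in 1:20) {
    cfg <- random_config()
    a <- crossing_probabilities(cfg$schedule, cfg$bounds, cfg$theta)
    b <- crossing_probabilities(cfg$schedule, cfg$bounds, cfg$theta,
                                method = "mvnorm")
    expect_equal(a$cumulative, b$cumulative, tolerance = 1e-6)
  }
})

test_that("per-look probabilities sum to the cumulative and stay in range", {
  set.seed(21)
  for (i in 1:10) {
    cfg <- random_config()
    cr <- crossing_probabilities(cfg$schedule, cfg$bounds, cfg$theta)
    expect_equal(cr$cumulative, cumsum(cr$per_look), tolerance = 1e-12)
    expect_true(all(cr$per_look >= 0 & cr$per_look <= 1))
    expect_true(all(diff(cr$cumulative) >= 0))
    expect_lte(max(cr$cumulative), 1)
  }
})

test_that("crossing probability is monotone in drift and in boundaries", {
  bounds <- c(2.5, 2.3, 2.1)
  sched <- info_schedule(c(1, 2, 3))
  overall <- vapply(seq(-1, 2, by = 0.25), function(th) {
    crossing_probabilities(sched, bounds, th)$cumulative[3]
  }, numeric(1))
  expect_true(all(diff(overall) > 0))

  base <- crossing_probabilities(sched, bounds, 0.3)$cumulative[3]
  for (k in 1:3) {
    raised <- bounds
    raised[k] <- raised[k] + 0.4
    expect_lte(crossing_probabilities(sched, raised, 0.3)$cumulative[3], base)
  }
})

test_that("an infinite boundary spends nothing and passes the density on", {
  sched <- info_schedule(c(1, 2, 3))
  cr <- crossing_probabilities(sched, c(2, Inf, 2), theta = 0)
  expect_equal(cr$per_look[2], 0)
  # skipping look 2 entirely must match the two-look design on looks 1 and 3
  cr13 <- crossing_probabilities(info_schedule(c(1, 3)), c(2, 2), theta = 0)
  expect_equal(cr$cumulative[3], cr13$cumulative[2], tolerance = 1e-9)
})

test_that("quadrature is converged at the default node count", {
  cfg <- list(schedule = sched5(), bounds = c(4.56, 3.23, 2.63, 2.28, 2.04))
  a <- crossing_probabilities(cfg$schedule, cfg$bounds, 0, nodes = 601)
  b <- crossing_probabilities(cfg$schedule, cfg$bounds, 0, nodes = 1201)
  expect_lt(max(abs(a$cumulative - b$cumulative)), 1e-7)
})

test_that("numerical crossing agrees with the path-simulation oracle", {
  # the K = 3 derived case and a batch of randomized configurations
  cr <- crossing_probabilities(info_schedule(c(1, 2, 3)), rep(2, 3), 0.5)
  sim <- simulate_paths(info_schedule(c(1, 2, 3)), rep(2, 3), 0.5,
                        n_paths = 200000, seed = 123)
  expect_within_3se(cr$cumulative[3], sim$cumulative[3], sim$se[3])

  set.seed(31)
  cfgs <- replicate(5, random_config(), simplify = FALSE)
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    cr <- crossing_probabilities(cfg$schedule, cfg$bounds, cfg$theta)
    sim <- simulate_paths(cfg$schedule, cfg$bounds, cfg$theta,
                          n_paths = 50000, seed = 1000 + i)
    expect_within_3se(cr$cumulative, sim$cumulative, sim$se)
  }
})

test_that("path simulation is reproducible and respects edge cases", {
  s1 <- simulate_paths(sched5(), rep(2.41, 5), 0, 5000, seed = 9)
  s2 <- simulate_paths(sched5(), rep(2.41, 5), 0, 5000, seed = 9)
  expect_identical(s1, s2)
  expect_error(simulate_paths(sched5(), rep(2.41, 5), 0, 10, seed = 1),
               class = "seqbayes_error_input")
  big <- simulate_paths(info_schedule(2), 1.96, theta = 10, 2000, seed = 2)
  expect_equal(big$cumulative[1], 1)
})

test_that("boundary solver hits cumulative targets recursively", {
  # first look is the plain normal quantile
  expect_equal(solve_boundary_at_look(sched5(), numeric(0), 0.025),
               qnorm(0.975), tolerance = 1e-8)
  # recursive application reproduces the linear-spending boundary table
  targets <- c(0.005, 0.010, 0.015, 0.020, 0.025)
  b <- numeric(0)
  for (k in 1:5) b <- c(b, solve_boundary_at_look(sched5(), b, targets[k]))
  expect_equal(round(b, 2), c(2.58, 2.49, 2.41, 2.34, 2.28))
  cr <- crossing_probabilities(sched5(), b, 0)
  expect_equal(cr$cumulative, targets, tolerance = 1e-7)
})

test_that("boundary solver handles zero and infeasible increments", {
  # no incremental spend allowed: sentinel
  u1 <- solve_boundary_at_look(sched5(), numeric(0), 0.01)
  expect_identical(solve_boundary_at_look(sched5(), u1, 0.01), Inf)
  # target below already-spent alpha
  expect_error(solve_boundary_at_look(sched5(), u1, 0.001),
               class = "seqbayes_error_infeasible")
  expect_error(solve_boundary_at_look(sched5(), numeric(0), 1),
               class = "seqbayes_error_input")
})
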