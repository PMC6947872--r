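# Reference configuration: five equally sized stages per arm with difference-
# scale information 2, 4, ..., 10, hence per-arm information 4, 8, ..., 20;
# informative control prior (mu00 = 0, I00 = 0.5), flat experimental prior.
ctrl_prior_pair <- function() group_prior_pair(mu00 = 0, info00 = 0.5,
                                          mu10 = 0, info10 = 0)
equal_arm_sched <- function() two_arm_schedule(seq(4, 20, by = 4), seq(4, 20, by = 4))

test_that("independent-prior posterior for the difference is exact", {
  flat <- posterior_theta_two_prior(group_prior_pair(), 0.2, 0.9, 4, 5)
  expect_equal(flat$mean, 0.7)
  expect_equal(flat$precision, 1 / (1 / 5 + 1 / 4), tolerance = 1e-12)

  sym <- posterior_theta_two_prior(ctrl_prior_pair(), 0, 0, 4, 4)
  expect_equal(sym$mean, 0)

  hand <- posterior_theta_two_prior(group_prior_pair(1, 1, 0, 0), 0, 0, 1, 1)
  expect_equal(hand$mean, -0.5)
  expect_equal(1 / hand$precision, 1.5, tolerance = 1e-12)

  expect_error(posterior_theta_two_prior(ctrl_prior_pair(), 0, 0, 0, 4),
               class = "seqbayes_error_input")
})

test_that("independent priors never lose posterior precision", {
  eq <- precision_compare(group_prior_pair(0, 1, 0, 1), 2, 2)
  expect_equal(eq$ratio, 1, tolerance = 1e-12)
  expect_equal(eq$lambda, 1)

  lt <- precision_compare(group_prior_pair(0, 1, 0, 1), 1, 4)
  expect_equal(lt$lambda, 4)
  expect_lt(lt$ratio, 1)

  set.seed(53)
  for (i in 1:1000) {
    pr <- group_prior_pair(0, runif(1, 0.05, 5), 0, runif(1, 0.05, 5))
    i0 <- runif(1, 0.1, 20)
    i1 <- runif(1, 0.1, 20)
    cmp <- precision_compare(pr, i0, i1)
    expect_lte(cmp$ratio, 1 + 1e-10)
    if (abs(cmp$lambda - 1) < 1e-12) {
      expect_equal(cmp$ratio, 1, tolerance = 1e-10)
    } else {
      expect_lt(cmp$ratio, 1)
    }
  }

  # flat arm: collapsed prior information is zero, ratio still <= 1
  fl <- precision_compare(group_prior_pair(0, 0, 0, 2), 3, 3)
  expect_true(is.na(fl$lambda))
  expect_lte(fl$ratio, 1)
})

test_that("the M-statistic law has the derived mean, covariance, thresholds", {
  law0 <- m_statistic_law(group_prior_pair(), equal_arm_sched(), 0, 0, 0.99)
  expect_equal(law0$mean, rep(0, 5))
  law_ex <- m_statistic_law(ctrl_prior_pair(), equal_arm_sched(), 0, 0, 0.9884)
  expect_equal(law_ex$mean, rep(0, 5))
  expect_true(all(eigen(law_ex$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(law_ex$precision,
               1 / (1 / seq(4, 20, 4) + 1 / (0.5 + seq(4, 20, 4))),
               tolerance = 1e-12)
  expect_equal(law_ex$thresholds, qnorm(0.9884) / sqrt(law_ex$precision),
               tolerance = 1e-12)

  # with a common true mean the mean of M_k picks up the prior-shrinkage gap
  law1 <- m_statistic_law(ctrl_prior_pair(), equal_arm_sched(), 1, 1, 0.99)
  gap <- 1 - seq(4, 20, 4) / (0.5 + seq(4, 20, 4))
  expect_equal(law1$mean, gap, tolerance = 1e-12)
  expect_true(all(law1$mean > 0) && all(diff(law1$mean) < 0))
  # unbounded drift as the common mean grows
  far <- m_statistic_law(ctrl_prior_pair(), equal_arm_sched(), 1e3, 1e3, 0.99)
  expect_gt(far$mean[5], 20)
})

test_that("proportionality detects when the design collapses to one parameter", {
  expect_true(all(proportionality_check(group_prior_pair(0, 1, 0, 1),
                                        two_arm_schedule(1:4, 1:4))))
  expect_false(any(proportionality_check(ctrl_prior_pair(), equal_arm_sched())))
  expect_true(all(proportionality_check(group_prior_pair(0, 1, 0, 2),
                                        two_arm_schedule(1:4, 2 * (1:4)))))
})

test_that("two-arm calibration controls the error at the reference mean only", {
  p <- find_common_p_two_param(ctrl_prior_pair(), equal_arm_sched(), 0.025, mu0_ref = 0)
  prof <- type1_profile(ctrl_prior_pair(), equal_arm_sched(), p,
                        mu0_grid = c(0, 0.5, 1, 2, 3))
  expect_equal(prof$type1[1], 0.025, tolerance = 1e-6)
  expect_true(all(diff(prof$type1) > 0))
  expect_true(all(prof$type1[-1] > 0.025))
  expect_s3_class(autoplot(prof, alpha = 0.025), "ggplot")

  # flat priors: the profile does not depend on the control mean
  p_flat <- find_common_p_two_param(group_prior_pair(), equal_arm_sched(), 0.025)
  prof_flat <- type1_profile(group_prior_pair(), equal_arm_sched(), p_flat,
                             mu0_grid = c(-1, 0, 2))
  expect_lt(diff(range(prof_flat$type1)), 1e-8)
})

test_that("proportional designs reduce to the one-parameter calibration", {
  # flat priors reduce to the non-informative one-parameter design
  p2 <- find_common_p_two_param(group_prior_pair(), equal_arm_sched(), 0.025)
  p1 <- find_common_p(normal_prior(0, 0), sched5(), 0.025)
  expect_equal(p2, p1, tolerance = 1e-5)

  # informative proportional case: collapsed prior (theta0 = 0, I0)
  pr <- group_prior_pair(0, 1, 0, 1)
  sc <- two_arm_schedule(seq(4, 20, 4), seq(4, 20, 4))
  expect_true(all(proportionality_check(pr, sc)))
  p2i <- find_common_p_two_param(pr, sc, 0.025)
  p1i <- find_common_p(normal_prior(0, 0.5), sched5(), 0.025)
  expect_equal(p2i, p1i, tolerance = 1e-5)
})

test_that("the analytic law agrees with simulated two-arm trials", {
  p <- 0.9884
  for (mu0 in c(0, 1)) {
    exact <- seqbayes:::two_arm_stop_prob(ctrl_prior_pair(), equal_arm_sched(), mu0, mu0, p)
    sim <- simulate_two_arm_paths(ctrl_prior_pair(), equal_arm_sched(), mu0, mu0, p,
                                  n_paths = 200000, seed = 60 + mu0)
    expect_within_3se(exact, sim$cumulative[5], sim$se[5])
  }
})
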