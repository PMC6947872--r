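test_that("conjugate posterior updates are exact", {
  flat <- posterior_normal(normal_prior(0, 0), ybar = 1.2, info_k = 4)
  expect_equal(flat$mean, 1.2)
  expect_equal(flat$precision, 4)

  inf <- posterior_normal(normal_prior(-0.25, 20), ybar = 0, info_k = 2)
  expect_equal(inf$mean, -5 / 22, tolerance = 1e-12)
  expect_equal(inf$precision, 22)

  agree <- posterior_normal(normal_prior(0.5, 1), ybar = 0.5, info_k = 9)
  expect_equal(agree$mean, 0.5)
  expect_equal(agree$precision, 10)

  expect_error(posterior_normal(normal_prior(0, 0), 1, 0),
               class = "seqbayes_error_input")
  expect_error(normal_prior(0, -1), class = "seqbayes_error_input")
})

test_that("posterior probability of benefit behaves and matches the table", {
  expect_equal(posterior_prob_positive(normal_prior(0, 5), 0, 2), 0.5)
  expect_equal(posterior_prob_positive(normal_prior(0, 0), 1.96 / 2, 4),
               pnorm(1.96), tolerance = 1e-12)
  # informative negative prior at its tabulated boundary point
  expect_equal(posterior_prob_positive(normal_prior(-0.25, 20), 4.43 / sqrt(2), 2),
               0.6063, tolerance = 1e-4)
  # strictly increasing in the observed mean
  ys <- seq(-2, 2, by = 0.5)
  ps <- posterior_prob_positive(normal_prior(0.3, 2), ys, 5)
  expect_true(all(diff(ps) > 0))
  # shifted-target variant is a pure location shift
  expect_equal(posterior_prob_positive(normal_prior(0, 0), 1.2, 4, delta = 0.5),
               pnorm((1.2 - 0.5) * 2), tolerance = 1e-12)
})

test_that("posterior thresholds map to standardized boundaries and back", {
  s5 <- sched5()
  expect_equal(bayes_boundaries(normal_prior(0, 0), 0.9921, s5),
               rep(qnorm(0.9921), 5), tolerance = 1e-12)
  expect_equal(round(bayes_boundaries(normal_prior(-0.25, 20), 0.6063, s5), 2),
               c(4.43, 3.16, 2.60, 2.27, 2.05))
  # printed boundaries correspond to the fully calibrated threshold, so the
  # 4-dp threshold reproduces them to the precision its own rounding permits
  expect_lte(max(abs(bayes_boundaries(normal_prior(0, 1), 0.9856, s5) -
                       c(2.68, 2.45, 2.36, 2.32, 2.29))), 8e-3)
  expect_error(bayes_boundaries(normal_prior(0, 0), 1, s5),
               class = "seqbayes_error_input")

  expect_equal(p_from_frequentist(normal_prior(0, 0), rep(2.41, 5), s5),
               rep(pnorm(2.41), 5), tolerance = 1e-12)
  expect_equal(p_from_frequentist(normal_prior(0, 0), rep(0, 5), s5),
               rep(0.5, 5))
  # round trip identity on random priors and boundaries
  set.seed(41)
  for (i in 1:10) {
    pr <- normal_prior(runif(1, -1, 1), runif(1, 0, 5))
    u <- runif(5, -1, 3)
    p <- p_from_frequentist(pr, u, s5)
    expect_equal(bayes_boundaries(pr, p, s5), u, tolerance = 1e-10)
  }
})

test_that("alpha spent by Bayesian designs matches the tabulated rows", {
  s5 <- sched5()
  a1 <- bayes_alpha_spent(normal_prior(-0.25, 20), 0.6063, s5)
  expect_equal(round(a1, 4), c(0.0000, 0.0008, 0.0049, 0.0133, 0.0250))
  a2 <- bayes_alpha_spent(normal_prior(0, 0.5), 0.9888, s5)
  expect_lte(max(abs(a2 - c(0.0053, 0.0114, 0.0167, 0.0212, 0.0250))), 1.1e-4)
  pr <- normal_prior(0.2, 3)
  expect_equal(bayes_alpha_spent(pr, 0.98, info_schedule(6)),
               pnorm(bayes_boundaries(pr, 0.98, info_schedule(6)),
                     lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("common-threshold calibration hits the target type I error", {
  s5 <- sched5()
  cases <- list(list(prior = normal_prior(0, 0), p = 0.9921),
                list(prior = normal_prior(-0.25, 20), p = 0.6063),
                list(prior = normal_prior(0.25, 1), p = 0.9889))
  for (cs in cases) {
    p <- find_common_p(cs$prior, s5, 0.025)
    expect_equal(p, cs$p, tolerance = 1.05e-4)
    expect_equal(bayes_alpha_spent(cs$prior, p, s5)[5], 0.025,
                 tolerance = 1e-6)
  }
  # informative negative prior makes early stopping almost impossible
  expect_lt(bayes_alpha_spent(normal_prior(-0.25, 20), 0.6063, s5)[1], 1e-4)
})

test_that("Bayesian and frequentist designs are two views of one rule", {
  s5 <- sched5()
  # equivalence: spending vector of a Bayesian design rebuilds its boundaries
  pr <- normal_prior(0.25, 1)
  p <- find_common_p(pr, s5, 0.025)
  spent <- bayes_alpha_spent(pr, p, s5)
  rebuilt <- design_from_spending(
    s5, spending_function("custom_vector", 0.025, values = spent))
  expect_equal(rebuilt$bounds, bayes_boundaries(pr, p, s5), tolerance = 1e-6)

  # non-informative common-p design is the Pocock design
  flat_p <- find_common_p(normal_prior(0, 0), s5, 0.025)
  poc <- pocock_design(s5, 0.025)
  expect_equal(bayes_boundaries(normal_prior(0, 0), flat_p, s5),
               poc$bounds, tolerance = 1e-6)
  expect_equal(flat_p, pnorm(poc$bounds[1]), tolerance = 1e-8)

  # thresholds loosen monotonically toward the non-informative limit
  ps <- vapply(list(normal_prior(-0.25, 20), normal_prior(-0.25, 1),
                    normal_prior(0, 1), normal_prior(0, 0.5),
                    normal_prior(0, 0)),
               find_common_p, numeric(1), sched5(), 0.025)
  expect_true(all(diff(ps) > 0))
})

test_that("bayes_design assembles a coherent report", {
  d <- bayes_design(normal_prior(0, 0.5), sched5(), alpha = 0.025)
  expect_s3_class(d, "bayes_design")
  expect_equal(d$alpha_spent[5], 0.025, tolerance = 1e-6)
  expect_equal(bayes_boundaries(d$prior, d$p, d$schedule), d$bounds)
  td <- tidy(d)
  expect_true("p" %in% names(td))
  expect_error(bayes_design(normal_prior(0, 0), sched5()),
               class = "seqbayes_error_input")
  expect_error(bayes_design(normal_prior(0, 0), sched5(), p = 0.99,
                            alpha = 0.025),
               class = "seqbayes_error_input")
})
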