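# shared fixtures: the canonical five-look schedule with I_k = 2k and the
# four-look binomial schedule, plus a generator of random valid
# (schedule, bounds, theta) configurations for property tests

sched5 <- function() info_schedule(c(2, 4, 6, 8, 10))

binom4 <- function() binom_schedule(c(25, 50, 75, 100), pi0 = 0.5)

random_config <- function() {
  K <- sample(2:5, 1)
  info <- cumsum(runif(K, 0.5, 3))
  bounds <- sort(runif(K, 1, 3.5), decreasing = sample(c(TRUE, FALSE), 1))
  theta <- runif(1, -0.5, 1)
  list(schedule = info_schedule(info), bounds = bounds, theta = theta)
}

expect_within_3se <- function(exact, sim_cum, sim_se) {
  slack <- pmax(3 * sim_se, 1e-12)
  expect_true(all(abs(exact - sim_cum) <= slack),
              label = sprintf("max |exact - sim| = %.3g vs 3*SE = %.3g",
                              max(abs(exact - sim_cum)), min(slack)))
}
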