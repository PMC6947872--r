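#' Joint distribution of the standardized sequential statistics
#'
#' The cumulative means \eqn{\bar Y_1, \dots, \bar Y_K} observed at the looks
#' of a group-sequential trial are multivariate normal with
#' \eqn{E(\bar Y_k) = \theta} and \eqn{cov(\bar Y_k, \bar Y_{k'}) = 1/I_{k'}}
#' for \eqn{k < k'}. The standardized statistics
#' \eqn{Z_k = \bar Y_k \sqrt{I_k}} therefore have mean \eqn{\theta\sqrt{I_k}},
#' unit variance and correlation \eqn{\sqrt{I_k/I_{k'}}} (\eqn{k < k'}).
#'
#' @param schedule An [info_schedule()] (or a numeric information vector).
#' @param theta True drift (effect size) at which moments are evaluated.
#'
#' @return A list with `mean` (length-K vector) and `cov` (K x K correlation
#'   matrix of the standardized statistics).
#' @examples
#' joint_moments(info_schedule(c(2, 4)), theta = 0)
#' @export
joint_moments <- function(schedule, theta = 0) {
  sched <- as_info_schedule(schedule)
  check_scalar_num(theta, "theta")
  si <- sqrt(sched$info)
  cov <- outer(si, si, function(a, b) pmin(a, b) / pmax(a, b))
  list(mean = theta * si, cov = cov)
}

## quadrature state for the Armitage-type forward recursion --------------
##
## The continuing (not-yet-stopped) statistic at look k has a sub-density on
## the Z_k scale, truncated above at u_k. We track it on a uniform grid with
## composite Simpson weights; transitions use the independent-increments
## representation W_k = Z_k * sqrt(I_k), with
## W_k - W_{k-1} ~ N(theta * (I_k - I_{k-1}), I_k - I_{k-1}).

GRID_HALFWIDTH <- 8

simpson_weights <- function(n, h) {
  # n odd; composite Simpson's rule on a uniform grid with spacing h
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

make_node_count <- function(nodes) {
  nodes <- as.integer(nodes)
  if (nodes < 301L) nodes <- 301L
  if (nodes %% 2L == 0L) nodes <- nodes + 1L
  nodes
}

# Continuing sub-densities through look `k_max` (default K). Element k is
# NULL when no continuation region exists (boundary at or below grid floor,
# or all mass already stopped).
gs_states <- function(info, upper, theta, nodes, k_max = length(info)) {
  si <- sqrt(info)
  states <- vector("list", k_max)
  per_look <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lo <- theta * si[k] - GRID_HALFWIDTH
    hi <- min(upper[k], theta * si[k] + GRID_HALFWIDTH)
    if (k == 1L) {
      per_look[1L] <- pnorm(upper[1L] - theta * si[1L], lower.tail = FALSE)
      if (hi <= lo) {
        states[k] <- list(NULL)
        next
      }
      z <- seq(lo, hi, length.out = nodes)
      states[[k]] <- list(z = z,
                          h = dnorm(z - theta * si[1L]),
                          w = simpson_weights(nodes, z[2L] - z[1L]))
    } else {
      prev <- states[[k - 1L]]
      if (is.null(prev)) {
        states[k] <- list(NULL)
        next
      }
      delta <- info[k] - info[k - 1L]
      sd <- sqrt(delta)
      wh <- prev$w * prev$h
      m <- prev$z * si[k - 1L] + theta * delta   # conditional mean of W_k
      per_look[k] <- sum(wh * pnorm((upper[k] * si[k] - m) / sd,
                                    lower.tail = FALSE))
      if (hi <= lo) {
        states[k] <- list(NULL)
        next
      }
      z <- seq(lo, hi, length.out = nodes)
      kern <- dnorm((outer(z * si[k], m, "-")) / sd)
      states[[k]] <- list(z = z,
                          h = as.vector(kern %*% wh) * si[k] / sd,
                          w = simpson_weights(nodes, z[2L] - z[1L]))
    }
  }
  list(states = states, per_look = per_look)
}

# incremental crossing probability at look k given the continuing state at
# look k-1 (prev = NULL handles k = 1)
gs_increment <- function(prev, info, theta, k, u_k) {
  si <- sqrt(info)
  if (k == 1L) {
    return(pnorm(u_k - theta * si[1L], lower.tail = FALSE))
  }
  if (is.null(prev)) {
    return(0)
  }
  delta <- info[k] - info[k - 1L]
  m <- prev$z * si[k - 1L] + theta * delta
  sum(prev$w * prev$h *
        pnorm((u_k * si[k] - m) / sqrt(delta), lower.tail = FALSE))
}

#' First-crossing (stopping) probabilities of a group-sequential boundary
#'
#' Computes, for each look \eqn{k}, the probability that the standardized
#' statistic first exceeds its boundary at look \eqn{k}:
#' \eqn{Pr(Z_1 < u_1, \dots, Z_{k-1} < u_{k-1}, Z_k \ge u_k; \theta)}. The
#' final cumulative value is the overall rejection probability — the type I
#' error when `theta = 0` and the power when `theta > 0`.
#'
#' The default method is deterministic recursive numerical integration over
#' the sub-density of the continuing statistic (Armitage-type recursion with
#' composite Simpson quadrature on a grid spanning 8 standardized units either
#' side of the drifted mean). `method = "mvnorm"` evaluates the same
#' probabilities as multivariate-normal rectangle probabilities via
#' [mvtnorm::pmvnorm()]; it serves as an independent cross-check.
#'
#' @inheritParams joint_moments
#' @param bounds Numeric vector of K standardized critical values; `+Inf`
#'   marks a look at which stopping is impossible.
#' @param nodes Number of quadrature nodes per look (minimum 301; rounded up
#'   to an odd count).
#' @param method `"recursion"` (default) or `"mvnorm"`.
#'
#' @return A tibble of class `gs_crossing` with columns `look`, `per_look`
#'   and `cumulative`, and attribute `theta`.
#' @examples
#' sched <- info_schedule(c(2, 4, 6, 8, 10))
#' crossing_probabilities(sched, rep(2.41, 5))
#' @export
crossing_probabilities <- function(schedule, bounds, theta = 0, nodes = 601,
                                   method = c("recursion", "mvnorm")) {
  sched <- as_info_schedule(schedule)
  upper <- check_bounds(bounds, sched$K)
  check_scalar_num(theta, "theta")
  method <- match.arg(method)
  per_look <- if (method == "recursion") {
    gs_states(sched$info, upper, theta, make_node_count(nodes))$per_look
  } else {
    crossing_mvnorm(sched$info, upper, theta)
  }
  new_gs_crossing(per_look, theta)
}

new_gs_crossing <- function(per_look, theta) {
  per_look <- pmin(pmax(per_look, 0), 1)
  out <- tibble(look = seq_along(per_look),
                per_look = per_look,
                cumulative = cumsum(per_look))
  attr(out, "theta") <- theta
  class(out) <- c("gs_crossing", class(out))
  out
}

# rectangle-probability route: cumulative[k] = 1 - Pr(Z_1<u_1,...,Z_k<u_k)
crossing_mvnorm <- function(info, upper, theta) {
  K <- length(info)
  mom <- joint_moments(info_schedule(info), theta)
  cum <- numeric(K)
  for (k in seq_len(K)) {
    if (k == 1L) {
      cum[1L] <- pnorm(upper[1L] - mom$mean[1L], lower.tail = FALSE)
    } else {
      none <- mvtnorm::pmvnorm(
        lower = rep(-Inf, k), upper = upper[seq_len(k)],
        mean = mom$mean[seq_len(k)],
        corr = mom$cov[seq_len(k), seq_len(k), drop = FALSE],
        algorithm = mvtnorm::Miwa(steps = 4097))
      cum[k] <- 1 - as.numeric(none)
    }
  }
  diff(c(0, cummax(cum)))
}

#' Solve for the boundary at one look given a cumulative alpha target
#'
#' Given boundaries already fixed for looks \eqn{1, \dots, k-1}, finds the
#' critical value \eqn{u_k} such that the cumulative crossing probability
#' through look \eqn{k} (at drift `theta0`, usually the null) equals
#' `target_cum_alpha`. This is the recursive step used to construct designs
#' from an alpha-spending sequence.
#'
#' A target equal to the alpha already spent (to within 1e-10) returns `+Inf`:
#' no stopping is possible at that look.
#'
#' @inheritParams crossing_probabilities
#' @param prior_bounds Boundaries for the first \eqn{k-1} looks (length 0 for
#'   the first look).
#' @param target_cum_alpha Cumulative crossing probability required through
#'   look \eqn{k}; must be at least the alpha already spent and below 1.
#' @param theta0 Drift at which the constraint holds (default 0, the null).
#'
#' @return The critical value \eqn{u_k} (possibly `+Inf`), solved to within
#'   1e-8 on the probability scale.
#' @examples
#' solve_boundary_at_look(info_schedule(4), numeric(0), 0.025)
#' @export
solve_boundary_at_look <- function(schedule, prior_bounds, target_cum_alpha,
                                   theta0 = 0, nodes = 601) {
  sched <- as_info_schedule(schedule)
  k <- length(prior_bounds) + 1L
  if (k > sched$K) {
    abort("More prior boundaries than looks in the schedule.",
          class = "seqbayes_error_dimension")
  }
  if (!is.numeric(target_cum_alpha) || length(target_cum_alpha) != 1L ||
      is.na(target_cum_alpha) || target_cum_alpha >= 1 || target_cum_alpha < 0) {
    abort("`target_cum_alpha` must be a single probability below 1.",
          class = "seqbayes_error_input")
  }
  nodes <- make_node_count(nodes)
  info <- sched$info[seq_len(k)]
  if (k == 1L) {
    spent <- 0
    prev <- NULL
  } else {
    fwd <- gs_states(info, c(check_bounds(prior_bounds, k - 1L), Inf),
                     theta0, nodes, k_max = k - 1L)
    spent <- sum(fwd$per_look)
    prev <- fwd$states[[k - 1L]]
  }
  gap <- target_cum_alpha - spent
  if (gap < -1e-10) {
    abort("Target cumulative alpha is below the alpha already spent.",
          class = "seqbayes_error_infeasible")
  }
  if (gap < 1e-10) {
    return(Inf)
  }
  if (k == 1L) {
    return(qnorm(gap, lower.tail = FALSE) + theta0 * sqrt(info[1L]))
  }
  f <- function(u) gs_increment(prev, info, theta0, k, u) - gap
  if (f(-10) < 0) {
    abort("Target cumulative alpha exceeds the attainable crossing probability.",
          class = "seqbayes_error_infeasible")
  }
  root <- uniroot(f, c(-10, 10), tol = 1e-12)$root
  if (abs(f(root)) > 1e-8) {
    abort("Boundary root search did not reach the 1e-8 probability tolerance.",
          class = "seqbayes_error_numeric")
  }
  root
}

#' Monte-Carlo oracle for crossing probabilities
#'
#' Simulates sample paths of the standardized statistics via their
#' independent-increments representation and tallies first crossings. Used to
#' validate the deterministic integration; slower but assumption-free.
#'
#' @inheritParams crossing_probabilities
#' @param n_paths Number of simulated trial paths (at least 1000).
#' @param seed Integer seed; required, no global RNG state is consumed.
#'
#' @return A tibble of class `gs_crossing_sim` with columns `look`,
#'   `per_look`, `cumulative` and `se` (binomial standard error of the
#'   cumulative estimate).
#' @examples
#' simulate_paths(info_schedule(c(2, 4)), c(2.2, 2.0), theta = 0,
#'                n_paths = 2000, seed = 1)
#' @export
simulate_paths <- function(schedule, bounds, theta, n_paths, seed) {
  sched <- as_info_schedule(schedule)
  upper <- check_bounds(bounds, sched$K)
  check_scalar_num(theta, "theta")
  if (!is.numeric(n_paths) || n_paths < 1000) {
    abort("`n_paths` must be at least 1000.", class = "seqbayes_error_input")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("An integer `seed` is required.", class = "seqbayes_error_input")
  }
  n_paths <- as.integer(n_paths)
  info <- sched$info
  K <- sched$K
  delta <- diff(c(0, info))
  first <- withr::with_seed(as.integer(seed), {
    w <- matrix(rnorm(n_paths * K), n_paths, K)
    w <- sweep(w, 2L, sqrt(delta), `*`)
    w <- sweep(w, 2L, theta * delta, `+`)
    if (K > 1L) {
      for (k in 2:K) w[, k] <- w[, k - 1L] + w[, k]
    }
    z <- sweep(w, 2L, sqrt(info), `/`)
    crossed <- sweep(z, 2L, upper, `>=`)
    ifelse(rowSums(crossed) > 0, max.col(crossed, ties.method = "first"), NA)
  })
  per_look <- tabulate(first, nbins = K) / n_paths
  cum <- cumsum(per_look)
  out <- tibble(look = seq_len(K), per_look = per_look, cumulative = cum,
                se = sqrt(pmax(cum * (1 - cum), 0) / n_paths))
  attr(out, "theta") <- theta
  attr(out, "n_paths") <- n_paths
  class(out) <- c("gs_crossing_sim", class(out))
  out
}
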