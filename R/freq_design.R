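## frequentist group-sequential designs ---------------------------------

new_gs_design <- function(label, schedule, bounds, alpha, alpha_spent,
                          extra = list(), subclass = character()) {
  obj <- c(list(label = label,
                schedule = schedule,
                bounds = bounds,
                alpha = alpha,
                alpha_spent = alpha_spent),
           extra)
  structure(obj, class = c(subclass, "gs_design"))
}

#' @export
print.gs_design <- function(x, digits = 4, ...) {
  cat("<gs_design>", x$label, " K =", x$schedule$K,
      " one-sided alpha =", format(x$alpha), "\n")
  print(tidy(x), n = x$schedule$K)
  invisible(x)
}

warn_if_unequal <- function(sched) {
  if (sched$K > 1L) {
    steps <- diff(c(0, sched$info))
    if (max(steps) - min(steps) > 1e-8 * max(steps)) {
      warn(paste("Schedule is not equally spaced in information;",
                 "the defining boundary shape is still applied."),
           class = "seqbayes_warning_unequal_spacing")
    }
  }
  invisible(sched)
}

#' Pocock design: constant standardized boundary
#'
#' Finds the constant \eqn{c} with \eqn{u_1 = \dots = u_K = c} such that the
#' overall one-sided crossing probability under the null is `alpha`. For
#' unequally spaced looks the constant-boundary definition is applied as-is
#' (with a warning).
#'
#' @inheritParams crossing_probabilities
#' @param alpha Overall one-sided type I error in (0, 1).
#' @return A `gs_design` object.
#' @examples
#' pocock_design(info_schedule(c(2, 4, 6, 8, 10)), 0.025)
#' @export
pocock_design <- function(schedule, alpha, nodes = 601) {
  sched <- as_info_schedule(schedule)
  check_scalar_prob(alpha, "alpha")
  warn_if_unequal(sched)
  nodes <- make_node_count(nodes)
  overall <- function(c_) {
    sum(gs_states(sched$info, rep(c_, sched$K), 0, nodes)$per_look)
  }
  lo <- qnorm(1 - alpha)
  c_ <- if (sched$K == 1L) lo else
    uniroot(function(c_) overall(c_) - alpha, c(lo, lo + 4),
            extendInt = "downX", tol = 1e-10)$root
  spent <- cumsum(gs_states(sched$info, rep(c_, sched$K), 0, nodes)$per_look)
  new_gs_design("pocock", sched, rep(c_, sched$K), alpha, spent,
                subclass = "freq_design")
}

#' O'Brien–Fleming design: constant boundary on the score scale
#'
#' The O'Brien–Fleming rule stops when \eqn{\bar Y_k I_k} exceeds a fixed
#' value, i.e. \eqn{u_k = C/\sqrt{I_k}} on the standardized scale, making
#' early stopping hard and the final look nearly unpenalized. \eqn{C} is
#' found so the overall one-sided size is `alpha`.
#'
#' @inheritParams pocock_design
#' @return A `gs_design` object.
#' @examples
#' obf_design(info_schedule(c(2, 4, 6, 8, 10)), 0.025)
#' @export
obf_design <- function(schedule, alpha, nodes = 601) {
  sched <- as_info_schedule(schedule)
  check_scalar_prob(alpha, "alpha")
  warn_if_unequal(sched)
  nodes <- make_node_count(nodes)
  si <- sqrt(sched$info)
  overall <- function(C) {
    sum(gs_states(sched$info, C / si, 0, nodes)$per_look)
  }
  lo <- qnorm(1 - alpha) * si[sched$K]
  C <- if (sched$K == 1L) lo else
    uniroot(function(C) overall(C) - alpha, c(lo, lo + 4 * si[sched$K]),
            extendInt = "downX", tol = 1e-10)$root
  spent <- cumsum(gs_states(sched$info, C / si, 0, nodes)$per_look)
  new_gs_design("obrien-fleming", sched, C / si, alpha, spent,
                extra = list(score_constant = C), subclass = "freq_design")
}

#' Build a design from an alpha-spending function
#'
#' Applies [solve_boundary_at_look()] recursively: the boundary at look
#' \eqn{k} is chosen so the cumulative crossing probability under the null
#' equals \eqn{\alpha^*(I_k/I_K)}.
#'
#' @inheritParams pocock_design
#' @param sf A [spending_function()]. For the `custom_vector` family the
#'   values are used as the per-look cumulative targets directly and must
#'   have length K.
#' @return A `gs_design` object.
#' @examples
#' design_from_spending(info_schedule(c(2, 4, 6, 8, 10)),
#'                      spending_function("linear", 0.025))
#' @export
design_from_spending <- function(schedule, sf, nodes = 601) {
  sched <- as_info_schedule(schedule)
  if (!inherits(sf, "spending_function")) {
    abort("`sf` must be a spending_function.", class = "seqbayes_error_input")
  }
  t_k <- sched$info / sched$info[sched$K]
  targets <- if (sf$family == "custom_vector") {
    if (length(sf$values) != sched$K) {
      abort("custom_vector spending values must have one entry per look.",
            class = "seqbayes_error_dimension")
    }
    sf$values
  } else {
    spending_value(sf, t_k)
  }
  if (any(diff(targets) < 0)) {
    abort("Spending targets must be non-decreasing.",
          class = "seqbayes_error_infeasible")
  }
  bounds <- numeric(0)
  for (k in seq_len(sched$K)) {
    bounds <- c(bounds,
                solve_boundary_at_look(sched, bounds, targets[k],
                                       theta0 = 0, nodes = nodes))
  }
  spent <- cumsum(gs_states(sched$info, bounds, 0,
                            make_node_count(nodes))$per_look)
  new_gs_design(paste0("spending-", sf$family), sched, bounds, sf$alpha,
                spent, extra = list(spending = sf, targets = targets),
                subclass = "freq_design")
}

#' Exact alpha spending of a design
#'
#' The cumulative crossing probabilities of the design's boundaries under the
#' null — the alpha actually spent by each look, whatever family constructed
#' the design.
#'
#' @param d A `gs_design`.
#' @inheritParams crossing_probabilities
#' @return Numeric vector \eqn{\alpha_1, \dots, \alpha_K}.
#' @examples
#' exact_spending_of_design(pocock_design(info_schedule(1:4), 0.05))
#' @export
exact_spending_of_design <- function(d, nodes = 601) {
  if (!inherits(d, "gs_design")) {
    abort("`d` must be a gs_design.", class = "seqbayes_error_input")
  }
  crossing_probabilities(d$schedule, d$bounds, theta = 0,
                         nodes = nodes)$cumulative
}
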