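#' Alpha-spending functions
#'
#' An alpha-spending function \eqn{\alpha^*(t)} allocates the overall
#' one-sided type I error \eqn{\alpha} across information time
#' \eqn{t = I_k/I_K}, with \eqn{\alpha^*(0) = 0} and
#' \eqn{\alpha^*(1) = \alpha}. Available families:
#'
#' * `linear`: \eqn{\alpha t} — equal spending per unit information.
#' * `lan_demets_pocock`: \eqn{\alpha \log(1 + (e - 1) t)} — approximates
#'   Pocock's constant boundary.
#' * `lan_demets_obf`: \eqn{2(1 - \Phi(z_{\alpha/2}/\sqrt t))} —
#'   approximates the O'Brien–Fleming boundary; the \eqn{t = 0} value is the
#'   continuity limit 0.
#' * `custom_vector`: explicit non-decreasing cumulative values
#'   \eqn{\alpha_1 \le \dots \le \alpha_K = \alpha} (Slud–Wei style),
#'   attached to the looks of a schedule rather than to a functional form.
#'
#' @param family Spending family name.
#' @param alpha Overall one-sided type I error in (0, 1).
#' @param values For `custom_vector`: the cumulative spend at each look.
#'
#' @return An object of class `spending_function`.
#' @examples
#' sf <- spending_function("linear", 0.025)
#' spending_value(sf, 0.6)
#' @export
spending_function <- function(family = c("linear", "lan_demets_pocock",
                                         "lan_demets_obf", "custom_vector"),
                              alpha, values = NULL) {
  family <- match.arg(family)
  check_scalar_prob(alpha, "alpha")
  if (family == "custom_vector") {
    if (is.null(values) || !is.numeric(values) || length(values) < 1L ||
        anyNA(values)) {
      abort("`values` must be supplied for the custom_vector family.",
            class = "seqbayes_error_input")
    }
    if (any(diff(values) < 0) || any(values < 0)) {
      abort("Custom spending values must be non-negative and non-decreasing.",
            class = "seqbayes_error_input")
    }
    if (abs(values[length(values)] - alpha) > 1e-12) {
      abort("The final custom spending value must equal `alpha`.",
            class = "seqbayes_error_input")
    }
  } else if (!is.null(values)) {
    warn("`values` is ignored except for the custom_vector family.")
  }
  structure(list(family = family, alpha = alpha, values = values),
            class = "spending_function")
}

#' @rdname spending_function
#' @param sf A `spending_function`.
#' @param t Information time(s) in \[0, 1\].
#' @export
spending_value <- function(sf, t) {
  if (!inherits(sf, "spending_function")) {
    abort("`sf` must be a spending_function.", class = "seqbayes_error_input")
  }
  if (!is.numeric(t) || anyNA(t) || any(t < 0 | t > 1)) {
    abort("`t` must lie in [0, 1].", class = "seqbayes_error_input")
  }
  alpha <- sf$alpha
  switch(sf$family,
    linear = alpha * t,
    lan_demets_pocock = alpha * log(1 + (exp(1) - 1) * t),
    lan_demets_obf = {
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- 2 * pnorm(qnorm(1 - alpha / 2) / sqrt(t[pos]),
                            lower.tail = FALSE)
      out
    },
    custom_vector = {
      # custom values are per-look, not a continuous function; interpolate
      # on the look grid t_k = k/K for evaluation at arbitrary t
      K <- length(sf$values)
      stats::approx(x = c(0, seq_len(K) / K), y = c(0, sf$values),
                    xout = t, rule = 2)$y
    })
}

#' @export
print.spending_function <- function(x, ...) {
  cat("<spending_function>", x$family, "alpha =", format(x$alpha), "\n")
  if (!is.null(x$values)) {
    cat("  values:", paste(format(x$values), collapse = ", "), "\n")
  }
  invisible(x)
}
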