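#' Information schedule for a group-sequential design
#'
#' A schedule records the number of looks `K` and the statistical
#' information \eqn{I_1 < \dots < I_K} available at each look. Information is
#' the inverse variance of the effect estimate: \eqn{I_k = n_k/\sigma^2} for a
#' single arm with known variance, or
#' \eqn{I_k = (\sigma_1^2/n_{1k} + \sigma_0^2/n_{0k})^{-1}} for a two-arm
#' difference in means.
#'
#' @param info Numeric vector of strictly increasing, positive information
#'   levels, one per look.
#'
#' @return An object of class `info_schedule` with fields `K` and `info`.
#' @examples
#' info_schedule(c(2, 4, 6, 8, 10))
#' @export
info_schedule <- function(info) {
  if (!is.numeric(info) || length(info) < 1L || anyNA(info)) {
    abort("`info` must be a non-empty numeric vector.",
          class = "seqbayes_error_invalid_schedule")
  }
  info <- as.numeric(info)
  if (any(info <= 0)) {
    abort("All information levels must be positive.",
          class = "seqbayes_error_invalid_schedule")
  }
  if (length(info) > 1L && any(diff(info) <= 0)) {
    abort("Information levels must be strictly increasing across looks.",
          class = "seqbayes_error_invalid_schedule")
  }
  structure(list(K = length(info), info = info), class = "info_schedule")
}

as_info_schedule <- function(x) {
  if (inherits(x, "info_schedule")) x else info_schedule(x)
}

#' @export
print.info_schedule <- function(x, ...) {
  cat("<info_schedule> K =", x$K, "\n")
  cat("  information:", paste(format(x$info), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.info_schedule <- function(x, ...) {
  sprintf("info_schedule(K = %d)", x$K)
}

check_bounds <- function(upper, K) {
  if (!is.numeric(upper) || anyNA(upper)) {
    abort("Boundary vector must be numeric without NAs.",
          class = "seqbayes_error_input")
  }
  if (length(upper) != K) {
    abort(sprintf("Boundary vector has length %d but the schedule has %d looks.",
                  length(upper), K),
          class = "seqbayes_error_dimension")
  }
  if (any(upper == -Inf)) {
    abort("Boundaries must be finite or +Inf (no-stopping sentinel).",
          class = "seqbayes_error_input")
  }
  as.numeric(upper)
}
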