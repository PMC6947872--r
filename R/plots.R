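#' Plot a group-sequential design
#'
#' `what = "boundaries"` draws the standardized stopping boundary against
#' information time; `what = "spending"` draws the cumulative alpha spent.
#'
#' @param object A `gs_design`.
#' @param what `"boundaries"` or `"spending"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_design <- function(object, what = c("boundaries", "spending"),
                               ...) {
  what <- match.arg(what)
  d <- tidy(object)
  d <- d[is.finite(d$boundary) | what == "spending", ]
  if (what == "boundaries") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$info_time, y = .data$boundary)) +
      ggplot2::geom_line(linetype = 2, colour = "grey50") +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "information time t = I_k / I_K",
                    y = "standardized boundary u_k",
                    title = object$label) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$info_time, y = .data$alpha_cum)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "information time t = I_k / I_K",
                    y = "cumulative type I error spent",
                    title = object$label) +
      ggplot2::theme_minimal()
  }
}

#' Plot a two-arm type I error profile
#'
#' Error rate of the calibrated Bayesian rule as the true common arm mean
#' moves away from the calibration point; the horizontal reference line (if
#' `alpha` is given) marks the nominal level.
#'
#' @param object A `gs_type1_profile` tibble from [type1_profile()].
#' @param alpha Optional nominal level to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_type1_profile <- function(object, alpha = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mu0, y = .data$type1)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true control-arm mean (mu0, with mu1 = mu0)",
                  y = "one-sided type I error rate") +
    ggplot2::theme_minimal()
  if (!is.null(alpha)) {
    gg <- gg + ggplot2::geom_hline(yintercept = alpha, linetype = 2,
                                   colour = "grey40")
  }
  gg
}

#' Compare several designs' boundaries in one plot
#'
#' @param ... Named `gs_design` objects.
#' @return A ggplot object.
#' @export
plot_boundaries <- function(...) {
  designs <- list(...)
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- vapply(designs, function(d) d$label, character(1))
  }
  d <- dplyr::bind_rows(lapply(designs, tidy), .id = "design")
  d <- d[is.finite(d$boundary), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$info_time, y = .data$boundary,
                                  colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "information time t = I_k / I_K",
                  y = "standardized boundary u_k", colour = NULL) +
    ggplot2::theme_minimal()
}
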