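#' Tidy a group-sequential design into a per-look tibble
#'
#' @param x A `gs_design`.
#' @param ... Unused.
#' @return A tibble with one row per look: `look`, `info`, `info_time`
#'   (\eqn{I_k/I_K}), `boundary`, `alpha_cum` and `alpha_incr`; Bayesian
#'   designs add the posterior threshold column `p`.
#' @export
tidy.gs_design <- function(x, ...) {
  K <- x$schedule$K
  out <- tibble(look = seq_len(K),
                info = x$schedule$info,
                info_time = x$schedule$info / x$schedule$info[K],
                boundary = x$bounds,
                alpha_cum = x$alpha_spent,
                alpha_incr = diff(c(0, x$alpha_spent)))
  if (!is.null(x$p)) out$p <- x$p
  out
}

#' One-row summary of a group-sequential design
#'
#' @inheritParams tidy.gs_design
#' @return A tibble with `label`, `K`, `alpha` (target), `alpha_realized`
#'   (exact overall spend) and `first_boundary`/`final_boundary`.
#' @export
glance.gs_design <- function(x, ...) {
  K <- x$schedule$K
  tibble(label = x$label, K = K, alpha = x$alpha,
         alpha_realized = x$alpha_spent[K],
         first_boundary = x$bounds[1L],
         final_boundary = x$bounds[K])
}

#' @export
tidy.binom_design <- function(x, ...) {
  dplyr::mutate(x$table, p = x$p, .after = "s")
}

#' @export
glance.binom_design <- function(x, ...) {
  tibble(label = "bayes-binomial-exact", K = x$schedule$K,
         pi0 = x$schedule$pi0, p = x$p, type1 = x$type1,
         final_threshold = x$s[x$schedule$K])
}

#' @export
tidy.gs_crossing <- function(x, ...) {
  as_tibble(unclass(x))
}
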