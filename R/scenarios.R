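## reference scenarios and config-driven dispatch ------------------------

#' Run a design from a configuration list
#'
#' Thin dispatcher used by the command-line interface and the scenario
#' runner. The configuration is a named list with a `kind` field:
#'
#' * `freq_pocock`, `freq_obf`: need `info`, `alpha`.
#' * `freq_spending`: needs `info`, `alpha`, `family` (and `values` for
#'   `custom_vector`).
#' * `bayes_normal`: needs `info`, `prior = list(theta0, info0)` and one of
#'   `p` / `alpha`.
#' * `bayes_binomial`: needs `n`, `pi0`, optional `prior = list(a, b)` and
#'   one of `p` / `alpha`.
#' * `two_param`: needs `info0`, `info1`,
#'   `priors = list(mu00, info00, mu10, info10)` and one of `p` / `alpha`
#'   (with optional `mu0_ref`).
#'
#' @param config Named list as above (e.g. parsed from YAML).
#' @return The constructed design object (`gs_design`, `binom_design`, or
#'   for `two_param` a list with the calibrated `p` and the design pieces).
#' @examples
#' run_design(list(kind = "freq_pocock", info = c(2, 4, 6, 8, 10),
#'                 alpha = 0.025))
#' @export
run_design <- function(config) {
  if (!is.list(config) || is.null(config$kind)) {
    abort("`config` must be a named list with a `kind` field.",
          class = "seqbayes_error_config")
  }
  need <- function(field, where = config) {
    if (is.null(where[[field]])) {
      abort(sprintf("Config field `%s` is required for kind '%s'.",
                    field, config$kind),
            class = "seqbayes_error_config")
    }
    where[[field]]
  }
  switch(config$kind,
    freq_pocock = pocock_design(info_schedule(need("info")), need("alpha")),
    freq_obf = obf_design(info_schedule(need("info")), need("alpha")),
    freq_spending = {
      sf <- spending_function(need("family"), need("alpha"),
                              values = config[["values"]])
      design_from_spending(info_schedule(need("info")), sf)
    },
    bayes_normal = {
      pr <- need("prior")
      bayes_design(normal_prior(need("theta0", pr), need("info0", pr)),
                   info_schedule(need("info")),
                   p = config[["p"]], alpha = config[["alpha"]])
    },
    bayes_binomial = {
      pr <- config[["prior"]] %||% list(a = 1, b = 1)
      binom_design(beta_prior(pr$a %||% 1, pr$b %||% 1),
                   binom_schedule(need("n"), need("pi0")),
                   alpha = config[["alpha"]], p = config[["p"]])
    },
    two_param = {
      pr <- need("priors")
      priors <- group_prior_pair(need("mu00", pr), need("info00", pr),
                                 need("mu10", pr), need("info10", pr))
      sched <- two_arm_schedule(need("info0"), need("info1"))
      p <- config[["p"]]
      if (is.null(p)) {
        p <- find_common_p_two_param(priors, sched, need("alpha"),
                                     mu0_ref = config[["mu0_ref"]] %||% 0)
      }
      law <- m_statistic_law(priors, sched, mu0 = config[["mu0_ref"]] %||% 0,
                             mu1 = config[["mu0_ref"]] %||% 0, p = p)
      list(kind = "two_param", priors = priors, schedule = sched, p = p,
           law = law,
           type1_at_ref = first_crossing_mvn(law$mean, law$cov,
                                             law$thresholds)$cumulative[sched$K])
    },
    abort(sprintf("Unknown design kind '%s'.", config$kind),
          class = "seqbayes_error_config")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference design scenarios
#'
#' The package's built-in validation suite: the canonical five-look normal
#' setting with equally spaced information \eqn{I_k = 2k} and one-sided
#' \eqn{\alpha = 0.025} (three frequentist designs and ten Bayesian priors),
#' the four-look exact binomial design (\eqn{n = 25, 50, 75, 100},
#' \eqn{\pi_0 = 0.5}, \eqn{\alpha = 0.05}) with its normal-approximation
#' Pocock comparator, and the five-look two-arm design with an informative
#' control prior. Each scenario carries the frozen values it must reproduce
#' (boundaries to 2 decimals, thresholds and spends to 4, success counts
#' exactly); [verify_scenarios()] recomputes and compares them.
#'
#' @return A tibble with columns `name`, `kind`, `config` (list) and
#'   `expected` (list).
#' @export
reference_scenarios <- function() {
  info5 <- c(2, 4, 6, 8, 10)
  bayes_row <- function(info0, theta0, p, u, a) {
    list(kind = "bayes_normal",
         config = list(kind = "bayes_normal", info = info5, alpha = 0.025,
                       prior = list(theta0 = theta0, info0 = info0)),
         expected = list(p = p, u = u, alpha_cum = a))
  }
  rows <- list(
    table1_bayes_i20_m025 = bayes_row(20, -0.25, 0.6063,
      c(4.43, 3.16, 2.60, 2.27, 2.05), c(0.0000, 0.0008, 0.0049, 0.0133, 0.0250)),
    table1_bayes_i1_m025 = bayes_row(1, -0.25, 0.9818,
      c(2.74, 2.46, 2.36, 2.31, 2.27), c(0.0031, 0.0089, 0.0148, 0.0202, 0.0250)),
    table1_bayes_i1_0 = bayes_row(1, 0, 0.9856,
      c(2.68, 2.45, 2.36, 2.32, 2.29), c(0.0037, 0.0097, 0.0155, 0.0205, 0.0250)),
    table1_bayes_i1_p025 = bayes_row(1, 0.25, 0.9889,
      c(2.62, 2.43, 2.37, 2.34, 2.32), c(0.0044, 0.0105, 0.0161, 0.0209, 0.0250)),
    table1_bayes_i1_p05 = bayes_row(1, 0.5, 0.9914,
      c(2.57, 2.42, 2.37, 2.35, 2.34), c(0.0051, 0.0114, 0.0168, 0.0213, 0.0251)),
    table1_bayes_i05_m025 = bayes_row(0.5, -0.25, 0.9872,
      c(2.58, 2.43, 2.37, 2.35, 2.33), c(0.0049, 0.0110, 0.0163, 0.0210, 0.0250)),
    table1_bayes_i05_0 = bayes_row(0.5, 0, 0.9888,
      c(2.55, 2.42, 2.38, 2.36, 2.34), c(0.0053, 0.0114, 0.0167, 0.0212, 0.0250)),
    table1_bayes_i05_p025 = bayes_row(0.5, 0.25, 0.9903,
      c(2.53, 2.42, 2.38, 2.37, 2.36), c(0.0058, 0.0119, 0.0171, 0.0213, 0.0250)),
    table1_bayes_i05_p05 = bayes_row(0.5, 0.5, 0.9916,
      c(2.50, 2.41, 2.39, 2.38, 2.37), c(0.0063, 0.0124, 0.0174, 0.0215, 0.0250)),
    table1_bayes_flat = bayes_row(0, 0, 0.9921,
      rep(2.41, 5), c(0.0079, 0.0138, 0.0183, 0.0220, 0.0250)),
    table1_obf = list(kind = "freq_obf",
      config = list(kind = "freq_obf", info = info5, alpha = 0.025),
      expected = list(u = c(4.56, 3.23, 2.63, 2.28, 2.04),
                      alpha_cum = c(0.0000, 0.0006, 0.0045, 0.0128, 0.0250))),
    table1_pocock = list(kind = "freq_pocock",
      config = list(kind = "freq_pocock", info = info5, alpha = 0.025),
      expected = list(u = rep(2.41, 5),
                      alpha_cum = c(0.0079, 0.0138, 0.0183, 0.0219, 0.0250))),
    table1_linear = list(kind = "freq_spending",
      config = list(kind = "freq_spending", family = "linear",
                    info = info5, alpha = 0.025),
      expected = list(u = c(2.58, 2.49, 2.41, 2.34, 2.28),
                      alpha_cum = c(0.0050, 0.0100, 0.0150, 0.0200, 0.0250))),
    example2_binomial = list(kind = "bayes_binomial",
      config = list(kind = "bayes_binomial", n = c(25, 50, 75, 100),
                    pi0 = 0.5, alpha = 0.05),
      expected = list(p = 0.977, s = c(18, 33, 47, 61),
                      pocock_constant = 2.067,
                      raw = c(17.7, 32.3, 46.5, 60.3))),
    example3_two_param = list(kind = "two_param",
      config = list(kind = "two_param",
                    info0 = 2 * info5, info1 = 2 * info5,
                    priors = list(mu00 = 0, info00 = 0.5,
                                  mu10 = 0, info10 = 0),
                    alpha = 0.025, mu0_ref = 0),
      expected = list(p = 0.9914))
  )
  tibble(name = names(rows),
         kind = vapply(rows, `[[`, character(1), "kind"),
         config = lapply(rows, `[[`, "config"),
         expected = lapply(rows, `[[`, "expected"))
}

# tolerance for one printed unit in the last place, with numerical headroom
printed_tol <- function(digits) 0.55 * 10^(-digits)

compare_scenario <- function(design, expected, kind) {
  checks <- list()
  if (kind %in% c("freq_pocock", "freq_obf", "freq_spending", "bayes_normal")) {
    checks$u <- max(abs(design$bounds - expected$u)) <= printed_tol(2)
    # cumulative alpha printed to 4 dp; allow one ulp for rounding collisions
    checks$alpha_cum <-
      max(abs(design$alpha_spent - expected$alpha_cum)) <= 2 * printed_tol(4)
    if (!is.null(expected$p)) {
      checks$p <- max(abs(design$p - expected$p)) <= 2 * printed_tol(4)
    }
  } else if (kind == "bayes_binomial") {
    checks$p <- abs(design$p - expected$p) <= printed_tol(3)
    checks$s <- all(design$s == expected$s)
    na <- normal_approx_design(design$schedule, 0.05)
    checks$pocock_constant <-
      abs(attr(na, "constant") - expected$pocock_constant) <= printed_tol(3)
    checks$raw <- max(abs(na$raw - expected$raw)) <= printed_tol(1)
    checks$rounded_match <- all(na$rounded == expected$s)
  } else if (kind == "two_param") {
    checks$p <- abs(design$p - expected$p) <= printed_tol(4)
  }
  checks
}

#' Recompute every reference scenario and compare to its frozen values
#'
#' @param scenarios A scenario tibble as from [reference_scenarios()].
#' @return A tibble with columns `name`, `kind`, `pass` and `detail`
#'   (per-quantity pass flags).
#' @examples
#' \donttest{verify_scenarios(reference_scenarios()[11:13, ])}
#' @export
verify_scenarios <- function(scenarios = reference_scenarios()) {
  res <- purrr::pmap(scenarios, function(name, kind, config, expected) {
    design <- run_design(config)
    checks <- compare_scenario(design, expected, kind)
    tibble(name = name, kind = kind,
           pass = all(unlist(checks)), detail = list(checks))
  })
  dplyr::bind_rows(res)
}

#' Write the reference scenarios as config files plus a manifest
#'
#' Emits one YAML configuration per scenario and a `manifest.json` mapping
#' scenario names to their expected values. Rerunning overwrites with
#' identical content (idempotent).
#'
#' @param output_dir Writable directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_scenario_fixtures <- function(output_dir) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The `yaml` package is required to write fixtures.",
          class = "seqbayes_error_input")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- reference_scenarios()
  paths <- character(0)
  for (i in seq_len(nrow(sc))) {
    path <- file.path(output_dir, paste0(sc$name[i], ".yaml"))
    yaml::write_yaml(sc$config[[i]], path)
    paths <- c(paths, path)
  }
  manifest <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(setNames(sc$expected, sc$name), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest))
}
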