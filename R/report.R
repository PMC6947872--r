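## serialization of completed designs ------------------------------------

#' Serialize a design report
#'
#' Writes a completed design as JSON (full double precision, deterministic —
#' identical designs give byte-identical files) and/or as a flat CSV with one
#' row per look. Bayesian designs carry the prior parameters and posterior
#' thresholds alongside the boundary and spending columns.
#'
#' @param design A `gs_design` or `binom_design`.
#' @param json,csv Optional output paths; at least one must be given.
#' @return The report list, invisibly.
#' @examples
#' d <- pocock_design(info_schedule(c(2, 4, 6, 8, 10)), 0.025)
#' f <- tempfile(fileext = ".json")
#' write_design_report(d, json = f)
#' @export
write_design_report <- function(design, json = NULL, csv = NULL) {
  if (is.null(json) && is.null(csv)) {
    abort("Supply at least one of `json` and `csv`.",
          class = "seqbayes_error_input")
  }
  rep <- design_report(design)
  if (!is.null(json)) {
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv)) {
    utils::write.csv(rep$looks, csv, row.names = FALSE)
  }
  invisible(rep)
}

#' @rdname write_design_report
#' @export
design_report <- function(design) {
  if (inherits(design, "gs_design")) {
    rep <- list(label = design$label,
                K = design$schedule$K,
                alpha = design$alpha,
                info = design$schedule$info,
                looks = as.data.frame(tidy(design)))
    if (!is.null(design$prior)) {
      rep$theta0 <- design$prior$theta0
      rep$info0 <- design$prior$info0
      rep$p <- design$p
    }
    rep
  } else if (inherits(design, "binom_design")) {
    list(label = "bayes-binomial-exact",
         K = design$schedule$K,
         pi0 = design$schedule$pi0,
         n = design$schedule$n,
         p = design$p,
         s = design$s,
         type1 = design$type1,
         looks = as.data.frame(design$table))
  } else {
    abort("Unsupported design class.", class = "seqbayes_error_input")
  }
}
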