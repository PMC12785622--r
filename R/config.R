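#' Analysis configuration
#'
#' Bundles the tunable settings of the shelf-life analysis. The defaults are
#' the packaged study's values: initial color-acceptance score `q0 = 6.3`,
#' hedonic reject point `qe = 5.0` (rejection is *strictly* below
#' threshold), color acceptance as the deciding attribute, week-0 baselines
#' included in kinetic fits, and floor rounding of reported weeks.
#'
#' @param q0 Initial attribute value used for predictions.
#' @param qe Rejection value used for predictions (must be below `q0`).
#' @param threshold Hedonic rejection threshold for experimental shelf life.
#' @param k_source Where predicted rate constants come from: `"fitted"`
#'   (kinetic fits of the data), `"printed"` (a published rate table) or
#'   `"arrhenius"` (Arrhenius extrapolation of the rate table).
#' @param include_baseline Include week-0 baselines in kinetic fits.
#' @param rounding Reporting policy for integer weeks, `"floor"` or
#'   `"nearest"`.
#' @param attribute Sensory attribute that decides shelf life.
#' @param rate_table Optional data frame `packaging, temperature_c, k`
#'   overriding the packaged published table for `"printed"`/`"arrhenius"`
#'   modes.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(q0 = 6.3, qe = 5.0, threshold = 5.0,
                            k_source = c("fitted", "printed", "arrhenius"),
                            include_baseline = TRUE,
                            rounding = c("floor", "nearest"),
                            attribute = "color_acceptance",
                            rate_table = NULL) {
  k_source <- match.arg(k_source)
  rounding <- match.arg(rounding)
  if (!is.numeric(q0) || !is.numeric(qe) || qe >= q0) {
    skn_stop("config needs numeric q0 and qe with qe < q0",
             "shelfkin_domain_error")
  }
  if (!is.null(rate_table)) {
    stopifnot(is.data.frame(rate_table),
              all(c("packaging", "temperature_c", "k") %in% names(rate_table)))
  }
  structure(
    list(q0 = q0, qe = qe, threshold = threshold, k_source = k_source,
         include_baseline = isTRUE(include_baseline), rounding = rounding,
         attribute = attribute, rate_table = rate_table),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> %s | Q0 = %g, Qe = %g, threshold = %g | k: %s | %s rounding%s\n",
    x$attribute, x$q0, x$qe, x$threshold, x$k_source, x$rounding,
    if (x$include_baseline) "" else " | baseline excluded"))
  invisible(x)
}

# Merge documented-default config with keys read from a YAML file and
# command-line overrides (flag > file > default).
config_from_keys <- function(keys) {
  allowed <- c("q0", "qe", "threshold", "k_source", "include_baseline",
               "rounding", "attribute")
  bad <- setdiff(names(keys), allowed)
  if (length(bad) > 0) {
    skn_stop(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
             "shelfkin_parse_error")
  }
  do.call(analysis_config, keys)
}
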