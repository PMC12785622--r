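#' Predict shelf life from kinetic parameters
#'
#' Inverts the fitted degradation model at the rejection value \eqn{Q_e}:
#' zero order gives \eqn{t_s = (Q_0 - Q_e)/k}, first order gives
#' \eqn{t_s = \ln(Q_0/Q_e)/k}. The default reporting policy truncates to
#' completed weeks (floor), the conservative shelf-life convention;
#' `rounding = "nearest"` rounds instead.
#'
#' @param order `"zero"` or `"first"`.
#' @param q0 Initial attribute value (for sensory attributes, the week-0
#'   hedonic mean).
#' @param qe Rejection value of the attribute (the hedonic reject point).
#' @param k Rate constant, per week; must be positive.
#' @param k_source Provenance tag for reporting: `"fitted"`, `"printed"`
#'   or `"arrhenius"`.
#' @param rounding `"floor"` (default) or `"nearest"`.
#' @return A `shelf_life_estimate`: list with `t_s_weeks` (real weeks),
#'   `reported_weeks` (integer weeks), `q0`, `qe`, `k`, `k_source`, `order`
#'   and `already_rejected`.
#' @examples
#' predict_shelf_life("first", q0 = 6.3, qe = 5.0, k = 0.028)
#' @export
predict_shelf_life <- function(order = c("first", "zero"), q0, qe, k,
                               k_source = c("fitted", "printed", "arrhenius"),
                               rounding = c("floor", "nearest")) {
  order <- match.arg(order)
  k_source <- match.arg(k_source)
  rounding <- match.arg(rounding)
  if (!is.finite(k) || k <= 0) {
    skn_stop("rate constant k must be positive", "shelfkin_domain_error")
  }
  if (order == "first" && (q0 <= 0 || qe <= 0)) {
    skn_stop("first-order shelf life needs q0 > 0 and qe > 0",
             "shelfkin_domain_error")
  }
  already_rejected <- qe >= q0
  if (already_rejected) {
    if (qe > q0) warning("rejection value qe exceeds initial value q0; ",
                         "product is already rejected (t_s = 0)")
    t_s <- 0
  } else {
    t_s <- switch(order,
                  zero = (q0 - qe) / k,
                  first = log(q0 / qe) / k)
  }
  reported <- switch(rounding, floor = floor(t_s), nearest = round(t_s))
  structure(
    list(t_s_weeks = t_s, reported_weeks = as.integer(reported),
         q0 = q0, qe = qe, k = k, k_source = k_source, order = order,
         already_rejected = already_rejected),
    class = "shelf_life_estimate"
  )
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  cat(sprintf(
    "<shelf_life_estimate> t_s = %.3f weeks (reported %d) | %s order, k = %.4g (%s)\n",
    x$t_s_weeks, x$reported_weeks, x$order, x$k, x$k_source))
  cat(sprintf("  Q0 = %g -> Qe = %g%s\n", x$q0, x$qe,
              if (x$already_rejected) "  [already rejected]" else ""))
  invisible(x)
}

#' Experimental shelf life of a censored sensory series
#'
#' The product is rejected at the first panel session whose mean score falls
#' *strictly* below the threshold (a score exactly at the threshold still
#' passes). The experimental shelf life is the time of the last passing
#' session. When the very first session already fails, only an upper bound
#' is known (`less_than`); when no session fails, only a lower bound is
#' known (`greater_than`, at the last observed time).
#'
#' @param series A [quality_series()] of a sensory attribute with at least
#'   one observation.
#' @param threshold Rejection threshold on the hedonic scale (default 5.0,
#'   the "neither like nor dislike" midpoint).
#' @return An `experimental_shelf_life`: list with `weeks`, `bound`
#'   (`"exact"`, `"greater_than"` or `"less_than"`), `attribute_used` and
#'   `threshold`.
#' @examples
#' ds <- builtin_fixture("table2_sensory")
#' experimental_shelf_life(extract_series(ds, "color_acceptance",
#'                                        "clear_plastic", 25))
#' @export
experimental_shelf_life <- function(series, threshold = 5.0) {
  stopifnot(inherits(series, "quality_series"))
  if (nrow(series) == 0) {
    skn_stop("series has no observations", "shelfkin_insufficient_data")
  }
  t <- series$time_weeks
  fails <- which(series$value < threshold)
  if (length(fails) == 0) {
    res <- list(weeks = t[length(t)], bound = "greater_than")
  } else if (fails[1] == 1) {
    res <- list(weeks = t[1], bound = "less_than")
  } else {
    res <- list(weeks = t[fails[1] - 1], bound = "exact")
  }
  structure(
    c(res, list(attribute_used = attr(series, "attribute"),
                threshold = threshold)),
    class = "experimental_shelf_life"
  )
}

#' @export
print.experimental_shelf_life <- function(x, ...) {
  sym <- switch(x$bound, exact = "", greater_than = ">", less_than = "<")
  cat(sprintf("<experimental_shelf_life> %s%g weeks (%s, threshold %g)\n",
              sym, x$weeks, x$attribute_used, x$threshold))
  invisible(x)
}

#' Compare experimental and model-predicted shelf life
#'
#' Builds the actual-vs-predicted comparison for every packaging and
#' temperature that has a sensory series of the configured attribute:
#' experimental shelf life from the censored panel series, predicted shelf
#' life from [predict_shelf_life()] with the rate constant chosen by
#' `config$k_source`:
#'
#' * `"fitted"` — fit both reaction orders to the series (baseline handling
#'   per `config$include_baseline`) and use [select_order()];
#' * `"printed"` — look up the first-order constant in `config$rate_table`
#'   (default: the packaged published color-acceptance table);
#' * `"arrhenius"` — fit the Arrhenius relation per packaging to the
#'   `rate_table` constants and extrapolate to each temperature.
#'
#' @param dataset A [storage_dataset()] with sensory series.
#' @param config An [analysis_config()].
#' @return A tibble with one row per condition: `packaging`,
#'   `temperature_c`, `actual_weeks`, `actual_bound`, `predicted_weeks`,
#'   `t_s_raw`, `k`, `k_source`, `order`. Conditions with no usable rate
#'   constant keep `NA` in the prediction columns.
#' @examples
#' ds <- builtin_fixture("table2_sensory")
#' compare_actual_predicted(ds, analysis_config(k_source = "printed"))
#' @export
compare_actual_predicted <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "storage_dataset"),
            inherits(config, "analysis_config"))
  info <- dataset$series[dataset$series$attribute == config$attribute, ,
                         drop = FALSE]
  empty <- tibble::tibble(
    packaging = character(), temperature_c = double(),
    actual_weeks = double(), actual_bound = character(),
    predicted_weeks = integer(), t_s_raw = double(), k = double(),
    k_source = character(), order = character())
  if (nrow(info) == 0) return(empty)

  rate_table <- config$rate_table
  if (is.null(rate_table) && config$k_source != "fitted") {
    tbl <- builtin_fixture("table4_color_k")
    rate_table <- tbl[tbl$order == "first", c("packaging", "temperature_c", "k")]
  }
  arr_fits <- list()
  if (config$k_source == "arrhenius") {
    for (p in unique(rate_table$packaging)) {
      pts <- rate_table[rate_table$packaging == p, , drop = FALSE]
      arr_fits[[p]] <- tryCatch(fit_arrhenius(pts), shelfkin_error = function(e) NULL)
    }
  }

  rows <- lapply(seq_len(nrow(info)), function(i) {
    pkg <- info$packaging[i]
    tc <- info$temperature_c[i]
    s <- extract_series(dataset, config$attribute, pkg, tc)
    act <- experimental_shelf_life(s, threshold = config$threshold)
    kin <- resolve_k(s, pkg, tc, config, rate_table, arr_fits)
    if (is.null(kin)) {
      return(tibble::tibble(
        packaging = pkg, temperature_c = tc,
        actual_weeks = act$weeks, actual_bound = act$bound,
        predicted_weeks = NA_integer_, t_s_raw = NA_real_, k = NA_real_,
        k_source = config$k_source, order = NA_character_))
    }
    est <- predict_shelf_life(kin$order, q0 = config$q0, qe = config$qe,
                              k = kin$k, k_source = config$k_source,
                              rounding = config$rounding)
    tibble::tibble(
      packaging = pkg, temperature_c = tc,
      actual_weeks = act$weeks, actual_bound = act$bound,
      predicted_weeks = est$reported_weeks, t_s_raw = est$t_s_weeks,
      k = kin$k, k_source = config$k_source, order = kin$order)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$packaging, .data$temperature_c)
}

resolve_k <- function(series, pkg, tc, config, rate_table, arr_fits) {
  switch(
    config$k_source,
    fitted = tryCatch({
      z <- fit_zero_order(series, include_baseline = config$include_baseline)
      f <- fit_first_order(series, include_baseline = config$include_baseline)
      best <- select_order(z, f)
      if (best$k <= 0) NULL else list(k = best$k, order = best$order)
    }, shelfkin_error = function(e) NULL),
    printed = {
      hit <- rate_table$packaging == pkg & rate_table$temperature_c == tc
      if (!any(hit)) NULL else list(k = rate_table$k[which(hit)[1]],
                                    order = "first")
    },
    arrhenius = {
      fit <- arr_fits[[pkg]]
      if (is.null(fit)) NULL else list(k = k_at(fit, tc), order = "first")
    }
  )
}

#' Format a comparison table as an aligned text report
#'
#' @param comparison Output of [compare_actual_predicted()].
#' @return A character vector of report lines.
#' @export
format_comparison <- function(comparison) {
  sym <- c(exact = "", greater_than = ">", less_than = "<")
  actual <- paste0(sym[comparison$actual_bound], comparison$actual_weeks)
  lines <- sprintf(
    "%-14s %5g °C  actual %-5s predicted %3s  (t_s = %s, k = %s, %s, %s)",
    comparison$packaging, comparison$temperature_c, actual,
    ifelse(is.na(comparison$predicted_weeks), "NA",
           comparison$predicted_weeks),
    ifelse(is.na(comparison$t_s_raw), "NA",
           sprintf("%.2f wk", comparison$t_s_raw)),
    ifelse(is.na(comparison$k), "NA", sprintf("%.4g", comparison$k)),
    ifelse(is.na(comparison$order), "?", comparison$order),
    comparison$k_source)
  c("Shelf life: experimental vs predicted", lines)
}
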