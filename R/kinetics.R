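#' Degradation kinetics of a quality series
#'
#' Food-quality loss during storage is conventionally modelled as either a
#' zero-order reaction, where the attribute declines linearly,
#' \deqn{Q(t) = Q_0 - k t,}
#' or a first-order reaction, where it declines exponentially,
#' \deqn{\ln Q(t) = \ln Q_0 - k t.}
#' Both are fitted by ordinary least squares with a free intercept:
#' zero-order regresses the value on time, first-order regresses the natural
#' log of the value on time (so its \eqn{R^2} is on the fitting, i.e. log,
#' scale). The rate constant is `k = -slope`, positive for a decaying series.
#' Detection-limit records are excluded from fitting.
#'
#' When the series carries a week-0 baseline (see [extract_series()]) and no
#' observation at time zero, the baseline is prepended as an observation if
#' `include_baseline = TRUE` (the default).
#'
#' @param series A [quality_series()].
#' @param include_baseline Include the week-0 baseline value as an
#'   observation when one is attached to the series.
#' @return A `kinetic_fit`: list with `order` (`"zero"` or `"first"`), `k`
#'   (per week; attribute units/week for zero order, 1/week for first
#'   order), `q0_hat` (fitted initial value, in attribute units),
#'   `r_squared`, `n_points`, and the series identity.
#' @examples
#' s <- quality_series(c(0, 2, 4, 6), 10 - 0.5 * c(0, 2, 4, 6))
#' fit_zero_order(s)
#' @name kinetics
NULL

fit_points <- function(series, include_baseline) {
  stopifnot(inherits(series, "quality_series"))
  keep <- !series$below_detection
  t <- series$time_weeks[keep]
  q <- series$value[keep]
  b <- attr(series, "baseline")
  if (isTRUE(include_baseline) && !is.null(b) && !any(t == 0)) {
    t <- c(0, t)
    q <- c(b, q)
  }
  list(t = t, q = q)
}

ols_fit <- function(t, y) {
  fit <- lm(y ~ t)
  res <- residuals(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps * sum(y^2)) 0 else 1 - sum(res^2) / tss
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = max(0, min(1, r2)))
}

new_kinetic_fit <- function(order, k, q0_hat, r_squared, n_points, series) {
  structure(
    list(order = order, k = k, q0_hat = q0_hat, r_squared = r_squared,
         n_points = n_points,
         attribute = attr(series, "attribute"),
         packaging = attr(series, "packaging"),
         temperature_c = attr(series, "temperature_c")),
    class = "kinetic_fit"
  )
}

#' @rdname kinetics
#' @export
fit_zero_order <- function(series, include_baseline = TRUE) {
  p <- fit_points(series, include_baseline)
  check_design(p$t)
  f <- ols_fit(p$t, p$q)
  new_kinetic_fit("zero", k = -f$slope, q0_hat = f$intercept,
                  r_squared = f$r_squared, n_points = length(p$t), series)
}

#' @rdname kinetics
#' @export
fit_first_order <- function(series, include_baseline = TRUE) {
  p <- fit_points(series, include_baseline)
  check_design(p$t)
  nonpos <- p$q <= 0
  if (any(nonpos)) {
    skn_stop(sprintf(
      "first-order fit needs positive values; offending week(s): %s",
      paste(p$t[nonpos], collapse = ", ")),
      "shelfkin_domain_error")
  }
  f <- ols_fit(p$t, log(p$q))
  new_kinetic_fit("first", k = -f$slope, q0_hat = exp(f$intercept),
                  r_squared = f$r_squared, n_points = length(p$t), series)
}

check_design <- function(t) {
  if (length(t) < 3) {
    skn_stop(sprintf("kinetic fits need at least 3 observations, got %d",
                     length(t)),
             "shelfkin_insufficient_data")
  }
  if (var(t) == 0) {
    skn_stop("observation times have zero variance",
             "shelfkin_degenerate_design")
  }
  invisible(t)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> %s order | k = %.4g /week | Q0_hat = %.4g | R2 = %.3f (n = %d)\n",
    x$order, x$k, x$q0_hat, x$r_squared, x$n_points))
  if (!is.na(x$temperature_c)) {
    cat(sprintf("  %s | %s @ %g °C\n", x$attribute, x$packaging,
                x$temperature_c))
  }
  invisible(x)
}

#' Select the better-fitting reaction order
#'
#' Given a zero-order and a first-order fit of the same series, returns the
#' fit with the larger coefficient of determination. An exact tie resolves
#' to the first-order fit, the conventional default model for sensory
#' quality loss.
#'
#' @param zero A zero-order `kinetic_fit`.
#' @param first A first-order `kinetic_fit`.
#' @return One of the two fits.
#' @export
select_order <- function(zero, first) {
  stopifnot(inherits(zero, "kinetic_fit"), inherits(first, "kinetic_fit"))
  if (zero$order != "zero" || first$order != "first") {
    skn_stop("arguments must be a zero-order and a first-order fit",
             "shelfkin_consistency_error")
  }
  same <- identical(zero$attribute, first$attribute) &&
    identical(zero$packaging, first$packaging) &&
    identical(zero$temperature_c, first$temperature_c) &&
    identical(zero$n_points, first$n_points)
  if (!same) {
    skn_stop("fits come from different series", "shelfkin_consistency_error")
  }
  if (zero$r_squared > first$r_squared) zero else first
}

#' Evaluate a fitted kinetic model
#'
#' @param fit A `kinetic_fit`, or a bare order string (`"zero"`/`"first"`)
#'   combined with the `k` argument.
#' @param t Storage time(s), weeks; non-negative.
#' @param q0 Initial value; defaults to the fitted intercept `q0_hat`.
#' @param k Rate constant, only used when `fit` is an order string.
#' @return Predicted attribute value(s) at `t`.
#' @examples
#' predict_quality("first", t = 8.254, q0 = 6.3, k = 0.028)
#' @export
predict_quality <- function(fit, t, q0 = NULL, k = NULL) {
  if (is.character(fit)) {
    order <- match.arg(fit, c("zero", "first"))
    if (is.null(k) || is.null(q0)) {
      skn_stop("supply k and q0 when `fit` is an order string",
               "shelfkin_domain_error")
    }
  } else {
    stopifnot(inherits(fit, "kinetic_fit"))
    order <- fit$order
    k <- fit$k
    if (is.null(q0)) q0 <- fit$q0_hat
  }
  if (any(t < 0)) skn_stop("t must be non-negative", "shelfkin_domain_error")
  if (order == "first" && q0 <= 0) {
    skn_stop("first-order prediction needs q0 > 0", "shelfkin_domain_error")
  }
  switch(order,
         zero = q0 - k * t,
         first = q0 * exp(-k * t))
}
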