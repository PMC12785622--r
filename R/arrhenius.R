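#' Arrhenius analysis of rate constants
#'
#' The temperature dependence of a degradation rate constant is described by
#' the Arrhenius equation \deqn{k = A \exp(-E_a / (R T)),} with activation
#' energy \eqn{E_a} (kJ/mol), pre-exponential factor \eqn{A}, gas constant
#' \eqn{R = 8.314} J/(mol K) and absolute temperature \eqn{T} (Kelvin;
#' Celsius + 273.15). Fitting is linear on the Arrhenius plot: ordinary
#' least squares of \eqn{\ln k} on \eqn{1/T}, so
#' \eqn{E_a = -\mathrm{slope} \times R / 1000} and
#' \eqn{\ln A = \mathrm{intercept}}.
#'
#' @param points Rate points: a data frame with columns `temperature_c` and
#'   `k` (e.g. from [generate_arrhenius_study()] or assembled from
#'   `kinetic_fit`s), or a numeric vector of rate constants named by their
#'   Celsius temperatures.
#' @return An `arrhenius_fit`: list with `ea_kj_mol`, `ln_a`, `r_squared`
#'   and `n_temps`.
#' @examples
#' pts <- data.frame(temperature_c = c(4, 25, 35, 45),
#'                   k = c(0.012, 0.028, 0.075, 0.11))
#' fit <- fit_arrhenius(pts)
#' fit
#' k_at(fit, 25)
#' @export
fit_arrhenius <- function(points) {
  if (is.numeric(points) && !is.null(names(points))) {
    points <- data.frame(temperature_c = as.numeric(names(points)),
                         k = unname(points))
  }
  stopifnot(is.data.frame(points),
            all(c("temperature_c", "k") %in% names(points)))
  tc <- points$temperature_c
  k <- points$k
  if (any(!is.finite(k) | k <= 0)) {
    skn_stop("all rate constants must be positive and finite",
             "shelfkin_domain_error")
  }
  if (length(unique(tc)) < 3) {
    skn_stop("Arrhenius fits need rate constants at >= 3 distinct temperatures",
             "shelfkin_degenerate_design")
  }
  inv_t <- 1 / (tc + .C_TO_K)
  f <- ols_fit(inv_t, log(k))
  structure(
    list(ea_kj_mol = -f$slope * .R_GAS / 1000,
         ln_a = f$intercept,
         r_squared = f$r_squared,
         n_temps = length(unique(tc))),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> Ea = %.4g kJ/mol | ln A = %.4g | R2 = %.3f (%d temperatures)\n",
    x$ea_kj_mol, x$ln_a, x$r_squared, x$n_temps))
  invisible(x)
}

#' Extrapolate a rate constant to a new temperature
#'
#' Evaluates \eqn{k(T) = \exp(\ln A - E_a \cdot 1000 / (R\,T))} from a
#' fitted Arrhenius relation. With \eqn{E_a > 0} the result is strictly
#' increasing in temperature.
#'
#' @param fit An `arrhenius_fit`.
#' @param temperature_c Temperature(s) in degrees Celsius (above absolute
#'   zero).
#' @return Rate constant(s) at the requested temperature(s), per week.
#' @export
k_at <- function(fit, temperature_c) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (any(temperature_c <= -.C_TO_K)) {
    skn_stop("temperature must exceed absolute zero", "shelfkin_domain_error")
  }
  exp(fit$ln_a - fit$ea_kj_mol * 1000 / (.R_GAS * (temperature_c + .C_TO_K)))
}
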