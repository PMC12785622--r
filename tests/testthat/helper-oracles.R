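# Hand-coded closed-form two-parameter OLS, independent of the fitting code
# under test.
oracle_ols <- function(x, y) {
  xm <- mean(x)
  ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - ym)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

oracle_zero <- function(t, q) {
  f <- oracle_ols(t, q)
  list(k = -f$slope, q0_hat = f$intercept, r_squared = f$r_squared)
}

oracle_first <- function(t, q) {
  f <- oracle_ols(t, log(q))
  list(k = -f$slope, q0_hat = exp(f$intercept), r_squared = f$r_squared)
}

oracle_arrhenius <- function(temperature_c, k) {
  f <- oracle_ols(1 / (temperature_c + 273.15), log(k))
  list(ea_kj_mol = -f$slope * 8.314 / 1000, ln_a = f$intercept,
       r_squared = f$r_squared)
}

# Random noisy decaying series for property-style loops.
random_series <- function(order = c("first", "zero"), n = 8) {
  order <- match.arg(order)
  t <- sort(sample(0:30, n))
  while (length(unique(t)) < n) t <- sort(sample(0:30, n))
  q0 <- runif(1, 4, 10)
  k <- runif(1, 0.005, 0.08)
  mu <- if (order == "first") q0 * exp(-k * t) else q0 - k * t
  q <- pmax(0.2, mu + rnorm(n, 0, 0.1))
  list(t = t, q = q, q0 = q0, k = k,
       series = quality_series(t, q, attribute = "color_acceptance"))
}

table2_color_series <- function(packaging, temperature_c) {
  extract_series(builtin_fixture("table2_sensory"), "color_acceptance",
                 packaging, temperature_c)
}
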