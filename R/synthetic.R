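#' Synthetic storage-study scenarios
#'
#' `decay_scenario()` describes an instrumental quality-decay experiment:
#' one attribute decaying from `q0` by zero- or first-order kinetics, with a
#' known rate constant per storage temperature and Gaussian measurement
#' noise. `panel_scenario()` wraps a decay scenario into a consumer-panel
#' study: at each session a panel of `n_consumers` scores the product on the
#' 1--9 hedonic scale (individual scores are Gaussian around the model mean,
#' clipped to the scale and rounded to whole points before averaging, which
#' reproduces the granularity of real panel means), and sessions after the
#' first rejection are censored like a real storage table.
#'
#' Defaults mirror the packaged study's design: storage at 4/25/35/45
#' degrees Celsius with published-study-scale first-order color rate constants,
#' q0 = 6.3, sessions every 3 weeks to week 24, panels of 50 consumers with
#' score spread 1.5, and a rejection threshold of 5.0.
#'
#' @param order Reaction order of the decay, `"first"` or `"zero"`.
#' @param q0 Initial attribute value.
#' @param k_by_temperature Named numeric vector mapping Celsius temperature
#'   labels to rate constants (all positive).
#' @param noise_sd Gaussian measurement noise, attribute units.
#' @param times Measurement weeks, strictly increasing.
#' @param seed Integer seed; generation is reproducible per scenario.
#' @return A `decay_scenario` list.
#' @export
decay_scenario <- function(order = c("first", "zero"), q0 = 6.3,
                           k_by_temperature = c(`4` = 0.012, `25` = 0.028,
                                                `35` = 0.075, `45` = 0.11),
                           noise_sd = 0.05, times = seq(0, 24, by = 3),
                           seed = 1L) {
  order <- match.arg(order)
  stopifnot(is.numeric(k_by_temperature), !is.null(names(k_by_temperature)))
  if (any(k_by_temperature <= 0)) {
    skn_stop("all rate constants must be positive", "shelfkin_domain_error")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    skn_stop("times must be strictly increasing", "shelfkin_domain_error")
  }
  if (noise_sd < 0) skn_stop("noise_sd must be >= 0", "shelfkin_domain_error")
  structure(
    list(order = order, q0 = q0, k_by_temperature = k_by_temperature,
         noise_sd = noise_sd, times = times, seed = as.integer(seed)),
    class = "decay_scenario"
  )
}

#' @param decay A `decay_scenario` describing the underlying quality decay;
#'   session weeks are the scenario's strictly positive `times`.
#' @param n_consumers Panel size per session.
#' @param consumer_sd Between-consumer score standard deviation.
#' @param threshold Rejection threshold applied to session means.
#' @param censor_after_rejection Drop all sessions after the first failing
#'   one and mark the series terminated early.
#' @param attribute Attribute label for the generated series.
#' @param packaging Packaging label for the generated series.
#' @rdname decay_scenario
#' @export
panel_scenario <- function(decay = decay_scenario(times = seq(0, 24, by = 3)),
                           n_consumers = 50L, consumer_sd = 1.5,
                           threshold = 5.0, censor_after_rejection = TRUE,
                           attribute = "color_acceptance",
                           packaging = "synthetic") {
  stopifnot(inherits(decay, "decay_scenario"))
  if (n_consumers < 1) skn_stop("n_consumers must be >= 1",
                                "shelfkin_domain_error")
  if (consumer_sd < 0) skn_stop("consumer_sd must be >= 0",
                                "shelfkin_domain_error")
  structure(
    list(decay = decay, n_consumers = as.integer(n_consumers),
         consumer_sd = consumer_sd, threshold = threshold,
         censor_after_rejection = isTRUE(censor_after_rejection),
         attribute = attribute, packaging = packaging),
    class = "panel_scenario"
  )
}

decay_mean <- function(scenario, k, t) {
  predict_quality(scenario$order, t = t, q0 = scenario$q0, k = k)
}

scenario_k <- function(scenario, temperature_c) {
  k <- scenario$k_by_temperature[as.character(temperature_c)]
  if (is.na(k)) {
    skn_stop(sprintf("temperature %g °C is not in the scenario map",
                     temperature_c),
             "shelfkin_lookup_error")
  }
  unname(k)
}

# Each temperature gets its own reproducible RNG substream so a single
# series can be regenerated without generating the whole study.
temp_seed <- function(scenario, temperature_c) {
  idx <- match(as.character(temperature_c),
               names(scenario$k_by_temperature))
  scenario$seed + (idx - 1L)
}

#' Generate one noisy instrumental decay series
#'
#' @param scenario A `decay_scenario`.
#' @param temperature_c One of the scenario's temperatures.
#' @return A [quality_series()] with values on the model curve plus
#'   Gaussian noise; identical scenario and seed give identical output.
#' @examples
#' sc <- decay_scenario(noise_sd = 0, seed = 7)
#' generate_decay_series(sc, 25)
#' @export
generate_decay_series <- function(scenario, temperature_c) {
  stopifnot(inherits(scenario, "decay_scenario"))
  k <- scenario_k(scenario, temperature_c)
  set.seed(temp_seed(scenario, temperature_c))
  mu <- decay_mean(scenario, k, scenario$times)
  value <- mu + rnorm(length(mu), 0, scenario$noise_sd)
  quality_series(
    time_weeks = scenario$times, value = value,
    attribute = "synthetic_quality", packaging = "synthetic",
    temperature_c = temperature_c, baseline = scenario$q0
  )
}

#' Generate a consumer-panel storage study
#'
#' Simulates the full multi-temperature panel design: per temperature and
#' session, `n_consumers` individual hedonic scores are drawn as
#' `Normal(model mean, consumer_sd)`, clipped to `[1, 9]`, rounded to whole
#' points, and summarised as mean, sd and n. With
#' `censor_after_rejection = TRUE`, sessions after the first one whose mean
#' falls strictly below the threshold are dropped and the series flagged as
#' terminated early — the censoring pattern of real storage tables.
#'
#' @param scenario A `panel_scenario`.
#' @return A [storage_dataset()] with one sensory series per temperature
#'   and the scenario's `q0` as the attribute baseline.
#' @export
generate_panel_study <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  dec <- scenario$decay
  sessions <- dec$times[dec$times > 0]
  temps <- as.numeric(names(dec$k_by_temperature))
  rows <- list()
  for (tc in temps) {
    k <- scenario_k(dec, tc)
    set.seed(temp_seed(dec, tc))
    mu <- decay_mean(dec, k, sessions)
    m <- s <- numeric(length(sessions))
    for (i in seq_along(sessions)) {
      scores <- rnorm(scenario$n_consumers, mu[i], scenario$consumer_sd)
      scores <- round(pmin(9, pmax(1, scores)))
      m[i] <- mean(scores)
      s[i] <- stats::sd(scores)
    }
    keep <- seq_along(sessions)
    terminated <- FALSE
    if (scenario$censor_after_rejection) {
      fail <- which(m < scenario$threshold)
      if (length(fail) > 0 && fail[1] < length(sessions)) {
        keep <- seq_len(fail[1])
        terminated <- TRUE
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      attribute = scenario$attribute, packaging = scenario$packaging,
      temperature_c = tc, time_weeks = sessions[keep],
      value = m[keep], sd = s[keep], n = scenario$n_consumers,
      below_detection = FALSE,
      terminated = terminated & keep == max(keep)
    )
  }
  storage_dataset(dplyr::bind_rows(rows),
                  baseline = setNames(dec$q0, scenario$attribute))
}

#' Generate an exact Arrhenius family of rate points
#'
#' Builds rate constants obeying
#' \eqn{k(T) = k_{ref} \exp(-E_a/R \cdot (1/T - 1/T_{ref}))} exactly, the
#' noise-free multi-temperature design used for round-trip testing of
#' [fit_arrhenius()].
#'
#' @param ea_kj_mol Activation energy, kJ/mol (non-negative).
#' @param k_ref Rate constant at the reference temperature (positive).
#' @param t_ref_c Reference temperature, degrees Celsius.
#' @param temps Temperatures (Celsius) at which to evaluate `k`.
#' @return A tibble of rate points with columns `temperature_c`, `k`.
#' @examples
#' pts <- generate_arrhenius_study(45.74, k_ref = 0.047, t_ref_c = 45,
#'                                 temps = c(4, 25, 35, 45))
#' fit_arrhenius(pts)
#' @export
generate_arrhenius_study <- function(ea_kj_mol, k_ref, t_ref_c,
                                     temps = c(4, 25, 35, 45)) {
  if (ea_kj_mol < 0) skn_stop("ea_kj_mol must be >= 0",
                              "shelfkin_domain_error")
  if (k_ref <= 0) skn_stop("k_ref must be positive", "shelfkin_domain_error")
  inv <- 1 / (temps + .C_TO_K) - 1 / (t_ref_c + .C_TO_K)
  tibble::tibble(
    temperature_c = temps,
    k = k_ref * exp(-ea_kj_mol * 1000 / .R_GAS * inv)
  )
}
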