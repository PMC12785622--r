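#' Storage-study datasets
#'
#' A `storage_dataset` holds the quality observations of one storage study in
#' tidy long format: one row per measured attribute, packaging, storage
#' temperature and storage week, together with per-series metadata (whether a
#' series was cut short because the product's shelf life ended) and optional
#' week-0 baseline values per attribute.
#'
#' @param observations A data frame with columns `attribute`, `packaging`,
#'   `temperature_c`, `time_weeks`, `value`, and optionally `sd`, `n`,
#'   `below_detection` (logical) and `terminated` (logical/0-1; any `TRUE`
#'   row marks its series as terminated early).
#' @param baseline Optional week-0 baseline values: either a named numeric
#'   vector (names are attribute labels) or a data frame with columns
#'   `attribute`, `value` and optionally `sd`, `n`.
#'
#' @return An object of class `storage_dataset` with components
#'   `observations` (tibble, sorted by series and week), `series` (tibble of
#'   per-series metadata including `terminated_early`) and `baseline`
#'   (tibble).
#'
#' @details Sensory attributes are hedonic means on the 1--9 scale, so their
#'   baselines must lie in `[1, 9]`. Observation times must be non-negative
#'   and unique within a series; detection-limit records are kept but flagged
#'   with `below_detection = TRUE` so that kinetic fitting and maximum
#'   statistics can exclude them.
#'
#' @seealso [load_quality_csv()], [extract_series()], [builtin_fixture()]
#' @export
storage_dataset <- function(observations, baseline = NULL) {
  obs <- tibble::as_tibble(observations)
  required <- c("attribute", "packaging", "temperature_c", "time_weeks", "value")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    skn_stop(paste0("observations lack column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "shelfkin_parse_error")
  }
  if (!"sd" %in% names(obs)) obs$sd <- NA_real_
  if (!"n" %in% names(obs)) obs$n <- NA_real_
  if (!"below_detection" %in% names(obs)) obs$below_detection <- FALSE
  if (!"terminated" %in% names(obs)) obs$terminated <- FALSE
  obs$below_detection <- isTRUE_vec(obs$below_detection)
  obs$terminated <- isTRUE_vec(obs$terminated)

  validate_observations(obs)

  # A row with a missing value is a truncation/not-measured marker, never an
  # observation; it contributes only its `terminated` flag.
  marker <- is.na(obs$value)
  series <- obs |>
    dplyr::group_by(.data$attribute, .data$packaging, .data$temperature_c) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$value)),
      terminated_early = any(.data$terminated),
      .groups = "drop"
    )
  obs <- obs[!marker, , drop = FALSE]
  obs <- dplyr::arrange(obs, .data$attribute, .data$packaging,
                        .data$temperature_c, .data$time_weeks)
  obs$terminated <- NULL

  structure(
    list(
      observations = obs,
      series = series,
      baseline = as_baseline_tbl(baseline)
    ),
    class = "storage_dataset"
  )
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(ifelse(is.na(x), FALSE, x != 0))
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("1", "TRUE", "true", "T", "yes")
}

as_baseline_tbl <- function(baseline) {
  if (is.null(baseline)) {
    return(tibble::tibble(attribute = character(), value = double(),
                          sd = double(), n = double()))
  }
  if (is.numeric(baseline) && !is.null(names(baseline))) {
    baseline <- tibble::tibble(attribute = names(baseline),
                               value = unname(baseline))
  }
  baseline <- tibble::as_tibble(baseline)
  if (!all(c("attribute", "value") %in% names(baseline))) {
    skn_stop("baseline needs columns `attribute` and `value`",
             "shelfkin_parse_error")
  }
  if (!"sd" %in% names(baseline)) baseline$sd <- NA_real_
  if (!"n" %in% names(baseline)) baseline$n <- NA_real_
  sensory <- grepl("acceptance$", baseline$attribute)
  bad <- sensory & (baseline$value < 1 | baseline$value > 9)
  if (any(bad)) {
    skn_stop("sensory baseline values must lie in [1, 9]",
             "shelfkin_domain_error")
  }
  baseline[, c("attribute", "value", "sd", "n")]
}

validate_observations <- function(obs) {
  if (any(!is.na(obs$time_weeks) & obs$time_weeks < 0)) {
    skn_stop("time_weeks must be non-negative", "shelfkin_domain_error")
  }
  if (any(!is.na(obs$sd) & obs$sd < 0)) {
    skn_stop("sd must be non-negative when present", "shelfkin_domain_error")
  }
  if (any(!is.na(obs$n) & obs$n < 1)) {
    skn_stop("n must be at least 1 when present", "shelfkin_domain_error")
  }
  if (any(!is.na(obs$temperature_c) & obs$temperature_c <= -273.15)) {
    skn_stop("temperature_c must exceed absolute zero",
             "shelfkin_domain_error")
  }
  key <- paste(obs$attribute, obs$packaging, obs$temperature_c,
               obs$time_weeks, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- obs[dup, ][1, ]
    skn_stop(sprintf(
      "duplicate observation for (%s, %s, %g °C) at week %g",
      d$attribute, d$packaging, d$temperature_c, d$time_weeks),
      "shelfkin_duplicate_error")
  }
  invisible(obs)
}

#' @export
print.storage_dataset <- function(x, ...) {
  cat("<storage_dataset>\n")
  cat("  series:      ", nrow(x$series), "\n")
  cat("  observations:", nrow(x$observations), "\n")
  if (nrow(x$baseline) > 0) {
    cat("  baseline:    ",
        paste(sprintf("%s=%g", x$baseline$attribute, x$baseline$value),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a storage-study CSV
#'
#' Reads the tidy storage CSV dialect: UTF-8, comma-separated, header
#' `attribute, packaging, temperature_c, time_weeks, value, sd, n, qualifier,
#' terminated`. The `value` field may be empty (a "not measured" marker);
#' `qualifier` is empty or `lt` (the value is a detection limit, the record a
#' non-detect); `terminated` is 0/1 and marks series truncated because shelf
#' life ended. Lines starting with `#` are comments.
#'
#' @param path Path to the CSV file.
#' @param baseline Optional baseline specification passed on to
#'   [storage_dataset()].
#' @return A [storage_dataset()].
#' @examples
#' path <- system.file("extdata", "table2_sensory.csv", package = "shelfkin")
#' ds <- load_quality_csv(path)
#' ds
#' @export
load_quality_csv <- function(path, baseline = NULL) {
  if (!file.exists(path)) {
    skn_stop(paste0("file not found: ", path), "shelfkin_lookup_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#",
    progress = FALSE
  )
  required <- c("attribute", "packaging", "temperature_c", "time_weeks",
                "value")
  if (!all(required %in% names(raw))) {
    skn_stop(paste0("CSV header must contain: ",
                    paste(required, collapse = ", ")),
             "shelfkin_parse_error")
  }
  n_row <- nrow(raw)
  num_or_fail <- function(col, allow_empty = FALSE) {
    x <- trimws(ifelse(is.na(raw[[col]]), "", raw[[col]]))
    out <- suppressWarnings(as.numeric(x))
    bad <- which(x != "" & is.na(out))
    if (length(bad) > 0) {
      skn_stop(sprintf("line %d: field `%s` is not numeric: '%s'",
                       bad[1] + 1L, col, x[bad[1]]),
               "shelfkin_parse_error")
    }
    if (!allow_empty) {
      empty <- which(x == "")
      if (length(empty) > 0) {
        skn_stop(sprintf("line %d: field `%s` is empty", empty[1] + 1L, col),
                 "shelfkin_parse_error")
      }
    }
    out
  }
  if (n_row == 0) {
    return(storage_dataset(tibble::tibble(
      attribute = character(), packaging = character(),
      temperature_c = double(), time_weeks = double(), value = double()
    ), baseline = baseline))
  }
  qualifier <- if ("qualifier" %in% names(raw)) {
    trimws(ifelse(is.na(raw$qualifier), "", raw$qualifier))
  } else rep("", n_row)
  bad_q <- which(!qualifier %in% c("", "lt"))
  if (length(bad_q) > 0) {
    skn_stop(sprintf("line %d: unknown qualifier '%s' (expected '' or 'lt')",
                     bad_q[1] + 1L, qualifier[bad_q[1]]),
             "shelfkin_parse_error")
  }
  obs <- tibble::tibble(
    attribute = raw$attribute,
    packaging = raw$packaging,
    temperature_c = num_or_fail("temperature_c"),
    time_weeks = num_or_fail("time_weeks"),
    value = num_or_fail("value", allow_empty = TRUE),
    sd = if ("sd" %in% names(raw)) num_or_fail("sd", TRUE) else NA_real_,
    n = if ("n" %in% names(raw)) num_or_fail("n", TRUE) else NA_real_,
    below_detection = qualifier == "lt",
    terminated = if ("terminated" %in% names(raw)) {
      isTRUE_vec(raw$terminated)
    } else FALSE
  )
  blank_pkg <- which(is.na(obs$packaging) | trimws(obs$packaging) == "")
  if (length(blank_pkg) > 0) {
    skn_stop(sprintf("line %d: packaging label is empty", blank_pkg[1] + 1L),
             "shelfkin_parse_error")
  }
  storage_dataset(obs, baseline = baseline)
}

#' Write a storage-study CSV
#'
#' Writes the same CSV dialect that [load_quality_csv()] reads. For series
#' that were terminated early, the last observation row carries
#' `terminated = 1` so a round trip preserves the flag.
#'
#' @param dataset A [storage_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quality_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "storage_dataset"))
  obs <- dataset$observations
  out <- tibble::tibble(
    attribute = obs$attribute,
    packaging = obs$packaging,
    temperature_c = obs$temperature_c,
    time_weeks = obs$time_weeks,
    value = obs$value,
    sd = obs$sd,
    n = obs$n,
    qualifier = ifelse(obs$below_detection, "lt", ""),
    terminated = 0L
  )
  term <- dataset$series[dataset$series$terminated_early, , drop = FALSE]
  for (i in seq_len(nrow(term))) {
    idx <- which(out$attribute == term$attribute[i] &
                   out$packaging == term$packaging[i] &
                   out$temperature_c == term$temperature_c[i])
    if (length(idx) > 0) out$terminated[idx[which.max(out$time_weeks[idx])]] <- 1L
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Extract one quality series from a dataset
#'
#' @param dataset A [storage_dataset()].
#' @param attribute Attribute label, e.g. `"color_acceptance"`.
#' @param packaging Packaging label, e.g. `"al_bag_n2"`.
#' @param temperature_c Storage temperature in degrees Celsius.
#' @return A `quality_series` object (see [quality_series()]). If the dataset
#'   carries a week-0 baseline for the attribute, it is attached to the
#'   series so kinetic fits can optionally include it.
#' @export
extract_series <- function(dataset, attribute, packaging, temperature_c) {
  stopifnot(inherits(dataset, "storage_dataset"))
  info <- dataset$series
  hit <- info$attribute == attribute & info$packaging == packaging &
    info$temperature_c == temperature_c
  if (!any(hit)) {
    skn_stop(sprintf("no series for (%s, %s, %g °C)",
                     attribute, packaging, temperature_c),
             "shelfkin_lookup_error")
  }
  obs <- dataset$observations
  rows <- obs$attribute == attribute & obs$packaging == packaging &
    obs$temperature_c == temperature_c
  obs <- obs[rows, , drop = FALSE]
  b <- dataset$baseline$value[dataset$baseline$attribute == attribute]
  quality_series(
    time_weeks = obs$time_weeks, value = obs$value, sd = obs$sd, n = obs$n,
    below_detection = obs$below_detection,
    attribute = attribute, packaging = packaging,
    temperature_c = temperature_c,
    terminated_early = info$terminated_early[hit][1],
    baseline = if (length(b) > 0) b[1] else NULL
  )
}

#' Construct a quality series
#'
#' An ordered, possibly censored time series of one quality attribute under
#' one packaging \eqn{\times}{x} temperature condition. This is the unit that
#' the kinetic fitting functions operate on.
#'
#' @param time_weeks Non-negative storage times, strictly increasing.
#' @param value Attribute values (hedonic score, L*, cfu/g, ...).
#' @param sd,n Optional per-observation standard deviation and panel size.
#' @param below_detection Logical; `TRUE` marks detection-limit records.
#' @param attribute,packaging,temperature_c Series identity.
#' @param terminated_early `TRUE` if measurement stopped because shelf life
#'   ended (the censoring pattern of sensory storage tables).
#' @param baseline Optional week-0 baseline value of the attribute.
#' @return A tibble of observations with class `quality_series` and the
#'   identity fields stored as attributes.
#' @export
quality_series <- function(time_weeks, value, sd = NULL, n = NULL,
                           below_detection = FALSE,
                           attribute = "quality", packaging = "unspecified",
                           temperature_c = NA_real_,
                           terminated_early = FALSE, baseline = NULL) {
  m <- length(time_weeks)
  if (length(value) != m) {
    skn_stop("time_weeks and value must have equal length",
             "shelfkin_domain_error")
  }
  if (any(time_weeks < 0)) {
    skn_stop("time_weeks must be non-negative", "shelfkin_domain_error")
  }
  if (m > 1 && any(diff(time_weeks) <= 0)) {
    skn_stop("observation times must be strictly increasing",
             "shelfkin_domain_error")
  }
  obs <- tibble::tibble(
    time_weeks = as.double(time_weeks),
    value = as.double(value),
    sd = if (is.null(sd)) NA_real_ else as.double(sd),
    n = if (is.null(n)) NA_real_ else as.double(n),
    below_detection = rep_len(as.logical(below_detection), m)
  )
  structure(obs,
            class = c("quality_series", class(obs)),
            attribute = attribute, packaging = packaging,
            temperature_c = temperature_c,
            terminated_early = isTRUE(terminated_early),
            baseline = baseline)
}

#' @export
print.quality_series <- function(x, ...) {
  cat(sprintf("<quality_series> %s | %s @ %g °C%s\n",
              attr(x, "attribute"), attr(x, "packaging"),
              attr(x, "temperature_c"),
              if (attr(x, "terminated_early")) " (terminated early)" else ""))
  if (!is.null(attr(x, "baseline"))) {
    cat(sprintf("  baseline (week 0): %g\n", attr(x, "baseline")))
  }
  print(tibble::as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Parse a microbial count, honouring detection limits
#'
#' Plate-count tables report either a measured count or a detection-limit
#' entry such as `"<2.5e-1"`. This parses both forms.
#'
#' @param text A single string: a positive number, or `"<"` followed by a
#'   positive number (scientific notation accepted).
#' @return A `microbial_count`: list with `value` (cfu/g, `NA` for
#'   non-detects), `qualifier` (`"measured"` or `"below_detection"`) and
#'   `limit` (the detection limit for non-detects).
#' @examples
#' parse_count("65")
#' parse_count("<2.5e-1")
#' @export
parse_count <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  x <- trimws(text)
  below <- startsWith(x, "<")
  payload <- if (below) trimws(substring(x, 2)) else x
  num <- suppressWarnings(as.numeric(payload))
  if (is.na(num)) {
    skn_stop(sprintf("cannot parse count '%s'", text), "shelfkin_parse_error")
  }
  if (num <= 0) {
    skn_stop("counts and detection limits must be positive",
             "shelfkin_parse_error")
  }
  microbial_count(
    value = if (below) NA_real_ else num,
    qualifier = if (below) "below_detection" else "measured",
    limit = if (below) num else NA_real_
  )
}

microbial_count <- function(value, qualifier, limit) {
  structure(list(value = value, qualifier = qualifier, limit = limit),
            class = "microbial_count")
}

#' @export
print.microbial_count <- function(x, ...) {
  if (x$qualifier == "measured") {
    cat(sprintf("<microbial_count> %g cfu/g\n", x$value))
  } else {
    cat(sprintf("<microbial_count> below detection (<%g cfu/g)\n", x$limit))
  }
  invisible(x)
}

#' Maximum measured microbial count for one attribute and packaging
#'
#' Scans every temperature and storage week of the given microbial attribute
#' and packaging and returns the largest *measured* count. Detection-limit
#' records do not compete with measured values; only when every record is a
#' non-detect is a below-detection result (with the largest limit) returned.
#'
#' @param dataset A [storage_dataset()].
#' @param attribute Microbial attribute label (e.g. `"tbc"`, `"ymc"`).
#' @param packaging Packaging label.
#' @return A `microbial_count`.
#' @examples
#' ds <- builtin_fixture("table1_microbial")
#' max_measured_count(ds, "tbc", "al_bag_n2")
#' @export
max_measured_count <- function(dataset, attribute, packaging) {
  stopifnot(inherits(dataset, "storage_dataset"))
  obs <- dataset$observations
  rows <- obs$attribute == attribute & obs$packaging == packaging
  if (!any(rows)) {
    skn_stop(sprintf("no series for attribute '%s' and packaging '%s'",
                     attribute, packaging),
             "shelfkin_lookup_error")
  }
  obs <- obs[rows, , drop = FALSE]
  measured <- obs[!obs$below_detection, , drop = FALSE]
  if (nrow(measured) > 0) {
    microbial_count(max(measured$value), "measured", NA_real_)
  } else {
    microbial_count(NA_real_, "below_detection", max(obs$value))
  }
}

#' CIE76 colour difference
#'
#' Total colour change \eqn{\Delta E} between two CIELAB coordinates,
#' computed as the Euclidean distance
#' \eqn{\sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}}.
#'
#' @param obs,ref Numeric length-3 vectors `c(L, a, b)`; `ref` is typically
#'   the week-0 measurement of the same storage condition.
#' @return Non-negative colour difference (CIE76 units).
#' @examples
#' delta_e(c(3, 4, 0), c(0, 0, 0)) # 5
#' @export
delta_e <- function(obs, ref) {
  stopifnot(length(obs) == 3, length(ref) == 3)
  if (!all(is.finite(obs)) || !all(is.finite(ref))) {
    skn_stop("colour coordinates must be finite", "shelfkin_domain_error")
  }
  sqrt(sum((as.numeric(obs) - as.numeric(ref))^2))
}
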