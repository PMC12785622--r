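#' Packaged storage-study fixtures
#'
#' The package ships the digitized tables of a 24-week storage study of
#' intermediate-moisture longan packed three ways (nitrogen-flushed aluminum
#' laminate `al_bag_n2`, air-packed aluminum laminate `al_bag_air`, clear
#' plastic `clear_plastic`) and stored at 4, 25, 35 and 45 degrees Celsius:
#'
#' * `table1_microbial` — total bacterial and yeast/mold counts (cfu/g) with
#'   detection-limit records (`<0.25`), as a [storage_dataset()].
#' * `table2_sensory` — 9-point hedonic means (overall, color, flavor;
#'   N = 50 consumers, every 3 weeks), censored once shelf life ended, as a
#'   [storage_dataset()] with the week-0 baselines attached.
#' * `table3_Lstar_k` — published zero/first-order rate constants for L*
#'   lightness change (tibble).
#' * `table4_color_k` — published zero/first-order rate constants for the
#'   color-acceptance score (tibble). One off-scale cell per table is kept
#'   verbatim and flagged `scale_suspect` in the `note` column.
#' * `table5_shelf_life` — published actual vs predicted shelf life (tibble;
#'   open bounds encoded as `actual_bound` of `greater_than`/`less_than`).
#' * `baselines` — week-0 initial values per attribute (tibble).
#'
#' @param name One of `"table1_microbial"`, `"table2_sensory"`,
#'   `"table3_Lstar_k"`, `"table4_color_k"`, `"table5_shelf_life"`,
#'   `"baselines"`.
#' @return A [storage_dataset()] for the observation tables, otherwise a
#'   tibble.
#' @examples
#' ds <- builtin_fixture("table2_sensory")
#' extract_series(ds, "color_acceptance", "clear_plastic", 25)
#' @export
builtin_fixture <- function(name) {
  known <- c("table1_microbial", "table2_sensory", "table3_Lstar_k",
             "table4_color_k", "table5_shelf_life", "baselines")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    skn_stop(paste0("unknown fixture; expected one of: ",
                    paste(known, collapse = ", ")),
             "shelfkin_lookup_error")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "shelfkin",
                      mustWork = TRUE)
  switch(
    name,
    table2_sensory = load_quality_csv(path, baseline = fixture_baselines()),
    table1_microbial = load_quality_csv(path),
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

fixture_baselines <- function() {
  path <- system.file("extdata", "baselines.csv", package = "shelfkin",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Look up a published rate constant
#'
#' Convenience accessor over the `table3_Lstar_k` / `table4_color_k`
#' fixtures.
#'
#' @param packaging Packaging label.
#' @param temperature_c Storage temperature in degrees Celsius.
#' @param order `"first"` (default) or `"zero"`.
#' @param table Which published table to use; the color-acceptance table by
#'   default.
#' @return The published rate constant (per week).
#' @export
printed_k <- function(packaging, temperature_c, order = "first",
                      table = c("table4_color_k", "table3_Lstar_k")) {
  table <- match.arg(table)
  tbl <- builtin_fixture(table)
  hit <- tbl$packaging == packaging & tbl$temperature_c == temperature_c &
    tbl$order == order
  if (!any(hit)) {
    skn_stop(sprintf("no published k for (%s, %g °C, %s order)",
                     packaging, temperature_c, order),
             "shelfkin_lookup_error")
  }
  tbl$k[hit][1]
}
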