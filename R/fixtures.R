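fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nutrieval")
  if (!nzchar(p)) abort(paste0("bundled fixture not found: ", file))
  p
}

read_fixture_csv <- function(file) {
  readr::read_csv(fixture_path(file),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

# Fixtures whose value column may carry ND / <x / None tokens.
parse_value_fixture <- function(tbl) {
  parsed <- parse_measurement(tbl$value)
  tbl$mean <- parsed$value
  tbl$censor <- parsed$censor
  tbl$limit <- parsed$limit
  tbl$value <- NULL
  tbl$ci95 <- as.numeric(tbl$ci95)
  dplyr::relocate(tbl, "mean", "ci95", "censor", "limit", .after = "analyte")
}

#' Load a bundled composition or growth fixture
#'
#' The published composition and growth tables for isopod meal, Antarctic krill
#' meal and white fish meal ship with the package as plain-text fixtures; every
#' printed cell (mean, 95% CI half-width, significance letter, censoring token)
#' appears verbatim. Available names:
#'
#' * `"table2"` — amino acid composition (g/100 g dry weight) with
#'   essential/flavor flags and the printed aggregate rows (`aggregate = TRUE`).
#' * `"table3_patterns"` — FAO/WHO and whole-egg reference amino acid patterns
#'   (mg per g nitrogen) over the 8 scoring categories.
#' * `"table3_scores"` — the printed AAS/CS/EAAI values (reference metadata for
#'   cross-checking, not inputs to any computation).
#' * `"table4"` — fatty acid composition (% of total fatty acids).
#' * `"table5"` — vitamins, with `ND` and `"<x"` censoring.
#' * `"table6"` — minerals (mg/kg; total phosphorus in %).
#' * `"growth_points"` — printed mean body weights (mg) by days after hatching.
#' * `"example_panel"` — a small synthetic replicate panel illustrating the
#'   `rep1..repK` on-disk format (returned via [read_panel()]).
#'
#' @param name fixture name, see above.
#' @return A tibble (a `nutrient_panel` for `"example_panel"`).
#' @examples
#' load_fixture("table3_patterns")
#' @export
load_fixture <- function(name) {
  switch(name,
    table2 = {
      tbl <- read_fixture_csv("table2_amino_acids.csv")
      tbl |>
        dplyr::mutate(mean = as.numeric(.data$mean),
                      ci95 = as.numeric(.data$ci95),
                      essential = .data$essential == "TRUE",
                      flavor = .data$flavor == "TRUE",
                      aggregate = .data$aggregate == "TRUE")
    },
    table3_patterns = read_fixture_csv("table3_patterns.csv") |>
      dplyr::mutate(mg_per_gN = as.numeric(.data$mg_per_gN)),
    table3_scores = read_fixture_csv("table3_scores.csv") |>
      dplyr::mutate(value = as.numeric(.data$value)),
    table4 = read_fixture_csv("table4_fatty_acids.csv") |>
      dplyr::mutate(aggregate = .data$aggregate == "TRUE") |>
      parse_value_fixture(),
    table5 = parse_value_fixture(read_fixture_csv("table5_vitamins.csv")),
    table6 = parse_value_fixture(read_fixture_csv("table6_minerals.csv")),
    growth_points = readr::read_csv(fixture_path("growth_points.csv"),
                                    col_types = "ddd", progress = FALSE),
    example_panel = read_panel(fixture_path("example_panel.csv")),
    abort(paste0("unknown fixture: '", name, "'"))
  )
}

#' Amino acid profile of one substrate
#'
#' Extracts the per-acid rows (aggregates dropped) of the bundled amino acid
#' table for one substrate, in the g/100 g dry-weight basis the scores are
#' computed from.
#'
#' @param substrate `"isopod"`, `"krill"` or `"fish"`.
#' @param table2 the amino acid table, defaulting to the bundled fixture. Any
#'   tibble with columns `substrate`, `analyte`, `mean`, `essential`, `flavor`,
#'   `aggregate` works, e.g. one assembled from [panel_summary()].
#' @return tibble with columns `analyte`, `content` (g/100 g), `essential`,
#'   `flavor`.
#' @examples
#' aa_profile("isopod")
#' @export
aa_profile <- function(substrate, table2 = load_fixture("table2")) {
  rows <- table2 |>
    dplyr::filter(.data$substrate == !!substrate, !.data$aggregate)
  if (nrow(rows) == 0) abort(paste0("no amino acid rows for substrate '", substrate, "'"))
  rows |>
    dplyr::transmute(analyte = .data$analyte, content = .data$mean,
                     essential = .data$essential, flavor = .data$flavor)
}

#' Published growth metrics (reference metadata)
#'
#' The printed growth-trial summary: power trendline coefficients, its r^2,
#' weight gain rate, specific growth rate and the trial endpoints. These are
#' reference values for comparison; the fixture of printed check-point means
#' ([load_fixture]`("growth_points")`) covers only 6 of the 15 check points, so
#' the trendline parameters cannot be recomputed from shipped data.
#'
#' @return one-row tibble.
#' @export
growth_reference <- function() {
  tibble::tibble(
    a = 0.1479, b = 1.8022, r2 = 0.9466,
    wgr_pct = 13026.76, sgr_pct_per_day = 6.97,
    initial_bw_mg = 0.24, final_bw_mg = 31.06, days = 70
  )
}
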