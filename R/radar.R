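#' Select the parameters of a category comparable across substrates
#'
#' The cross-substrate "highest value" comparison only makes sense for
#' parameters that were actually assayed everywhere on a common footing. A
#' parameter is retained when
#' * it is detected (`observed`) in at least one substrate,
#' * it is absent (not part of the substrate's profile at all, as opposed to
#'   assayed-but-not-detected) in at most `max_absent` substrates,
#' * its unit agrees across substrates and is not in `exclude_units`
#'   (by default `%`, which marks bulk proximate-style measures that do not
#'   compare with trace concentrations).
#'
#' @param tbl summary tibble with columns `substrate`, `analyte`, `mean`,
#'   `censor`, `unit` (e.g. a parsed fixture or [panel_summary()] output with
#'   a `censor` column). Aggregate rows should be removed beforehand.
#' @param max_absent drop a parameter absent in more substrates than this.
#' @param exclude_units units excluded from comparison.
#' @return character vector of retained parameter names, in table order.
#' @examples
#' comparable_parameters(load_fixture("table6"))
#' @export
comparable_parameters <- function(tbl, max_absent = 1, exclude_units = "%") {
  keep <- tbl |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n_absent = sum(.data$censor == "absent"),
      any_observed = any(.data$censor == "observed"),
      unit_ok = dplyr::n_distinct(.data$unit[.data$censor != "absent"]) == 1 &&
        !any(.data$unit %in% exclude_units),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$any_observed, .data$n_absent <= max_absent, .data$unit_ok)
  params <- intersect(unique(tbl$analyte), keep$analyte)
  if (length(params) == 0) abort("no comparable parameters in this category")
  params
}

#' Count the parameters each substrate wins
#'
#' For every retained parameter the substrate with the strictly highest mean
#' (censored values counting as zero) scores one win; ties share the win in
#' equal fractions and are flagged.
#'
#' @inheritParams comparable_parameters
#' @param parameters parameter names, typically from [comparable_parameters()].
#' @return tibble: `substrate`, `wins`, `ties` (number of tied parameters the
#'   substrate was part of), with attribute `n_parameters`.
#' @export
win_counts <- function(tbl, parameters = comparable_parameters(tbl)) {
  sub_levels <- unique(tbl$substrate)
  rows <- tbl |>
    dplyr::filter(.data$analyte %in% parameters) |>
    dplyr::mutate(score_value = dplyr::if_else(.data$censor == "observed",
                                               .data$mean, 0))
  wins <- setNames(rep(0, length(sub_levels)), sub_levels)
  ties <- setNames(rep(0L, length(sub_levels)), sub_levels)
  for (p in parameters) {
    d <- rows[rows$analyte == p, ]
    top <- d$substrate[d$score_value == max(d$score_value)]
    wins[top] <- wins[top] + 1 / length(top)
    if (length(top) > 1) ties[top] <- ties[top] + 1L
  }
  out <- tibble::tibble(substrate = sub_levels, wins = unname(wins[sub_levels]),
                        ties = unname(ties[sub_levels]))
  attr(out, "n_parameters") <- length(parameters)
  out
}

#' Convert win counts to 50/40/30 rank scores
#'
#' The substrate with the most wins scores 50, the second 40, the third 30.
#' Substrates tied on wins share the arithmetic mean of the scores of the
#' positions they span (e.g. two substrates tied for last share
#' `(40 + 30)/2 = 35`), and the tie is flagged. Scores always sum to 120.
#'
#' @param counts tibble from [win_counts()] (columns `substrate`, `wins`), or a
#'   named numeric vector of win counts.
#' @param scores score ladder, first rank first.
#' @return tibble: `substrate`, `wins`, `rank`, `score`, `tied`.
#' @examples
#' rank_scores(c(isopod = 6, krill = 2, fish = 1))
#' @export
rank_scores <- function(counts, scores = c(50, 40, 30)) {
  if (is.numeric(counts)) {
    counts <- tibble::tibble(substrate = names(counts), wins = unname(counts))
  }
  if (nrow(counts) != length(scores)) {
    abort(paste0("expected ", length(scores), " substrates"))
  }
  ord <- order(-counts$wins, counts$substrate)
  out <- counts[ord, c("substrate", "wins")]
  out$rank <- rank(-out$wins, ties.method = "min")
  pos_score <- scores[seq_len(nrow(out))]
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    tied_pos <- which(out$wins == out$wins[i])
    mean(pos_score[tied_pos])
  }, 0)
  out$tied <- duplicated(out$wins) | duplicated(out$wins, fromLast = TRUE)
  out
}

#' Assemble the radar comparison table
#'
#' Six factors summarise the overall comparison: the flavor and essential
#' amino acid ratios, the EAAI and the total PUFA enter with their actual
#' values; the vitamin and mineral categories enter as 50/40/30 rank scores
#' derived from win counts.
#'
#' @param faa_over_aa,eaa_over_aa,eaai_values,pufa named numeric vectors
#'   (names = substrates): actual-value factors, in percent (ratios), index
#'   units (EAAI) and % of total fatty acids (PUFA).
#' @param vitamin_counts,mineral_counts win-count tibbles ([win_counts()]) or
#'   named numeric vectors.
#' @return tibble of class `radar_table`: `factor`, `substrate`, `score`,
#'   `provenance` (`"actual value"` or `"rank score"`), `unit`.
#' @export
build_radar <- function(faa_over_aa, eaa_over_aa, eaai_values, pufa,
                        vitamin_counts, mineral_counts) {
  subs <- names(faa_over_aa)
  if (is.null(subs) || length(subs) == 0) abort("actual-value factors must be named by substrate")
  actuals <- list(
    "FAA/AA (%)" = list(v = faa_over_aa, unit = "%"),
    "EAA/AA (%)" = list(v = eaa_over_aa, unit = "%"),
    "EAAI" = list(v = eaai_values, unit = "index"),
    "Sum PUFA" = list(v = pufa, unit = "% of total FA")
  )
  rows <- purrr::imap_dfr(actuals, function(a, nm) {
    if (!setequal(names(a$v), subs)) abort(paste0("factor '", nm, "' misses substrates"))
    if (anyNA(a$v)) abort(paste0("factor '", nm, "' has missing values"))
    tibble::tibble(factor = nm, substrate = subs, score = unname(a$v[subs]),
                   provenance = "actual value", unit = a$unit)
  })
  ranked <- purrr::imap_dfr(list(Vitamins = vitamin_counts,
                                 Minerals = mineral_counts), function(cnt, nm) {
    rs <- rank_scores(cnt)
    if (!setequal(rs$substrate, subs)) abort(paste0("factor '", nm, "' misses substrates"))
    tibble::tibble(factor = nm, substrate = rs$substrate, score = rs$score,
                   provenance = "rank score", unit = "points")
  })
  out <- dplyr::bind_rows(rows, ranked)
  structure(out, class = c("radar_table", class(out)))
}

#' Radar table for the bundled composition tables
#'
#' Convenience wrapper assembling the full radar comparison from the shipped
#' fixtures: protein-quality reports per substrate, the printed total PUFA
#' values, and vitamin/mineral win counts from the comparability filter.
#'
#' @param substrates substrate labels present in the fixtures.
#' @return a `radar_table`, see [build_radar()].
#' @examples
#' radar_from_fixtures()
#' @export
radar_from_fixtures <- function(substrates = c("isopod", "krill", "fish")) {
  reports <- lapply(setNames(substrates, substrates),
                    function(s) protein_quality(aa_profile(s)))
  g <- purrr::imap_dfr(reports, function(r, s) {
    dplyr::bind_cols(tibble::tibble(substrate = s), glance(r))
  })
  t4 <- load_fixture("table4")
  pufa <- t4 |> dplyr::filter(.data$analyte == "SumPUFA")
  t5 <- load_fixture("table5")
  t6 <- load_fixture("table6")
  build_radar(
    faa_over_aa = setNames(g$faa_over_aa_pct, g$substrate),
    eaa_over_aa = setNames(g$eaa_over_aa_pct, g$substrate),
    eaai_values = setNames(g$eaai, g$substrate),
    pufa = setNames(pufa$mean, pufa$substrate),
    vitamin_counts = win_counts(t5),
    mineral_counts = win_counts(t6)
  )
}

#' Plot a radar table
#'
#' A polar line plot of the six factors; a thin visual layer over the tested
#' table.
#'
#' @param radar a `radar_table` from [build_radar()].
#' @return a ggplot object.
#' @export
plot_radar <- function(radar) {
  ggplot2::ggplot(radar,
                  ggplot2::aes(x = .data$factor, y = .data$score,
                               group = .data$substrate,
                               colour = .data$substrate)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "score / actual value")
}
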