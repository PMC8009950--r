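#' The eight amino acid scoring categories
#'
#' Protein-quality scoring pools methionine with cysteine and phenylalanine
#' with tyrosine, giving eight scored categories. Each element names the
#' profile analytes summed into the category.
#'
#' @return named list of character vectors.
#' @export
aa_scoring_categories <- function() {
  list(
    "Ile" = "Ile", "Leu" = "Leu", "Lys" = "Lys", "Thr" = "Thr",
    "Val" = "Val", "Trp" = "Trp",
    "Met+Cys" = c("Met", "Cys"), "Phe+Tyr" = c("Phe", "Tyr")
  )
}

#' Reference amino acid patterns
#'
#' The FAO/WHO scoring pattern and the whole-egg protein pattern, in mg of
#' amino acid per g nitrogen, over the eight scoring categories.
#'
#' @param name `"fao_who"` or `"egg"`.
#' @return tibble with columns `category`, `mg_per_gN`.
#' @examples
#' reference_pattern("egg")
#' @export
reference_pattern <- function(name = c("fao_who", "egg")) {
  name <- match.arg(name)
  pat <- load_fixture("table3_patterns") |>
    dplyr::filter(.data$pattern == name) |>
    dplyr::select("category", "mg_per_gN")
  stopifnot(nrow(pat) == 8, all(pat$mg_per_gN > 0))
  pat
}

#' Convert an amino acid profile to mg per g nitrogen
#'
#' Contents in g per 100 g are converted to mg of amino acid per g nitrogen by
#' the factor 62.5 (protein-to-nitrogen factor 6.25 x 10), after pooling the
#' member acids of each scoring category (Met+Cys, Phe+Tyr).
#'
#' @param profile tibble with columns `analyte`, `content` (g/100 g), e.g. from
#'   [aa_profile()].
#' @param categories named list mapping category to member analytes; defaults
#'   to [aa_scoring_categories()].
#' @param factor conversion factor from g/100 g to mg/g N.
#' @return tibble with columns `category`, `mg_per_gN`.
#' @examples
#' to_mg_per_g_n(aa_profile("isopod"))
#' @export
to_mg_per_g_n <- function(profile, categories = aa_scoring_categories(),
                          factor = 62.5) {
  members <- unlist(categories, use.names = FALSE)
  missing <- setdiff(members, profile$analyte)
  if (length(missing) > 0) {
    abort(paste0("profile lacks amino acid(s): ", paste(missing, collapse = ", ")))
  }
  if (any(profile$content < 0, na.rm = TRUE)) abort("negative amino acid content")
  tibble::tibble(
    category = names(categories),
    mg_per_gN = unname(purrr::map_dbl(categories, function(m) {
      sum(profile$content[profile$analyte %in% m]) * factor
    }))
  )
}

score_against <- function(sample, pattern, score_name) {
  joined <- dplyr::inner_join(sample, pattern, by = "category",
                              suffix = c("_sample", "_ref"))
  if (nrow(joined) < nrow(sample)) {
    absent <- setdiff(sample$category, pattern$category)
    abort(paste0("reference pattern lacks categor",
                 if (length(absent) > 1) "ies: " else "y: ",
                 paste(absent, collapse = ", ")))
  }
  if (any(joined$mg_per_gN_ref <= 0)) abort("reference pattern content must be > 0")
  out <- tibble::tibble(
    category = joined$category,
    sample_mg_per_gN = joined$mg_per_gN_sample,
    reference_mg_per_gN = joined$mg_per_gN_ref,
    score = joined$mg_per_gN_sample / joined$mg_per_gN_ref
  )
  out$score_2dp <- round_half_up(out$score, 2)
  names(out)[names(out) == "score"] <- score_name
  names(out)[names(out) == "score_2dp"] <- paste0(score_name, "_2dp")
  out
}

#' Amino acid score (AAS)
#'
#' Per-category ratio of the sample content (mg/g N) to the FAO/WHO reference
#' pattern: `AAS = aa / AA_FAO&WHO`. Reported unrounded and rounded half-up to
#' 2 decimals.
#'
#' @param sample tibble `category`, `mg_per_gN`, from [to_mg_per_g_n()].
#' @param pattern reference pattern tibble; defaults to the FAO/WHO pattern.
#' @return tibble with columns `category`, `sample_mg_per_gN`,
#'   `reference_mg_per_gN`, `aas`, `aas_2dp`.
#' @examples
#' amino_acid_score(to_mg_per_g_n(aa_profile("isopod")))
#' @export
amino_acid_score <- function(sample, pattern = reference_pattern("fao_who")) {
  score_against(sample, pattern, "aas")
}

#' Chemical score (CS)
#'
#' Per-category ratio of the sample content (mg/g N) to whole-egg protein:
#' `CS = aa / AA_egg`. Its minimum identifies the limiting amino acid.
#'
#' @inheritParams amino_acid_score
#' @param egg whole-egg reference pattern tibble.
#' @return tibble as [amino_acid_score()], score columns `cs`, `cs_2dp`.
#' @export
chemical_score <- function(sample, egg = reference_pattern("egg")) {
  score_against(sample, egg, "cs")
}

#' Essential amino acid index (EAAI)
#'
#' Geometric mean over the scoring categories of 100 x (sample / egg):
#' 100 means egg-equivalent essential amino acid balance. A zero sample
#' content in any category makes the index 0.
#'
#' @inheritParams chemical_score
#' @return a single number.
#' @examples
#' eaai(to_mg_per_g_n(aa_profile("fish")))
#' @export
eaai <- function(sample, egg = reference_pattern("egg")) {
  cs <- chemical_score(sample, egg)
  if (any(cs$cs == 0)) return(0)
  100 * exp(mean(log(cs$cs)))
}

#' Amino acid sums and ratios
#'
#' Totals of all, essential, non-essential and flavor amino acids (g/100 g)
#' and the percentage ratios EAA/AA, EAA/NEAA and FAA/AA, computed from the
#' per-acid contents and their `essential`/`flavor` flags. Taurine (analyte
#' `Tau`) is counted in the totals and in the flavor sum by default; set
#' `include_taurine = FALSE` for the protein-amino-acids-only convention.
#'
#' @param profile tibble with columns `analyte`, `content`, `essential`,
#'   `flavor`, e.g. [aa_profile()].
#' @param include_taurine include taurine in the AA and FAA totals?
#' @return one-row tibble: `sum_aa`, `sum_eaa`, `sum_neaa`, `sum_faa`,
#'   `eaa_over_aa_pct`, `eaa_over_neaa_pct`, `faa_over_aa_pct`.
#' @examples
#' aa_summaries(aa_profile("isopod"))
#' @export
aa_summaries <- function(profile, include_taurine = TRUE) {
  p <- profile
  if (!include_taurine) p <- dplyr::filter(p, .data$analyte != "Tau")
  sum_aa <- sum(p$content)
  sum_eaa <- sum(p$content[p$essential])
  sum_neaa <- sum_aa - sum_eaa
  sum_faa <- sum(p$content[p$flavor])
  tibble::tibble(
    sum_aa = sum_aa, sum_eaa = sum_eaa, sum_neaa = sum_neaa, sum_faa = sum_faa,
    eaa_over_aa_pct = if (sum_aa > 0) 100 * sum_eaa / sum_aa else 0,
    eaa_over_neaa_pct = if (sum_neaa > 0) 100 * sum_eaa / sum_neaa else NA_real_,
    faa_over_aa_pct = if (sum_aa > 0) 100 * sum_faa / sum_aa else 0
  )
}

#' Full protein-quality report for one amino acid profile
#'
#' Computes AAS against the FAO/WHO pattern, CS against whole-egg protein, the
#' EAAI, the first and second limiting categories (smallest CS; ties broken
#' alphabetically and reported as co-limiting), and the amino acid sums and
#' ratios.
#'
#' @inheritParams aa_summaries
#' @param fao FAO/WHO reference pattern.
#' @param egg whole-egg reference pattern.
#' @param categories scoring categories, see [aa_scoring_categories()]. Passing
#'   a different list (e.g. nine single acids) changes the scored categories
#'   and the EAAI accordingly.
#' @return object of class `protein_quality` with elements `scores` (per
#'   category: mg/g N, AAS, CS, rounded columns), `eaai`, `limiting` (ordered
#'   category names), `summaries`, `categories`.
#' @examples
#' pq <- protein_quality(aa_profile("isopod"))
#' glance(pq)
#' @export
protein_quality <- function(profile, fao = reference_pattern("fao_who"),
                            egg = reference_pattern("egg"),
                            categories = aa_scoring_categories(),
                            include_taurine = TRUE) {
  sample <- to_mg_per_g_n(profile, categories)
  aas <- amino_acid_score(sample, fao)
  cs <- chemical_score(sample, egg)
  scores <- dplyr::inner_join(
    aas, dplyr::select(cs, "category", "cs", "cs_2dp"), by = "category")
  ord <- order(cs$cs, cs$category)
  limiting <- cs$category[ord]
  co_limiting <- sum(cs$cs == min(cs$cs)) > 1
  structure(
    list(
      scores = scores,
      eaai = eaai(sample, egg),
      limiting = limiting,
      co_limiting = co_limiting,
      summaries = aa_summaries(profile, include_taurine = include_taurine),
      categories = categories
    ),
    class = "protein_quality"
  )
}

#' @export
print.protein_quality <- function(x, ...) {
  cat("Protein quality report (", length(x$categories), " scoring categories)\n",
      sep = "")
  print(x$scores, ...)
  cat(sprintf("EAAI: %.2f\nLimiting: %s, then %s%s\n",
              x$eaai, x$limiting[1], x$limiting[2],
              if (x$co_limiting) " (co-limiting tie)" else ""))
  invisible(x)
}

#' @rdname protein_quality
#' @param x a `protein_quality` object.
#' @param ... unused.
#' @export
tidy.protein_quality <- function(x, ...) {
  x$scores
}

#' @rdname protein_quality
#' @export
glance.protein_quality <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(eaai = x$eaai,
                   limiting_1 = x$limiting[1],
                   limiting_2 = x$limiting[2],
                   co_limiting = x$co_limiting),
    x$summaries
  )
}
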