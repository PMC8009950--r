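#' Parse measurement tokens
#'
#' Composition tables report a replicate either as a number, as `"ND"` (assayed
#' but not detected), as `"<x"` (detected below the quantification limit `x`),
#' or as `"None"` (the analyte is absent from the substrate's profile
#' altogether). Non-detects and below-limit values are carried as zero for
#' group statistics; the limit is retained so the original `"<x"` string can be
#' reproduced.
#'
#' @param token character vector of raw cell values.
#' @return A tibble with columns `value`, `censor`
#'   (`observed`/`not_detected`/`below_limit`/`absent`) and `limit`.
#' @examples
#' parse_measurement(c("9.45", "ND", "<0.05", "None"))
#' @export
parse_measurement <- function(token) {
  token <- trimws(as.character(token))
  out <- tibble::tibble(
    value = rep(NA_real_, length(token)),
    censor = rep("observed", length(token)),
    limit = rep(NA_real_, length(token))
  )
  is_nd <- !is.na(token) & toupper(token) == "ND"
  is_absent <- is.na(token) | token %in% c("None", "none", "NA", "")
  is_lt <- !is.na(token) & grepl("^<", token)
  out$censor[is_nd] <- "not_detected"
  out$value[is_nd] <- 0
  out$censor[is_absent] <- "absent"
  out$censor[is_lt] <- "below_limit"
  lim <- suppressWarnings(as.numeric(sub("^<\\s*", "", token[is_lt])))
  if (any(is.na(lim) | lim <= 0)) {
    abort("below-limit token must be '<x' with x > 0")
  }
  out$limit[is_lt] <- lim
  out$value[is_lt] <- 0
  plain <- !(is_nd | is_absent | is_lt)
  val <- suppressWarnings(as.numeric(token[plain]))
  if (any(is.na(val))) {
    bad <- token[plain][is.na(val)]
    abort(paste0("unparseable measurement token(s): ", paste(bad, collapse = ", ")))
  }
  if (any(val < 0)) {
    abort("negative measurement value is not allowed")
  }
  out$value[plain] <- val
  out
}

format_measurement <- function(value, censor, limit) {
  dplyr::case_when(
    censor == "not_detected" ~ "ND",
    censor == "absent" ~ "None",
    censor == "below_limit" ~ paste0("<", format(limit, trim = TRUE, scientific = FALSE)),
    TRUE ~ format(value, trim = TRUE, scientific = FALSE)
  )
}

new_nutrient_panel <- function(x) {
  structure(x, class = c("nutrient_panel", class(tibble::tibble())))
}

#' Read a replicate nutrient-composition panel
#'
#' The on-disk format is a delimited table with one row per substrate and
#' analyte and replicate measurements in columns `rep1..repK`:
#' `substrate, category, analyte, rep1, ..., repK, unit, basis`. Censoring
#' tokens `"ND"`, `"<x"` and `"None"` are parsed per [parse_measurement()].
#'
#' @param path path to a CSV file.
#' @param category optional category (`amino_acid`, `fatty_acid`, `vitamin`,
#'   `mineral`, `proximate`) used when the file lacks a `category` column.
#' @return A `nutrient_panel`: a long tibble with one row per replicate and
#'   columns `substrate`, `category`, `analyte`, `replicate`, `value`,
#'   `censor`, `limit`, `unit`, `basis`.
#' @examples
#' f <- system.file("extdata", "example_panel.csv", package = "nutrieval")
#' read_panel(f)
#' @export
read_panel <- function(path, category = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  rep_cols <- grep("^rep[0-9]+$", names(raw), value = TRUE)
  need <- c("substrate", "analyte", "unit", "basis")
  if (!all(need %in% names(raw)) || length(rep_cols) == 0) {
    abort("panel file must have columns substrate, analyte, rep1..repK, unit, basis")
  }
  if (!"category" %in% names(raw)) {
    if (is.null(category)) abort("file has no 'category' column and none was supplied")
    raw$category <- category
  }
  long <- tidyr::pivot_longer(raw, dplyr::all_of(rep_cols),
                              names_to = "replicate", values_to = "token")
  long$replicate <- as.integer(sub("^rep", "", long$replicate))
  parsed <- tryCatch(parse_measurement(long$token), error = function(e) {
    # re-parse row-wise only to name the offending row in the message
    for (i in seq_len(nrow(long))) {
      ok <- tryCatch({ parse_measurement(long$token[i]); TRUE },
                     error = function(e2) FALSE)
      if (!ok) {
        abort(paste0("malformed measurement for substrate '", long$substrate[i],
                     "', analyte '", long$analyte[i], "', replicate ",
                     long$replicate[i], ": ", conditionMessage(e)))
      }
    }
    abort(conditionMessage(e))
  })
  out <- dplyr::bind_cols(
    long[c("substrate", "category", "analyte", "replicate")],
    parsed,
    long[c("unit", "basis")]
  )
  new_nutrient_panel(out)
}

#' Write a nutrient panel back to its delimited format
#'
#' Inverse of [read_panel()]: replicates return to `rep1..repK` columns and
#' censored measurements to their `"ND"` / `"<x"` / `"None"` tokens, so that
#' `write_panel(read_panel(f))` is content-identical to `f`.
#'
#' @param panel a `nutrient_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  wide <- panel |>
    dplyr::mutate(token = format_measurement(.data$value, .data$censor, .data$limit),
                  replicate = paste0("rep", .data$replicate)) |>
    dplyr::select("substrate", "category", "analyte", "replicate", "token",
                  "unit", "basis") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "token") |>
    dplyr::relocate("unit", "basis", .after = dplyr::last_col())
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Summarise replicate measurements as mean and t-based 95% CI
#'
#' For every substrate x analyte the replicate values (censored replicates
#' counted as zero) are reduced to a mean, the replicate count and the
#' half-width of the t-based 95% confidence interval,
#' \eqn{t_{0.975, n-1} \, s / \sqrt{n}}. Analytes whose replicates are all
#' censored are flagged (`censored = TRUE`) and carry `NA` statistics rather
#' than a number.
#'
#' @param panel a `nutrient_panel`.
#' @return tibble with columns `substrate`, `category`, `analyte`, `mean`, `n`,
#'   `ci95`, `censored`, `unit`, `basis`.
#' @examples
#' f <- system.file("extdata", "example_panel.csv", package = "nutrieval")
#' panel_summary(read_panel(f))
#' @export
panel_summary <- function(panel) {
  panel |>
    dplyr::filter(.data$censor != "absent") |>
    dplyr::group_by(.data$substrate, .data$category, .data$analyte,
                    .data$unit, .data$basis) |>
    dplyr::summarise(
      n = dplyr::n(),
      censored = all(.data$censor != "observed"),
      mean = if (censored[1]) NA_real_ else mean(.data$value),
      ci95 = if (censored[1] || dplyr::n() < 2) {
        if (censored[1]) NA_real_ else 0
      } else {
        qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n())
      },
      .groups = "drop"
    ) |>
    dplyr::select("substrate", "category", "analyte", "mean", "n", "ci95",
                  "censored", "unit", "basis")
}
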