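#' Generate a synthetic replicate nutrient panel
#'
#' Emulates the replicate assay design: each analyte is measured `n_reps`
#' times per substrate with additive normal noise around a known true mean,
#' floored at zero (concentrations cannot be negative). Draws falling below an
#' analyte's quantification limit are emitted as below-limit measurements
#' carrying the limit, like the `"<x"` entries of real panels. A fixed seed
#' makes the output fully reproducible.
#'
#' @param truth tibble with columns `substrate`, `analyte`, `mean`, `sd`
#'   (the ground truth; `sd >= 0`).
#' @param n_reps replicates per substrate and analyte (study design: 3).
#' @param limits optional named numeric vector: quantification limit per
#'   analyte.
#' @param category,unit,basis panel metadata.
#' @param seed integer seed fixing all randomness.
#' @return a `nutrient_panel` (see [read_panel()]).
#' @examples
#' truth <- tidyr::crossing(substrate = c("A", "B"), analyte = c("Met", "Lys"))
#' truth <- dplyr::mutate(truth, mean = c(1, 2, 1.5, 2.5), sd = 0.05)
#' gen_panel(truth, seed = 1)
#' @export
gen_panel <- function(truth, n_reps = 3, limits = NULL, category = "amino_acid",
                      unit = "g/100g", basis = "dry_weight", seed = NULL) {
  stopifnot(all(c("substrate", "analyte", "mean", "sd") %in% names(truth)),
            all(truth$sd >= 0), n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  out <- truth |>
    tidyr::crossing(replicate = seq_len(n_reps)) |>
    dplyr::mutate(
      value = pmax(0, rnorm(dplyr::n(), .data$mean, .data$sd)),
      limit = if (is.null(limits)) NA_real_ else unname(limits[.data$analyte]),
      censor = dplyr::if_else(!is.na(.data$limit) & .data$value < .data$limit,
                              "below_limit", "observed"),
      value = dplyr::if_else(.data$censor == "below_limit", 0, .data$value),
      limit = dplyr::if_else(.data$censor == "below_limit", .data$limit, NA_real_),
      category = category, unit = unit, basis = basis
    ) |>
    dplyr::select("substrate", "category", "analyte", "replicate", "value",
                  "censor", "limit", "unit", "basis")
  new_nutrient_panel(out)
}

#' Generate synthetic power-law growth series
#'
#' Body weights follow `BW(t) = a * t^b * exp(e)` with `e ~ N(0, sigma^2)`
#' drawn independently per group and check point — multiplicative lognormal
#' noise, so weights stay positive and spread grows with size, as replicate
#' growth trials do.
#'
#' @param a,b power-law coefficient (mg / day^b) and exponent, both `> 0`.
#' @param times check-point ages in days (positive for fitting).
#' @param n_groups replicate groups per check point.
#' @param sigma multiplicative noise level on the log scale.
#' @param seed integer seed.
#' @return tibble: `dah`, `group`, `weight_mg`.
#' @examples
#' gen_growth(0.1479, 1.8022, times = seq(5, 70, by = 5), seed = 1)
#' @export
gen_growth <- function(a, b, times, n_groups = 3, sigma = 0.15, seed = NULL) {
  stopifnot(a > 0, b > 0, sigma >= 0, n_groups >= 1)
  if (!is.null(seed)) set.seed(seed)
  tidyr::crossing(dah = times, group = seq_len(n_groups)) |>
    dplyr::mutate(weight_mg = a * .data$dah^b *
                    exp(rnorm(dplyr::n(), 0, sigma)))
}

#' Generate near-consistent expert judgment matrices
#'
#' Builds reciprocal pairwise matrices around known true weights:
#' `a[j,k] = (w_j / w_k) * exp(d)` with `d ~ N(0, jitter^2)` on the upper
#' triangle, reciprocals filled below, entries clipped to the 1-9 scale range
#' `[1/9, 9]` (clipping preserves reciprocity). `jitter = 0` returns perfectly
#' consistent matrices that recover `true_weights` exactly.
#'
#' @param true_weights named positive weights, summing to 1.
#' @param jitter log-scale judgment noise, `>= 0`.
#' @param n_experts number of matrices.
#' @param seed integer seed.
#' @return list of judgment matrices (see [ahp_matrix()]).
#' @examples
#' gen_expert_matrices(c(a = 0.5, b = 0.3, c = 0.2), jitter = 0.05, seed = 1)
#' @export
gen_expert_matrices <- function(true_weights, jitter = 0.1, n_experts = 3,
                                seed = NULL) {
  stopifnot(all(true_weights > 0), jitter >= 0, n_experts >= 1)
  w <- true_weights / sum(true_weights)
  n <- length(w)
  items <- names(w) %||% paste0("item", seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_experts), function(e) {
    m <- diag(n)
    for (j in seq_len(n - 1)) {
      for (k in seq((j + 1), n)) {
        v <- (w[j] / w[k]) * exp(rnorm(1, 0, jitter))
        v <- min(max(v, 1 / 9), 9)
        m[j, k] <- v
        m[k, j] <- 1 / v
      }
    }
    ahp_matrix(m, items = items)
  })
}

#' Build a fully consistent AHP model from known global weights
#'
#' Constructs consistent judgment matrices (`a[j,k] = w_j / w_k`) from given
#' criteria weights and per-criterion alternative weights, so that
#' [ahp_synthesize()] recovers `sum_c w(c) w(alt|c)` exactly. Useful as a
#' construction oracle for testing the synthesis chain.
#'
#' @param criteria_weights named positive weights over criteria.
#' @param alt_weights named list (by criterion) of named positive weight
#'   vectors over alternatives.
#' @param n_experts how many identical experts to emit.
#' @return an [ahp_model()].
#' @export
gen_consistent_model <- function(criteria_weights, alt_weights, n_experts = 1) {
  consistent <- function(w) {
    w <- w / sum(w)
    m <- outer(w, w, `/`)
    ahp_matrix(m, items = names(w))
  }
  cm <- consistent(criteria_weights)
  am <- lapply(alt_weights, consistent)
  ahp_model(rep(list(cm), n_experts),
            rep(list(am), n_experts))
}
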