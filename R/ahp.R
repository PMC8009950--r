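#' Validate a pairwise comparison matrix
#'
#' A judgment matrix on the 1-9 scale must be square, have a unit diagonal,
#' be reciprocal (`a[j,k] * a[k,j] = 1`) and keep every entry within
#' `[1/9, 9]`.
#'
#' @param m numeric matrix; row/column names (if any) label the items.
#' @param items optional item labels; defaults to existing dimnames or
#'   `item1..itemn`.
#' @param tol tolerance for the reciprocity and diagonal checks.
#' @return the validated matrix with dimnames set, invisibly classed
#'   `ahp_matrix`.
#' @examples
#' ahp_matrix(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)))
#' @export
ahp_matrix <- function(m, items = NULL, tol = 1e-8) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || n < 2 || n > 10) abort("judgment matrix must be square, 2 <= n <= 10")
  if (any(!is.finite(m)) || any(m <= 0)) abort("judgment matrix entries must be positive")
  if (any(abs(diag(m) - 1) > tol)) abort("judgment matrix diagonal must be 1")
  if (any(abs(m * t(m) - 1) > tol * 10)) abort("judgment matrix is not reciprocal")
  if (any(m < 1 / 9 - tol | m > 9 + tol)) abort("entries must lie in [1/9, 9]")
  items <- items %||% rownames(m) %||% paste0("item", seq_len(n))
  dimnames(m) <- list(items, items)
  class(m) <- c("ahp_matrix", "matrix", "array")
  m
}

# Saaty's random consistency index by matrix order.
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (n < 1 || n > length(ri)) abort("random index defined for n <= 10")
  ri[n]
}

#' Eigenvector priorities and consistency of a judgment matrix
#'
#' Computes the principal right eigenvector by power iteration from the
#' uniform vector (deterministic start, convergence tolerance `1e-12` on the
#' normalised vector), the principal eigenvalue `lambda_max`, the consistency
#' index `CI = (lambda_max - n)/(n - 1)` and the consistency ratio `CR =
#' CI/RI` with Saaty's random-index table. A matrix is acceptably consistent
#' when `CR < 0.1`; 2 x 2 matrices are always consistent (`CR = 0`).
#'
#' @param m a judgment matrix (validated via [ahp_matrix()]).
#' @param tol convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return object of class `ahp_priorities`: `weights` (tibble `item`,
#'   `weight`, summing to 1), `lambda_max`, `ci`, `ri`, `cr`, `acceptable`,
#'   `n`.
#' @examples
#' pr <- ahp_priorities(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)))
#' tidy(pr)
#' glance(pr)
#' @export
ahp_priorities <- function(m, tol = 1e-12, max_iter = 10000L) {
  m <- ahp_matrix(m)
  n <- nrow(m)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w_new <- as.vector(m %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  lambda_max <- mean(as.vector(m %*% w) / w)
  ci <- max(0, (lambda_max - n) / (n - 1))
  ri <- saaty_ri(n)
  cr <- if (n <= 2) 0 else ci / ri
  structure(
    list(weights = tibble::tibble(item = rownames(m), weight = w / sum(w)),
         lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
         acceptable = cr < 0.1, n = n),
    class = "ahp_priorities"
  )
}

#' @export
print.ahp_priorities <- function(x, ...) {
  cat(sprintf("AHP priorities (n = %d, lambda_max = %.4f, CR = %.4f%s)\n",
              x$n, x$lambda_max, x$cr,
              if (x$acceptable) ", consistent" else ", INCONSISTENT"))
  print(x$weights, ...)
  invisible(x)
}

#' @rdname ahp_priorities
#' @param x an `ahp_priorities` object.
#' @param ... unused.
#' @export
tidy.ahp_priorities <- function(x, ...) x$weights

#' @rdname ahp_priorities
#' @export
glance.ahp_priorities <- function(x, ...) {
  tibble::tibble(n = x$n, lambda_max = x$lambda_max, ci = x$ci, ri = x$ri,
                 cr = x$cr, acceptable = x$acceptable)
}

#' Aggregate expert priority vectors
#'
#' Group judgment is synthesised as the element-wise arithmetic mean of the
#' per-expert priority vectors (optionally weighted), renormalised to sum 1.
#' All vectors must cover the same items.
#'
#' @param vectors list of tibbles with columns `item`, `weight` (e.g. the
#'   `weights` element of [ahp_priorities()]).
#' @param expert_weights optional non-negative weights, one per expert.
#' @return tibble `item`, `weight`.
#' @export
aggregate_experts <- function(vectors, expert_weights = NULL) {
  stopifnot(length(vectors) >= 1)
  items <- vectors[[1]]$item
  for (v in vectors) {
    if (!setequal(v$item, items)) abort("priority vectors cover different item sets")
  }
  ew <- expert_weights %||% rep(1, length(vectors))
  if (length(ew) != length(vectors) || any(ew < 0) || sum(ew) == 0) {
    abort("invalid expert weights")
  }
  ew <- ew / sum(ew)
  w <- Reduce(`+`, purrr::map2(vectors, ew, function(v, e) {
    e * v$weight[match(items, v$item)]
  }))
  tibble::tibble(item = items, weight = w / sum(w))
}

# Element-wise geometric mean of reciprocal matrices (stays reciprocal);
# the alternative group-aggregation convention.
aggregate_matrices_geomean <- function(mats) {
  stopifnot(length(mats) >= 1)
  logs <- lapply(mats, function(m) log(ahp_matrix(m)))
  exp(Reduce(`+`, logs) / length(mats))
}

#' Build an AHP model
#'
#' A two-level hierarchy: a goal, criteria compared pairwise under the goal,
#' and alternatives compared pairwise under each criterion, judged by one or
#' more experts.
#'
#' @param criteria_matrices list (one per expert) of judgment matrices over
#'   the criteria.
#' @param alternative_matrices list (one per expert) of named lists mapping
#'   each criterion to a judgment matrix over the alternatives.
#' @param goal goal label.
#' @return object of class `ahp_model`.
#' @export
ahp_model <- function(criteria_matrices, alternative_matrices,
                      goal = "nutritional value") {
  stopifnot(length(criteria_matrices) == length(alternative_matrices),
            length(criteria_matrices) >= 1)
  criteria_matrices <- lapply(criteria_matrices, ahp_matrix)
  criteria <- rownames(criteria_matrices[[1]])
  alternative_matrices <- lapply(alternative_matrices, function(am) {
    if (!setequal(names(am), criteria)) {
      abort("each expert must supply one alternatives matrix per criterion")
    }
    lapply(am[criteria], ahp_matrix)
  })
  alternatives <- rownames(alternative_matrices[[1]][[1]])
  structure(list(goal = goal, criteria = criteria, alternatives = alternatives,
                 criteria_matrices = criteria_matrices,
                 alternative_matrices = alternative_matrices,
                 n_experts = length(criteria_matrices)),
            class = "ahp_model")
}

#' Hierarchical synthesis of an AHP model
#'
#' For each expert, criteria weights and per-criterion alternative weights are
#' taken from the principal eigenvectors and combined as
#' `global(alt) = sum_c w(c) * w(alt | c)`; experts are then aggregated by
#' arithmetic vector averaging (default) or by synthesising the element-wise
#' geometric-mean matrices. Every matrix must pass the consistency check
#' (`CR < cr_threshold`) unless `override = TRUE`.
#'
#' @param model an [ahp_model()].
#' @param cr_threshold consistency ratio limit.
#' @param override synthesise even when some matrix fails the check.
#' @param aggregation `"vector_mean"` or `"matrix_geomean"`.
#' @param expert_weights optional per-expert weights (vector-mean aggregation).
#' @return object of class `ahp_synthesis`: `weights` (tibble `alternative`,
#'   `weight`, summing to 1), `criteria_weights`, `consistency` (per-matrix CR
#'   report), `per_expert` global vectors, `aggregation`.
#' @export
ahp_synthesize <- function(model, cr_threshold = 0.1, override = FALSE,
                           aggregation = c("vector_mean", "matrix_geomean"),
                           expert_weights = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(model, "ahp_model"))
  report <- list(); cons <- list()
  add_cons <- function(label, pr) {
    cons[[length(cons) + 1]] <<- dplyr::bind_cols(
      tibble::tibble(matrix = label), glance(pr))
  }
  if (aggregation == "matrix_geomean") {
    cmat <- aggregate_matrices_geomean(model$criteria_matrices)
    crit_pr <- ahp_priorities(cmat)
    add_cons("criteria (group geomean)", crit_pr)
    alt_pr <- lapply(model$criteria, function(cr) {
      am <- aggregate_matrices_geomean(
        lapply(model$alternative_matrices, `[[`, cr))
      pr <- ahp_priorities(am)
      add_cons(paste0("alternatives | ", cr, " (group geomean)"), pr)
      pr$weights
    })
    names(alt_pr) <- model$criteria
    crit_w <- crit_pr$weights
    gl <- global_from(crit_w, alt_pr, model$alternatives)
    per_expert <- list(gl)
  } else {
    per_expert <- vector("list", model$n_experts)
    crit_vecs <- vector("list", model$n_experts)
    for (e in seq_len(model$n_experts)) {
      crit_pr <- ahp_priorities(model$criteria_matrices[[e]])
      add_cons(paste0("expert ", e, ": criteria"), crit_pr)
      alt_w <- lapply(model$criteria, function(cr) {
        pr <- ahp_priorities(model$alternative_matrices[[e]][[cr]])
        add_cons(paste0("expert ", e, ": alternatives | ", cr), pr)
        pr$weights
      })
      names(alt_w) <- model$criteria
      crit_vecs[[e]] <- crit_pr$weights
      per_expert[[e]] <- global_from(crit_pr$weights, alt_w, model$alternatives)
    }
    crit_w <- aggregate_experts(crit_vecs, expert_weights)
    gl_tbls <- lapply(per_expert, function(g) {
      tibble::tibble(item = g$alternative, weight = g$weight)
    })
    agg <- aggregate_experts(gl_tbls, expert_weights)
    gl <- tibble::tibble(alternative = agg$item, weight = agg$weight)
  }
  consistency <- dplyr::bind_rows(cons)
  bad <- consistency[consistency$cr >= cr_threshold, ]
  if (nrow(bad) > 0 && !override) {
    abort(paste0("inconsistent judgment matrix (CR >= ", cr_threshold, "): ",
                 paste(sprintf("%s (CR = %.4f)", bad$matrix, bad$cr),
                       collapse = "; "),
                 ". Revise the judgments or synthesise with override = TRUE."))
  }
  structure(list(weights = gl, criteria_weights = crit_w,
                 consistency = consistency, per_expert = per_expert,
                 aggregation = aggregation, goal = model$goal),
            class = "ahp_synthesis")
}

global_from <- function(crit_w, alt_w_by_crit, alternatives) {
  gw <- setNames(rep(0, length(alternatives)), alternatives)
  for (cr in crit_w$item) {
    aw <- alt_w_by_crit[[cr]]
    gw[aw$item] <- gw[aw$item] + crit_w$weight[crit_w$item == cr] * aw$weight
  }
  tibble::tibble(alternative = names(gw), weight = unname(gw) / sum(gw))
}

#' @export
print.ahp_synthesis <- function(x, ...) {
  cat("AHP synthesis (", x$aggregation, "): ", x$goal, "\n", sep = "")
  print(x$weights, ...)
  invisible(x)
}

#' @rdname ahp_synthesize
#' @param x an `ahp_synthesis`.
#' @param ... unused.
#' @export
tidy.ahp_synthesis <- function(x, ...) x$weights

#' @rdname ahp_synthesize
#' @export
glance.ahp_synthesis <- function(x, ...) {
  tibble::tibble(aggregation = x$aggregation,
                 n_matrices = nrow(x$consistency),
                 max_cr = max(x$consistency$cr),
                 all_consistent = all(x$consistency$acceptable))
}

#' @rdname ahp_synthesize
#' @param object an `ahp_synthesis`.
#' @param ... unused.
#' @export
autoplot.ahp_synthesis <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(x = stats::reorder(.data$alternative, .data$weight),
                               y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "global priority weight", title = object$goal)
}

#' Read an AHP model from a YAML or JSON file
#'
#' The file lists `goal`, `criteria`, `alternatives` and `experts`; each
#' expert has a `criteria_matrix` (list of rows) and an `alternatives` map of
#' criterion to matrix rows.
#'
#' @param path file path.
#' @return an [ahp_model()].
#' @export
read_ahp_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  spec <- yaml::read_yaml(path)
  need <- c("criteria", "alternatives", "experts")
  if (!all(need %in% names(spec))) {
    abort("model file must define criteria, alternatives and experts")
  }
  to_matrix <- function(rows, items) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    ahp_matrix(m, items = items)
  }
  cms <- lapply(spec$experts, function(e) to_matrix(e$criteria_matrix, spec$criteria))
  ams <- lapply(spec$experts, function(e) {
    lapply(e$alternatives, to_matrix, items = spec$alternatives)
  })
  ahp_model(cms, ams, goal = spec$goal %||% "goal")
}
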