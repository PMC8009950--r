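split_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(v) || anyNA(g)) abort("missing values in group data")
  gd <- split(v, g)
  if (length(gd) < 2) abort("need at least 2 groups")
  if (any(lengths(gd) < 2)) abort("every group needs at least 2 replicates")
  gd
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper with the domain checks used throughout the pipeline: sample
#' size between 3 and 5000 and non-constant input.
#'
#' @param x numeric vector of replicate values.
#' @return one-row tibble: `statistic` (W), `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) abort("Shapiro-Wilk needs 3 <= n <= 5000")
  if (sd(x) == 0) abort("degenerate input: all values identical")
  ht <- shapiro.test(x)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(x))
}

#' Levene's test for homogeneity of variances
#'
#' The mean-centred variant: a one-way ANOVA F on the absolute deviations
#' `|x - group mean|`. Used as the gate between classical ANOVA + Duncan and
#' Welch ANOVA + Dunnett T3.
#'
#' @param data data frame of replicate values.
#' @param value,group columns holding the values and the group labels.
#' @return one-row tibble: `statistic`, `df1`, `df2`, `p_value`, `degenerate`
#'   (`TRUE` when every group has zero spread, in which case the statistic is 0).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 10, 20, 30))
#' levene_test(d, y, g)
#' @export
levene_test <- function(data, value, group) {
  gd <- split_groups(data, {{ value }}, {{ group }})
  z <- lapply(gd, function(x) abs(x - mean(x)))
  k <- length(z); n <- sum(lengths(z))
  zbar <- mean(unlist(z))
  ssb <- sum(lengths(z) * (vapply(z, mean, 0) - zbar)^2)
  ssw <- sum(vapply(z, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                          degenerate = TRUE))
  }
  stat <- if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = stat, df1 = df1, df2 = df2,
                 p_value = pf(stat, df1, df2, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' One-way ANOVA
#'
#' Classical between/within decomposition. For two groups the F statistic is
#' the square of the pooled-variance t statistic.
#'
#' @inheritParams levene_test
#' @return one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `ms_within` (the pooled error mean square reused by the
#'   post-hoc procedures).
#' @export
one_way_anova <- function(data, value, group) {
  gd <- split_groups(data, {{ value }}, {{ group }})
  k <- length(gd); n <- sum(lengths(gd))
  grand <- mean(unlist(gd))
  ssb <- sum(lengths(gd) * (vapply(gd, mean, 0) - grand)^2)
  ssw <- sum(vapply(gd, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1; df2 <- n - k
  msw <- ssw / df2
  stat <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df1) / msw
  p <- if (ssb == 0) 1 else pf(stat, df1, df2, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df_between = df1, df_within = df2,
                 p_value = p, ms_within = msw)
}

#' Welch's ANOVA (unequal variances)
#'
#' @inheritParams levene_test
#' @return one-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(data, value, group) {
  gd <- split_groups(data, {{ value }}, {{ group }})
  df <- data.frame(y = unlist(gd), g = rep(names(gd), lengths(gd)))
  ht <- oneway.test(y ~ g, data = df, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
                 p_value = ht$p.value)
}

# Duncan least-significant-range critical point for a span of p means:
# studentized range at protection level alpha_p = 1 - (1 - alpha)^(p - 1).
duncan_q <- function(p, df, alpha) {
  qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

# Step-down range decisions on means sorted ascending. A span is declared
# non-significant if its extremes differ by <= R_span or if it is contained in
# an already-retained non-significant span (protection). Returns a k x k
# logical matrix of significant pairs, in sorted-mean order.
duncan_decisions <- function(sorted_means, se, df, alpha) {
  k <- length(sorted_means)
  sig <- matrix(FALSE, k, k)
  ns_ranges <- list()
  for (span in seq(k, 2)) {
    r_crit <- duncan_q(span, df, alpha) * se
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      inside_ns <- any(vapply(ns_ranges, function(r) r[1] <= i && j <= r[2], TRUE))
      if (inside_ns) next
      if (sorted_means[j] - sorted_means[i] > r_crit) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        ns_ranges <- c(ns_ranges, list(c(i, j)))
      }
    }
  }
  sig
}

# Compact letter display by insert-absorb on a logical "differs" matrix whose
# rows/cols follow the display order of the groups. Guarantees: groups sharing
# a letter are never significantly different, and every non-significant pair
# shares at least one letter.
cld_insert_absorb <- function(labels, sig) {
  k <- length(labels)
  cols <- list(rep(TRUE, k))
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[b] && all(cols[[a]] <= cols[[b]]) &&
            !identical(cols[[a]], cols[[b]])) keep[a] <- FALSE
      }
    }
    # drop exact duplicates too
    cols <- cols[keep]
    cols[!duplicated(vapply(cols, paste, "", collapse = ""))]
  }
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!sig[i, j]) next
      hit <- which(vapply(cols, function(cc) cc[i] && cc[j], TRUE))
      for (h in hit) {
        c1 <- cols[[h]]; c1[j] <- FALSE
        c2 <- cols[[h]]; c2[i] <- FALSE
        cols[[h]] <- c1
        cols <- c(cols, list(c2))
      }
      cols <- absorb(cols)
    }
  }
  ord <- order(vapply(cols, function(cc) which(cc)[1], 1L))
  cols <- cols[ord]
  lets <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cc) cc[i], TRUE))], collapse = "")
  }, "")
  setNames(lets, labels)
}

group_summary_tbl <- function(gd) {
  tibble::tibble(
    group = names(gd),
    mean = unname(vapply(gd, mean, 0)),
    n = unname(lengths(gd)),
    ci95 = unname(vapply(gd, function(x) {
      qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
    }, 0))
  )
}

order_for_display <- function(summary, letters) {
  if (letters == "desc") order(-summary$mean, summary$group)
  else order(summary$mean, summary$group)
}

#' Duncan's multiple range test with compact letter display
#'
#' Computes the protected step-down range decisions with least significant
#' ranges from the studentized-range distribution at protection level
#' `1 - (1 - alpha)^(p-1)`, using the pooled ANOVA error mean square (harmonic
#' mean group size for unbalanced data, with a warning), and summarises the
#' decisions as letters: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @inheritParams levene_test
#' @param alpha significance level.
#' @param letters `"asc"` (default; letter `a` goes to the smallest mean) or
#'   `"desc"`.
#' @param protect only run the range test when the omnibus ANOVA is significant
#'   at `alpha`; otherwise all groups share one letter. Keeps the familywise
#'   type-I rate of the whole pipeline near `alpha`.
#' @return object of class `group_comparison`; see [compare_groups()].
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 3),
#'                 y = c(0, 1, -1, 100, 101, 99, 200, 201, 199))
#' tidy(duncan_letters(d, y, g))
#' @export
duncan_letters <- function(data, value, group, alpha = 0.05,
                           letters = c("asc", "desc"), protect = TRUE) {
  letters <- match.arg(letters)
  gd <- split_groups(data, {{ value }}, {{ group }})
  aov_row <- one_way_anova(data, {{ value }}, {{ group }})
  summ <- group_summary_tbl(gd)
  ord <- order_for_display(summ, letters)
  summ <- summ[ord, ]
  k <- nrow(summ)
  ns <- summ$n
  if (length(unique(ns)) > 1) {
    warn("unbalanced groups: using the harmonic mean group size for Duncan ranges")
  }
  n_h <- k / sum(1 / ns)
  se <- sqrt(aov_row$ms_within / n_h)
  rank_asc <- order(summ$mean)   # positions in ascending-mean order
  sorted_means <- summ$mean[rank_asc]
  gated <- protect && aov_row$p_value >= alpha
  sig_sorted <- if (gated || se == 0 && diff(range(sorted_means)) == 0) {
    matrix(FALSE, k, k)
  } else {
    duncan_decisions(sorted_means, se, aov_row$df_within, alpha)
  }
  # map back to display order
  pos <- match(seq_len(k), rank_asc)
  sig <- sig_sorted[pos, pos, drop = FALSE]
  lets <- cld_insert_absorb(summ$group, sig)
  pairs <- t(utils::combn(k, 2))
  pairwise <- tibble::tibble(
    group1 = summ$group[pairs[, 1]], group2 = summ$group[pairs[, 2]],
    difference = abs(summ$mean[pairs[, 1]] - summ$mean[pairs[, 2]]),
    span = abs(match(pairs[, 1], rank_asc) - match(pairs[, 2], rank_asc)) + 1,
    significant = sig[pairs]
  )
  pairwise$critical <- duncan_q(pairwise$span, aov_row$df_within, alpha) * se
  summ$letter <- unname(lets)
  new_group_comparison(method = "anova+duncan", omnibus = aov_row,
                       letters_tbl = summ, pairwise = pairwise,
                       alpha = alpha, gated = gated)
}

#' Fisher's LSD comparisons against a control group
#'
#' t-based pairwise comparisons of a control versus every other group using
#' the pooled ANOVA error mean square.
#'
#' @inheritParams duncan_letters
#' @param control label of the control group.
#' @return tibble: `group`, `difference` (group mean - control mean), `lsd`
#'   (the least significant difference at `alpha`), `t`, `p_value`,
#'   `significant`.
#' @export
lsd_pairwise <- function(data, value, group, control, alpha = 0.05) {
  gd <- split_groups(data, {{ value }}, {{ group }})
  if (!control %in% names(gd)) {
    abort(paste0("unknown control group: '", control, "'"))
  }
  aov_row <- one_way_anova(data, {{ value }}, {{ group }})
  others <- setdiff(names(gd), control)
  x0 <- gd[[control]]
  purrr::map_dfr(others, function(g) {
    se <- sqrt(aov_row$ms_within * (1 / length(x0) + 1 / length(gd[[g]])))
    d <- mean(gd[[g]]) - mean(x0)
    tcrit <- qt(1 - alpha / 2, aov_row$df_within)
    tstat <- if (se == 0) ifelse(d == 0, 0, Inf) else d / se
    tibble::tibble(group = g, difference = d, lsd = tcrit * se, t = tstat,
                   p_value = 2 * pt(abs(tstat), aov_row$df_within, lower.tail = FALSE),
                   significant = abs(d) > tcrit * se)
  })
}

#' Studentized maximum modulus quantile
#'
#' Quantile of `max(|T_1|, ..., |T_k|)` where the `T_i` are t variates sharing
#' one chi-based denominator with `df` degrees of freedom; the critical point
#' of Dunnett's T3. Computed by numerical integration of
#' `P(max|T| <= q) = int (2 Phi(q u) - 1)^k f_df(u) du` and root finding.
#'
#' @param p cumulative probability (e.g. `1 - alpha`).
#' @param k number of comparisons.
#' @param df degrees of freedom (may be fractional, per Welch-Satterthwaite).
#' @return the quantile.
#' @export
qsmm <- function(p, k, df) {
  stopifnot(p > 0, p < 1, k >= 1, df > 0)
  if (!is.finite(df)) {
    return(stats::qnorm((1 + p^(1 / k)) / 2))
  }
  lognc <- (df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2)
  cdf <- function(q) {
    integrate(function(u) {
      (2 * pnorm(q * u) - 1)^k * exp(lognc + (df - 1) * log(u) - df * u^2 / 2)
    }, 0, Inf, rel.tol = 1e-9)$value
  }
  uniroot(function(q) cdf(q) - p, lower = 1e-3, upper = 200, tol = 1e-9)$root
}

#' Dunnett's T3 all-pairs comparisons with compact letter display
#'
#' Pairwise Welch-type t statistics with per-pair Satterthwaite degrees of
#' freedom, judged against studentized-maximum-modulus critical points for the
#' `k(k-1)/2` comparisons. Intended for data that failed Levene's test; paired
#' with Welch's ANOVA as the omnibus.
#'
#' @inheritParams duncan_letters
#' @param protect only letter differences when Welch's ANOVA is significant at
#'   `alpha`.
#' @return object of class `group_comparison`.
#' @export
dunnett_t3 <- function(data, value, group, alpha = 0.05,
                       letters = c("asc", "desc"), protect = TRUE) {
  letters <- match.arg(letters)
  gd <- split_groups(data, {{ value }}, {{ group }})
  omn <- welch_anova(data, {{ value }}, {{ group }})
  summ <- group_summary_tbl(gd)
  ord <- order_for_display(summ, letters)
  summ <- summ[ord, ]
  k <- nrow(summ)
  vs <- unname(vapply(gd[summ$group], var, 0))
  ns <- summ$n
  m <- k * (k - 1) / 2
  pairs <- t(utils::combn(k, 2))
  gated <- protect && omn$p_value >= alpha
  pw <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    v1 <- vs[i] / ns[i]; v2 <- vs[j] / ns[j]
    d <- abs(summ$mean[i] - summ$mean[j])
    if (v1 + v2 == 0) {
      # zero spread in both groups: limit rule, flagged
      return(tibble::tibble(group1 = summ$group[i], group2 = summ$group[j],
                            difference = d, df = NA_real_, critical = 0,
                            significant = d > 0, zero_variance = TRUE))
    }
    df_pair <- (v1 + v2)^2 / (v1^2 / (ns[i] - 1) + v2^2 / (ns[j] - 1))
    crit <- qsmm(1 - alpha, m, df_pair) * sqrt(v1 + v2)
    tibble::tibble(group1 = summ$group[i], group2 = summ$group[j],
                   difference = d, df = df_pair, critical = crit,
                   significant = d > crit, zero_variance = FALSE)
  })
  sig <- matrix(FALSE, k, k)
  sig[pairs] <- if (gated) FALSE else pw$significant
  sig <- sig | t(sig)
  if (gated) pw$significant <- FALSE
  lets <- cld_insert_absorb(summ$group, sig)
  summ$letter <- unname(lets)
  new_group_comparison(method = "welch+dunnettT3", omnibus = omn,
                       letters_tbl = summ, pairwise = pw,
                       alpha = alpha, gated = gated)
}

new_group_comparison <- function(method, omnibus, letters_tbl, pairwise,
                                 alpha, gated, levene = NULL) {
  structure(
    list(method = method, omnibus = omnibus, letters = letters_tbl,
         pairwise = pairwise, alpha = alpha, gated = gated, levene = levene),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$method, ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$letters, ...)
  invisible(x)
}

#' Compare groups with the Levene-gated pipeline
#'
#' The full decision chain used for every analyte: Levene's test routes to
#' classical one-way ANOVA with Duncan's multiple range test when variances
#' are homogeneous (`p >= alpha`), and to Welch's ANOVA with Dunnett's T3
#' otherwise. Post-hoc letters only differ when the omnibus test is significant.
#'
#' @inheritParams duncan_letters
#' @param method `"auto"` applies the Levene gate; `"anova_duncan"` or
#'   `"welch_t3"` force a branch.
#' @return object of class `group_comparison`: `method`, `levene`, `omnibus`,
#'   `letters` (group, mean, n, ci95, letter), `pairwise`, `alpha`. `tidy()`
#'   returns the letters table, `glance()` the omnibus row.
#' @examples
#' d <- data.frame(g = rep(c("iso", "krill", "fish"), each = 3),
#'                 y = c(0.52, 0.54, 0.56, 1.44, 1.46, 1.48, 1.70, 1.72, 1.74))
#' compare_groups(d, y, g)
#' @export
compare_groups <- function(data, value, group, alpha = 0.05,
                           letters = c("asc", "desc"),
                           method = c("auto", "anova_duncan", "welch_t3")) {
  letters <- match.arg(letters)
  method <- match.arg(method)
  lev <- levene_test(data, {{ value }}, {{ group }})
  branch <- switch(method,
    auto = if (!lev$degenerate && lev$p_value < alpha) "welch_t3" else "anova_duncan",
    method)
  res <- if (branch == "welch_t3") {
    dunnett_t3(data, {{ value }}, {{ group }}, alpha = alpha, letters = letters)
  } else {
    duncan_letters(data, {{ value }}, {{ group }}, alpha = alpha, letters = letters)
  }
  res$levene <- lev
  res
}

#' @rdname compare_groups
#' @param x,object a `group_comparison`.
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$letters
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(method = x$method, gated = x$gated,
                                  alpha = x$alpha),
                   x$omnibus[1, ],
                   tibble::tibble(levene_p = x$levene$p_value %||% NA_real_))
}

#' Run the comparison pipeline over every analyte of a panel
#'
#' Applies [compare_groups()] substrate-wise to each analyte of a replicate
#' panel (censored replicates entering as zero), returning one row per
#' substrate and analyte with its mean, CI and significance letter. Analytes
#' whose replicates are all censored in every substrate are skipped.
#'
#' @param panel a `nutrient_panel`.
#' @inheritParams compare_groups
#' @return tibble: `category`, `analyte`, `substrate`, `mean`, `n`, `ci95`,
#'   `letter`, `method`, `statistic`, `p_value`.
#' @export
compare_panel <- function(panel, alpha = 0.05, letters = c("asc", "desc")) {
  letters <- match.arg(letters)
  usable <- panel |>
    dplyr::filter(.data$censor != "absent") |>
    dplyr::group_by(.data$category, .data$analyte) |>
    dplyr::filter(!all(.data$censor != "observed")) |>
    dplyr::ungroup()
  usable |>
    dplyr::group_by(.data$category, .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      res <- compare_groups(d, .data$value, .data$substrate,
                            alpha = alpha, letters = letters)
      out <- res$letters
      names(out)[names(out) == "group"] <- "substrate"
      out$method <- res$method
      out$statistic <- res$omnibus$statistic[1]
      out$p_value <- res$omnibus$p_value[1]
      out
    }) |>
    dplyr::ungroup()
}
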