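#' Fit a power growth curve by log-log least squares
#'
#' Fits \eqn{BW = a \cdot t^{b}} by ordinary least squares on
#' \eqn{(\ln t, \ln BW)}: `a = exp(intercept)`, `b = slope`. The reported `r2`
#' is the coefficient of determination of the linear fit on the transformed
#' scale (the spreadsheet power-trendline convention); an original-scale
#' `r2_original = 1 - SSE/SST` on back-transformed predictions is also
#' returned. Points with `time <= 0` (log undefined) or non-positive weight
#' are excluded with a warning.
#'
#' @param data data frame of body-weight observations.
#' @param time column of ages (days after hatching).
#' @param weight column of body weights (mg); replicate group means may appear
#'   as multiple rows per time.
#' @return object of class `power_fit`: `a`, `b`, `r2` (log-log scale),
#'   `r2_original`, `n_points_used`, and the underlying `lm` fit.
#' @examples
#' pts <- load_fixture("growth_points")
#' fit_power(pts, dah, mean_bw_mg)
#' @export
fit_power <- function(data, time, weight) {
  t <- dplyr::pull(data, {{ time }})
  w <- dplyr::pull(data, {{ weight }})
  drop <- t <= 0 | w <= 0 | is.na(t) | is.na(w)
  if (any(drop)) {
    warn(paste0(sum(drop), " point(s) with nonpositive time or weight excluded from the log-log fit"))
  }
  t <- t[!drop]; w <- w[!drop]
  if (length(t) < 3) abort("power fit needs at least 3 points with time > 0 and weight > 0")
  fit <- lm(log(w) ~ log(t))
  a <- exp(unname(coef(fit)[1]))
  b <- unname(coef(fit)[2])
  pred <- a * t^b
  sst <- sum((w - mean(w))^2)
  r2_orig <- if (sst > 0) 1 - sum((w - pred)^2) / sst else NA_real_
  # r2 on the transformed scale, computed directly (summary.lm warns on
  # near-perfect fits)
  lw <- log(w)
  sst_log <- sum((lw - mean(lw))^2)
  r2_log <- if (sst_log > 0) 1 - sum(residuals(fit)^2) / sst_log else NA_real_
  structure(
    list(a = a, b = b,
         r2 = r2_log,
         r2_original = r2_orig,
         n_points_used = length(t),
         model = fit,
         data = tibble::tibble(time = t, weight = w)),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power growth fit: BW = %.4g * t^%.4g  (r2 log-log = %.4f, n = %d)\n",
              x$a, x$b, x$r2, x$n_points_used))
  invisible(x)
}

#' @rdname fit_power
#' @param x a `power_fit`.
#' @param ... unused.
#' @export
tidy.power_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- suppressMessages(stats::confint(x$model))
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    conf.low = c(exp(ci[1, 1]), ci[2, 1]),
    conf.high = c(exp(ci[1, 2]), ci[2, 2]),
    # log-scale standard errors; a's applies to log(a)
    std.error = unname(s[, "Std. Error"])
  )
}

#' @rdname fit_power
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r.squared = x$r2,
                 r.squared.original = x$r2_original, nobs = x$n_points_used)
}

#' @rdname fit_power
#' @param object a `power_fit`.
#' @export
autoplot.power_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time = seq(min(object$data$time), max(object$data$time), length.out = 200))
  grid$weight <- object$a * grid$time^object$b
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$weight)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, linetype = "dashed") +
    ggplot2::labs(x = "days after hatching", y = "body weight (mg)",
                  title = sprintf("BW = %.4g t^%.3g, r2 = %.3f",
                                  object$a, object$b, object$r2))
}

#' Weight gain rate (WGR)
#'
#' `(final - initial) / initial * 100`, in percent over the whole trial.
#'
#' @param initial,final body weights (same unit), `initial > 0`.
#' @return percent.
#' @examples
#' weight_gain_rate(0.24, 31.06)
#' @export
weight_gain_rate <- function(initial, final) {
  if (any(initial <= 0)) abort("initial weight must be > 0")
  if (any(final < 0)) abort("final weight must be >= 0")
  (final - initial) / initial * 100
}

#' Specific growth rate (SGR)
#'
#' `(ln final - ln initial) / days * 100`, in percent per day.
#'
#' @inheritParams weight_gain_rate
#' @param days trial duration in days, `> 0`.
#' @return percent per day.
#' @examples
#' specific_growth_rate(0.24, 31.06, 70)
#' @export
specific_growth_rate <- function(initial, final, days) {
  if (any(initial <= 0) || any(final <= 0)) abort("weights must be > 0")
  if (any(days <= 0)) abort("days must be > 0")
  (log(final) - log(initial)) / days * 100
}

#' Shapiro-Wilk normality check of power-fit residuals
#'
#' Standardises the log-scale residuals of a [fit_power()] fit and tests them
#' for normality; `pass` is `TRUE` when `p > 0.05`, supporting the assumption
#' that weight-gain values scatter lognormally around the trend.
#'
#' @param fit a `power_fit`.
#' @return one-row tibble: `statistic` (W), `p_value`, `pass`, `n`.
#' @export
residual_normality <- function(fit) {
  r <- residuals(fit$model)
  if (length(r) < 3) abort("need at least 3 residuals")
  if (sd(r) < 1e-10) abort("degenerate fit: residuals are constant")
  ht <- shapiro.test(as.numeric(scale(r)))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 pass = ht$p.value > 0.05, n = length(r))
}
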