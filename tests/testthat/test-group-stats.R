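make_groups <- function(...) {
  vals <- list(...)
  tibble::tibble(g = rep(names(vals), lengths(vals)), y = unlist(vals))
}

test_that("Levene's statistic matches the textbook formula and car's oracle", {
  d <- make_groups(a = c(1, 2, 3), b = c(10, 20, 30))
  lv <- levene_test(d, y, g)
  # hand computation on absolute deviations from group means
  z <- c(abs(c(1, 2, 3) - 2), abs(c(10, 20, 30) - 20))
  zg <- rep(c("a", "b"), each = 3)
  ssb <- sum(3 * (tapply(z, zg, mean) - mean(z))^2)
  ssw <- sum((z - ave(z, zg))^2)
  expect_equal(lv$statistic, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  skip_if_not_installed("car")
  cr <- car::leveneTest(y ~ factor(g), data = d, center = mean)
  expect_equal(lv$statistic, cr$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p_value, cr$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene's test handles identical and degenerate groups", {
  same <- make_groups(a = c(1, 2, 3), b = c(1, 2, 3))
  lv <- levene_test(same, y, g)
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p_value, 1)
  flat <- make_groups(a = c(2, 2, 2), b = c(5, 5, 5))
  expect_true(levene_test(flat, y, g)$degenerate)
})

test_that("Levene's type-I error is near nominal under equal variances", {
  set.seed(31)
  rej <- 0
  for (i in 1:1000) {
    d <- make_groups(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    rej <- rej + (levene_test(d, y, g)$p_value < 0.05)
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("one-way ANOVA matches lm and reduces to t^2 for two groups", {
  d <- make_groups(a = rnorm(5, 0), b = rnorm(5, 1), c = rnorm(5, 2))
  a1 <- one_way_anova(d, y, g)
  or <- anova(lm(y ~ g, data = d))
  expect_equal(a1$statistic, or$`F value`[1], tolerance = 1e-10)
  expect_equal(a1$p_value, or$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(a1$df_between, 2)  # three substrates -> df = 2
  flat <- make_groups(a = c(1, 1, 1), b = c(1, 1, 1))
  expect_equal(one_way_anova(flat, y, g)$statistic, 0)
  d2 <- make_groups(a = rnorm(6), b = rnorm(6, 0.5))
  a2 <- one_way_anova(d2, y, g)
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(a2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("Duncan letters separate well-separated means and match a published pattern", {
  far <- make_groups(a = c(-1, 0, 1), b = c(99, 100, 101), c = c(199, 200, 201))
  r <- duncan_letters(far, y, g)
  expect_equal(tidy(r)$letter, c("a", "b", "c"))
  # Cys row reconstruction: sd back-solved from printed CI half-widths
  sds <- c(0.07, 0.05, 0.05) / 4.302653 * sqrt(3)
  mk <- function(m, s) m + s * c(-1, 0, 1)  # mean m, sample sd s exactly
  d <- make_groups(isopod = mk(0.09, sds[1]), krill = mk(1.34, sds[2]),
                   fish = mk(1.37, sds[3]))
  letters_tbl <- tidy(duncan_letters(d, y, g))
  expect_equal(letters_tbl$letter[letters_tbl$group == "isopod"], "a")
  expect_equal(letters_tbl$letter[letters_tbl$group == "krill"], "b")
  expect_equal(letters_tbl$letter[letters_tbl$group == "fish"], "b")
})

test_that("compact letters agree with the recursive range-test oracle", {
  set.seed(17)
  for (case in 1:150) {
    k <- sample(3:5, 1)
    n <- 3
    mu <- runif(k, 0, 3)
    d <- tibble::tibble(g = rep(letters[1:k], each = n),
                        y = rnorm(k * n, rep(mu, each = n), 0.5))
    r <- duncan_letters(d, y, g, protect = FALSE)
    summ <- r$letters
    ord <- order(summ$mean)
    se <- sqrt(one_way_anova(d, y, g)$ms_within / n)
    sig_oracle <- duncan_oracle_pairs(summ$mean[ord], se,
                                      df = k * n - k, alpha = 0.05)
    shared <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      any(strsplit(summ$letter[ord][i], "")[[1]] %in%
            strsplit(summ$letter[ord][j], "")[[1]])
    }))
    expect_identical(!shared & upper.tri(shared), sig_oracle & upper.tri(sig_oracle))
  }
})

test_that("LSD comparisons against a control match the closed form", {
  same <- make_groups(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(!lsd_pairwise(same, y, g, control = "a")$significant))
  d <- make_groups(iso = c(1.0, 1.1, 0.9), krill = c(2.0, 2.2, 1.8),
                   fish = c(1.1, 1.0, 1.2))
  tbl <- lsd_pairwise(d, y, g, control = "iso")
  expect_setequal(tbl$group, c("krill", "fish"))
  aovr <- one_way_anova(d, y, g)
  lsd_hand <- qt(0.975, aovr$df_within) * sqrt(aovr$ms_within * (2 / 3))
  expect_equal(tbl$lsd, rep(lsd_hand, 2), tolerance = 1e-12)
  expect_true(tbl$significant[tbl$group == "krill"])
  expect_false(tbl$significant[tbl$group == "fish"])
  expect_error(lsd_pairwise(d, y, g, control = "nope"), "unknown control")
})

test_that("studentized maximum modulus quantile reduces to t and grows with k", {
  expect_equal(qsmm(0.95, 1, 12), qt(0.975, 12), tolerance = 1e-6)
  expect_gt(qsmm(0.95, 3, 12), qsmm(0.95, 1, 12))
  expect_gt(qsmm(0.95, 3, 5), qsmm(0.95, 3, 50))
})

test_that("Dunnett T3 agrees with Duncan on well-separated equal-variance groups", {
  far <- make_groups(a = c(-1, 0, 1, 0.5), b = c(99, 100, 101, 100.5),
                     c = c(199, 200, 201, 200.5))
  t3 <- dunnett_t3(far, y, g)
  expect_equal(tidy(t3)$letter, c("a", "b", "c"))
  same <- make_groups(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(tidy(dunnett_t3(same, y, g))$letter == "a"))
})

test_that("Dunnett T3 familywise type-I error stays at or below nominal", {
  set.seed(23)
  rej <- 0
  nsim <- 400
  for (i in 1:nsim) {
    d <- make_groups(a = rnorm(10, 0, 1), b = rnorm(10, 0, 3), c = rnorm(10, 0, 6))
    pw <- dunnett_t3(d, y, g, protect = FALSE)$pairwise
    rej <- rej + any(pw$significant)
  }
  expect_lte(rej / nsim, 0.05 + 0.02)
})

test_that("decisions are invariant to location shifts and positive scaling", {
  set.seed(29)
  d <- make_groups(a = rnorm(4, 0), b = rnorm(4, 1), c = rnorm(4, 1.2))
  base <- tidy(compare_groups(d, y, g))$letter
  shifted <- dplyr::mutate(d, y = y + 100)
  scaled <- dplyr::mutate(d, y = y * 7.3)
  expect_equal(tidy(compare_groups(shifted, y, g))$letter, base)
  expect_equal(tidy(compare_groups(scaled, y, g))$letter, base)
})

test_that("the Levene gate routes heteroscedastic data to Welch + T3", {
  set.seed(37)
  het <- make_groups(a = rnorm(15, 0, 0.05), b = rnorm(15, 0.1, 5),
                     c = rnorm(15, 0, 10))
  r <- compare_groups(het, y, g)
  expect_equal(r$method, "welch+dunnettT3")
  hom <- make_groups(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  expect_equal(compare_groups(hom, y, g)$method, "anova+duncan")
  # override
  expect_equal(compare_groups(het, y, g, method = "anova_duncan")$method,
               "anova+duncan")
})

test_that("Shapiro-Wilk wrapper enforces its domain", {
  set.seed(43)
  expect_gt(shapiro_wilk(rnorm(30))$p_value, 0.05)
  expect_lt(shapiro_wilk(rexp(100))$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "degenerate")
})

test_that("letters sharing encodes exactly the pairwise decisions (soundness)", {
  set.seed(47)
  for (case in 1:50) {
    k <- sample(3:5, 1)
    d <- tibble::tibble(g = rep(letters[1:k], each = 4),
                        y = rnorm(4 * k, rep(runif(k, 0, 2), each = 4),
                                  rep(runif(k, 0.1, 2), each = 4)))
    r <- dunnett_t3(d, y, g, protect = FALSE)
    lt <- setNames(r$letters$letter, r$letters$group)
    share <- function(g1, g2) {
      any(strsplit(lt[[g1]], "")[[1]] %in% strsplit(lt[[g2]], "")[[1]])
    }
    for (i in seq_len(nrow(r$pairwise))) {
      expect_equal(!share(r$pairwise$group1[i], r$pairwise$group2[i]),
                   r$pairwise$significant[i])
    }
  }
})

test_that("compare_panel letters every analyte of a replicate panel", {
  truth <- tidyr::crossing(substrate = c("iso", "krill", "fish"),
                           analyte = c("Met", "Lys")) |>
    dplyr::arrange(analyte, substrate)
  truth$mean <- c(5, 1, 3, 2, 2, 2)   # Lys: fish 5 iso 1 krill 3; Met: equal
  truth$sd <- 0.05
  pan <- gen_panel(truth, seed = 3)
  res <- compare_panel(pan)
  lys <- dplyr::filter(res, analyte == "Lys")
  expect_equal(lys$letter[order(lys$mean)], c("a", "b", "c"))
  met <- dplyr::filter(res, analyte == "Met")
  expect_true(length(unique(met$letter)) %in% c(1L, 2L))  # null case, usually one letter
})
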