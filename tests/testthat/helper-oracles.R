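# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Duncan decisions by exhaustive enumeration: a pair of means (ascending-mean
# positions i < j) is significantly different iff EVERY range containing the
# pair -- including the pair's own span -- exceeds its least significant range
# (the protection rule: a difference inside any failed range is shielded).
duncan_oracle_pairs <- function(sorted_means, se, df, alpha = 0.05) {
  k <- length(sorted_means)
  exceeds <- function(p, q) {
    span <- q - p + 1
    r_crit <- qtukey((1 - alpha)^(span - 1), nmeans = span, df = df) * se
    sorted_means[q] - sorted_means[p] > r_crit
  }
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      all_exceed <- TRUE
      for (p in seq_len(i)) {
        for (q in seq(j, k)) {
          if (!exceeds(p, q)) all_exceed <- FALSE
        }
      }
      sig[i, j] <- sig[j, i] <- all_exceed
    }
  }
  sig
}

# Geometric mean via explicit product and n-th root (log-free path).
geomean_product <- function(x) prod(x)^(1 / length(x))

random_profile <- function(analytes = c("Ile", "Leu", "Lys", "Thr", "Val",
                                        "Trp", "Met", "Cys", "Phe", "Tyr")) {
  tibble::tibble(analyte = analytes,
                 content = stats::runif(length(analytes), 0.05, 6),
                 essential = TRUE, flavor = FALSE)
}

random_reciprocal_matrix <- function(n) {
  m <- diag(n)
  for (j in seq_len(n - 1)) {
    for (k in seq(j + 1, n)) {
      v <- exp(stats::runif(1, -log(9), log(9)))
      m[j, k] <- v
      m[k, j] <- 1 / v
    }
  }
  m
}
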