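test_that("judgment matrix validation enforces the 1-9 reciprocal structure", {
  expect_silent(ahp_matrix(rbind(c(1, 3), c(1 / 3, 1))))
  expect_error(ahp_matrix(rbind(c(1, 3), c(1 / 2, 1))), "reciprocal")
  expect_error(ahp_matrix(rbind(c(1, 12), c(1 / 12, 1))), "1/9, 9")
  expect_error(ahp_matrix(rbind(c(2, 3), c(1 / 3, 2))), "diagonal")
  expect_error(ahp_matrix(matrix(1, 1, 1)), "square")
})

test_that("a consistent matrix returns its generating weights with CR = 0", {
  w <- c(0.5, 0.3, 0.2)
  m <- outer(w, w, `/`)
  pr <- ahp_priorities(m)
  expect_equal(pr$weights$weight, w, tolerance = 1e-10)
  expect_equal(pr$cr, 0, tolerance = 1e-10)
  expect_equal(pr$lambda_max, 3, tolerance = 1e-10)
  # any normalised column of a consistent matrix is the priority vector
  expect_equal(pr$weights$weight, m[, 2] / sum(m[, 2]), tolerance = 1e-10)
})

test_that("the 3x3 example matrix yields the known eigenvector and CR", {
  m <- rbind(c(1, 3, 5), c(1 / 3, 1, 3), c(1 / 5, 1 / 3, 1))
  pr <- ahp_priorities(m)
  expect_equal(pr$weights$weight, c(0.637, 0.258, 0.105), tolerance = 0.002)
  expect_lt(abs(pr$cr - 0.033), 0.002)
  # dense eigen-decomposition oracle
  ev <- eigen(m)
  v <- abs(Re(ev$vectors[, 1])); v <- v / sum(v)
  expect_equal(pr$weights$weight, v, tolerance = 1e-8)
  expect_equal(pr$lambda_max, Re(ev$values[1]), tolerance = 1e-8)
})

test_that("2x2 matrices are always consistent", {
  pr <- ahp_priorities(rbind(c(1, 7), c(1 / 7, 1)))
  expect_equal(pr$cr, 0)
})

test_that("power iteration matches the dense eigensolver on random matrices", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    m <- random_reciprocal_matrix(n)
    pr <- ahp_priorities(m)
    ev <- eigen(m)
    v <- abs(Re(ev$vectors[, 1])); v <- v / sum(v)
    expect_equal(pr$weights$weight, v, tolerance = 1e-8)
    expect_equal(pr$lambda_max, Re(ev$values[1]), tolerance = 1e-8)
    expect_gte(pr$lambda_max, n - 1e-10)
    expect_equal(sum(pr$weights$weight), 1, tolerance = 1e-12)
  }
})

test_that("priorities are invariant to simultaneous row/column permutation", {
  set.seed(59)
  m <- random_reciprocal_matrix(5)
  rownames(m) <- colnames(m) <- paste0("i", 1:5)
  pr <- ahp_priorities(m)
  perm <- sample(5)
  mp <- m[perm, perm]
  prp <- ahp_priorities(mp)
  expect_equal(prp$weights$weight[match(pr$weights$item, prp$weights$item)],
               pr$weights$weight, tolerance = 1e-10)
  expect_equal(prp$cr, pr$cr, tolerance = 1e-10)
})

test_that("expert aggregation averages priority vectors", {
  v1 <- tibble::tibble(item = c("a", "b"), weight = c(0.6, 0.4))
  expect_equal(aggregate_experts(list(v1))$weight, c(0.6, 0.4))
  v2 <- tibble::tibble(item = c("a", "b"), weight = c(0.4, 0.6))
  expect_equal(aggregate_experts(list(v1, v2))$weight, c(0.5, 0.5))
  v3 <- tibble::tibble(item = c("a", "c"), weight = c(0.5, 0.5))
  expect_error(aggregate_experts(list(v1, v3)), "different item sets")
  # weighted experts
  expect_equal(aggregate_experts(list(v1, v2), expert_weights = c(3, 1))$weight,
               c(0.55, 0.45))
  # perturbed vectors around a known truth stay within the perturbation radius
  set.seed(61)
  truth <- c(0.5, 0.3, 0.2)
  vs <- lapply(1:3, function(i) {
    w <- truth + runif(3, -0.02, 0.02); w <- w / sum(w)
    tibble::tibble(item = c("a", "b", "c"), weight = w)
  })
  expect_lt(max(abs(aggregate_experts(vs)$weight - truth)), 0.025)
})

test_that("synthesis recovers known global weights from consistent matrices", {
  crit <- c(AA = 0.4, FA = 0.3, Vit = 0.2, Min = 0.1)
  alts <- list(AA = c(fish = 0.5, iso = 0.2, krill = 0.3),
               FA = c(fish = 0.6, iso = 0.1, krill = 0.3),
               Vit = c(fish = 0.3, iso = 0.5, krill = 0.2),
               Min = c(fish = 0.2, iso = 0.6, krill = 0.2))
  truth <- Reduce(`+`, purrr::imap(alts, function(a, cr) crit[[cr]] * a))
  model <- gen_consistent_model(crit, alts, n_experts = 3)
  syn <- ahp_synthesize(model)
  expect_equal(setNames(syn$weights$weight, syn$weights$alternative),
               truth[syn$weights$alternative], tolerance = 1e-9)
  expect_equal(sum(syn$weights$weight), 1, tolerance = 1e-12)
  expect_true(all(syn$consistency$cr < 1e-8))
  # matrix-geomean aggregation gives the same answer for identical experts
  syn2 <- ahp_synthesize(model, aggregation = "matrix_geomean")
  expect_equal(syn2$weights$weight, syn$weights$weight, tolerance = 1e-9)
})

test_that("uniform criteria with identical alternative matrices pass local weights through", {
  alt <- c(x = 0.7, y = 0.2, z = 0.1)
  model <- gen_consistent_model(c(c1 = 0.5, c2 = 0.5),
                                list(c1 = alt, c2 = alt))
  syn <- ahp_synthesize(model)
  expect_equal(setNames(syn$weights$weight, syn$weights$alternative),
               alt[syn$weights$alternative], tolerance = 1e-9)
})

test_that("synthesis is monotone in a local alternative weight", {
  crit <- c(c1 = 0.6, c2 = 0.4)
  base_alt <- list(c1 = c(A = 0.3, B = 0.3, C = 0.4),
                   c2 = c(A = 0.2, B = 0.5, C = 0.3))
  w0 <- ahp_synthesize(gen_consistent_model(crit, base_alt))$weights
  bumped <- base_alt
  bumped$c1 <- c(A = 0.5, B = 0.3 * 0.5 / 0.7, C = 0.4 * 0.5 / 0.7)
  w1 <- ahp_synthesize(gen_consistent_model(crit, bumped))$weights
  expect_gt(w1$weight[w1$alternative == "A"], w0$weight[w0$alternative == "A"])
})

test_that("inconsistent matrices are refused with a CR report unless overridden", {
  set.seed(67)
  noisy <- gen_expert_matrices(c(a = 0.4, b = 0.35, c = 0.15, d = 0.1),
                               jitter = 2, n_experts = 1)[[1]]
  alt <- c(x = 0.5, y = 0.5)
  cm <- list(noisy)
  am <- list(setNames(lapply(rownames(noisy), function(cr) {
    ahp_matrix(outer(alt, alt, `/`), items = names(alt))
  }), rownames(noisy)))
  model <- ahp_model(cm, am)
  expect_gt(ahp_priorities(noisy)$cr, 0.1)
  expect_error(ahp_synthesize(model), "CR")
  expect_s3_class(ahp_synthesize(model, override = TRUE), "ahp_synthesis")
})

test_that("generated expert matrices behave as specified", {
  # zero jitter: perfectly consistent, exact recovery
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  m0 <- gen_expert_matrices(w, jitter = 0, n_experts = 2, seed = 1)
  pr <- ahp_priorities(m0[[1]])
  expect_equal(setNames(pr$weights$weight, pr$weights$item), w, tolerance = 1e-10)
  expect_equal(pr$cr, 0, tolerance = 1e-10)
  # identical seeds give identical matrices
  expect_identical(m0, gen_expert_matrices(w, jitter = 0, n_experts = 2, seed = 1))
  # moderate jitter keeps most matrices consistent
  set.seed(71)
  ok <- 0
  for (i in 1:200) {
    m <- gen_expert_matrices(c(0.4, 0.3, 0.2, 0.1), jitter = 0.1,
                             n_experts = 1)[[1]]
    ok <- ok + (ahp_priorities(m)$cr < 0.1)
  }
  expect_gte(ok / 200, 0.95)
})

test_that("AHP models round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "goal: nutritional value",
    "criteria: [AA, FA]",
    "alternatives: [fish, iso]",
    "experts:",
    "  - criteria_matrix:",
    "      - [1, 3]",
    "      - [0.3333333333333333, 1]",
    "    alternatives:",
    "      AA:",
    "        - [1, 2]",
    "        - [0.5, 1]",
    "      FA:",
    "        - [1, 0.5]",
    "        - [2, 1]"
  ), path)
  model <- read_ahp_model(path)
  expect_equal(model$criteria, c("AA", "FA"))
  syn <- ahp_synthesize(model)
  expect_equal(sum(syn$weights$weight), 1, tolerance = 1e-12)
})
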