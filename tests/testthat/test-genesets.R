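test_that("Tau hits its closed-form values", {
  expect_equal(tau_score(c(5, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(tau_score(rep(3, 8)), 0)
  expect_equal(tau_score(c(10, 5, 0, 0, 0, 0, 0, 0)), (0.5 + 6) / 7)
  # scale invariance
  set.seed(41)
  x <- runif(8, 0, 100)
  expect_equal(tau_score(x), tau_score(x * 37.5))
})

test_that("entropy hits its closed-form values in bits", {
  expect_equal(entropy_score(rep(2, 8)), 3)
  expect_equal(entropy_score(c(9, 0, 0, 0)), 0)
  expect_equal(entropy_score(c(1, 1, 0, 0, 0, 0, 0, 0)), 1)
  set.seed(42)
  x <- runif(8, 0, 10)
  expect_equal(entropy_score(x), entropy_score(x * 5))
})

test_that("matrix scoring handles all-zero genes", {
  m <- rbind(g1 = c(10, 5, rep(0, 6)), g2 = rep(0, 8))
  s <- specificity_scores(m)
  expect_equal(s$tau[1], (0.5 + 6) / 7)
  expect_true(is.na(s$tau[2]))
})

test_that("permutation enrichment is exact at the forced extreme and
          reproducible", {
  universe <- paste0("g", 1:1000)
  catalogue <- universe[1:20]
  query <- universe[1:10]  # entirely inside a rare catalogue
  r <- permutation_enrichment(query, catalogue, universe, n_perm = 500,
                              seed = 3)
  expect_equal(r$observed, 10)
  expect_equal(r$p_value, 1 / 501)
  r2 <- permutation_enrichment(query, catalogue, universe, n_perm = 500,
                               seed = 3)
  expect_equal(r$p_value, r2$p_value)
  expect_error(permutation_enrichment(character(), catalogue, universe),
               "empty")
  expect_error(permutation_enrichment("zz", catalogue, universe),
               "subset")
})

test_that("random queries give roughly uniform permutation p-values", {
  set.seed(8)
  universe <- paste0("g", 1:500)
  catalogue <- sample(universe, 100)
  ps <- vapply(1:40, function(i)
    permutation_enrichment(sample(universe, 50), catalogue, universe,
                           n_perm = 400)$p_value, numeric(1))
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)
})

test_that("overlap chi-square matches the hand 2x2 computation", {
  universe <- paste0("g", 1:1000)
  A <- universe[1:100]
  B <- universe[c(1:20, 101:280)]  # overlap 20 = expected
  r <- overlap_chisq(A, B, universe)
  expect_equal(r$expected, 20)
  expect_lt(r$statistic, 1e-20)
  # observed 50 under the same sizes
  B2 <- universe[c(1:50, 101:250)]
  r2 <- overlap_chisq(A, B2, universe)
  tab <- matrix(c(50, 150, 50, 750), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / 1000
  expect_equal(r2$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_error(overlap_chisq(c("zz"), B, universe), "subsets")
})
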