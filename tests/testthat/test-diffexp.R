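test_that("size factors recover forced library scalings", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  sf <- size_factors(m)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  same <- cbind(a = c(5, 9, 2), b = c(5, 9, 2))
  expect_equal(unname(size_factors(same)), c(1, 1))
  # hand-computed median-of-ratios on a 5x2 matrix
  k <- matrix(c(4, 10, 6, 50, 8,   8, 10, 18, 40, 2), ncol = 2)
  ref <- exp(rowMeans(log(k)))
  want <- c(median(k[, 1] / ref), median(k[, 2] / ref))
  expect_equal(unname(size_factors(k)), want)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("identical replicate vectors are called unchanged with p near 1", {
  r <- nb_test(c(10, 12, 11), c(10, 12, 11))
  expect_equal(r$log2_fold_change, 0, tolerance = 1e-6)
  expect_gt(r$p_value, 0.9)
  z <- nb_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(z$p_value, 1)
  expect_equal(z$log2_fold_change, 0)
})

test_that("swapping condition labels flips the fold change and keeps p", {
  set.seed(201)
  k <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6)
  rownames(k) <- paste0("c", 1:100)
  cond <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  cond_sw <- factor(rep(c("A", "B"), each = 3), levels = c("B", "A"))
  r1 <- nb_diffexp(k, cond)
  r2 <- nb_diffexp(k, cond_sw)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("clusters with a planted fold change are detected", {
  set.seed(202)
  n_null <- 1500; n_de <- 60
  mu <- rep(100, n_null + n_de)
  muB <- mu * c(rep(1, n_null), rep(4, n_de))
  k <- cbind(matrix(rnbinom(3 * length(mu), mu = mu, size = 10),
                    ncol = 3),
             matrix(rnbinom(3 * length(mu), mu = muB, size = 10),
                    ncol = 3))
  rownames(k) <- paste0("c", seq_along(mu))
  res <- nb_diffexp(k, factor(rep(c("A", "B"), each = 3)))
  de <- seq_len(n_de) + n_null
  expect_gt(mean(res$call[de] == "up_B"), 0.8)
  # specificity on the null part
  expect_gt(mean(res$call[seq_len(n_null)] == "unchanged"), 0.93)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(301)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    # invariance under permutation of input order
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), oracle_bh(p)[o], tolerance = 1e-12)
  }
})
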