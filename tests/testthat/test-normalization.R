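test_that("power-law fitting recovers a known Pareto exponent", {
  set.seed(123)
  u <- runif(1e5)
  counts <- floor(u^(-1 / 1.2))  # reverse cumulative ~ x^(-1.2)
  counts <- counts[counts >= 1]
  fit <- fit_power_law(counts, fit_range = c(1, 1000))
  expect_lt(abs(fit$fitted_slope - (-1.2)), 0.05)
})

test_that("degenerate count distributions are rejected", {
  expect_error(fit_power_law(rep(7, 1000)), "distinct")
  expect_error(fit_power_law(1:5, fit_range = c(1, 10)), "distinct")
})

test_that("fitted slope equals the closed-form regression on geometric
          counts", {
  counts <- 2^(0:10)  # 11 distinct values, once each
  fit <- fit_power_law(counts, fit_range = c(1, 1024))
  # hand least squares on (log10 x_i, log10 revcum_i), revcum_i = 11..1
  x <- log10(2^(0:10)); y <- log10(11:1)
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit$fitted_slope, slope, tolerance = 1e-12)
  expect_equal(fit$n_points, 11L)
})

test_that("tpm mapping is strictly monotone and preserves ties", {
  set.seed(5)
  counts <- sample(1:2000, 3000, replace = TRUE)
  tab <- data.frame(chrom = "c", pos = seq_along(counts), strand = "+",
                    count = counts)
  out <- normalize_ctss(tab)
  o <- order(out$count)
  expect_true(all(diff(out$tpm[o]) >= 0))
  expect_true(all(diff(out$tpm[o])[diff(out$count[o]) > 0] > 0))
  same <- out$count == out$count[1]
  expect_equal(length(unique(out$tpm[same])), 1L)
  expect_error(normalize_to_tpm(tab, structure(list(), class = "lm")),
               "power_law_model")
})

test_that("a library already following the reference law is left nearly
          unchanged", {
  # construct counts whose reverse cumulative is the reference law
  # r(k) = beta * k^(-1.05) with implied total 1e6 (independent solver)
  alpha <- 1.05
  total_of <- function(beta) {
    kmax <- floor(beta^(1 / alpha))
    beta * sum(seq_len(kmax)^(-alpha)) - 1e6
  }
  beta <- uniroot(total_of, c(1e3, 1e6), tol = 1e-8)$root
  # the r-th largest count of the law: r = beta * x^(-alpha)
  r <- seq_len(floor(beta))
  counts <- floor((beta / r)^(1 / alpha))
  tab <- data.frame(chrom = "c", pos = seq_along(counts), strand = "+",
                    count = counts)
  out <- normalize_ctss(tab)
  inr <- out$count >= 5 & out$count <= 1000
  rel <- abs(out$tpm[inr] - out$count[inr]) / out$count[inr]
  expect_lt(max(rel), 0.1)
})

test_that("normalized tpm follows the reference exponent", {
  set.seed(11)
  u <- runif(2e5)
  counts <- floor(1 * u^(-1 / 1.3))
  counts <- counts[counts >= 1 & counts <= 1e6]
  tab <- data.frame(chrom = "c", pos = seq_along(counts), strand = "+",
                    count = counts)
  out <- normalize_ctss(tab, alpha_ref = 1.05)
  slope <- revcum_slope(out$tpm, range = quantile(out$tpm, c(0.5, 0.9999)))
  expect_lt(abs(slope - (-1.05)), 0.05)
})
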