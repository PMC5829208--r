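test_that("EM recovers mixing weights and matches the direct-ML oracle", {
  x <- rgmm3(3000, w = c(0.3, 0.4, 0.3), mu = c(0.25, 0.5, 0.75),
             sig = rep(0.04, 3), seed = 101)
  fit <- fit_ratio_mixture(x)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$lambda - c(0.3, 0.4, 0.3))), 0.03)
  expect_lt(max(abs(fit$mu - c(0.25, 0.5, 0.75))), 0.01)
  # independent direct maximisation of the same likelihood
  ll_oracle <- gmm3_direct_ml(x)
  expect_lt(abs(fit$loglik - ll_oracle), 1e-3)
})

test_that("the EM log-likelihood never decreases across iterations", {
  for (seed in c(7, 8)) {
    x <- rgmm3(1500, w = c(0.45, 0.2, 0.35), mu = c(0.3, 0.5, 0.7),
               sig = c(0.05, 0.08, 0.05), seed = seed)
    fit <- fit_ratio_mixture(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("a single central peak is absorbed by the middle component", {
  set.seed(5)
  x <- rnorm(2000, 0.5, 0.01)
  fit <- fit_ratio_mixture(x)
  expect_gte(fit$lambda[2], 0.98)
  expect_lt(abs(fit$mu[2] - 0.5), 0.005)
})

test_that("simulated tetraploid ratios recover the three dosage peaks", {
  cfg <- snp_sim_config(ploidy = 4, n_snps = 10000, depth_law = "fixed",
                        depth_mean = 60, error_rate = 0.005,
                        n_replicates = 1, seed = 17)
  r <- simulate_read_ratio_dataset(cfg)
  fit <- fit_ratio_mixture(compute_ratios(r))
  expect_lt(max(abs(fit$mu - c(0.25, 0.5, 0.75))), 0.03)
})

test_that("components are reported sorted by mean with weights summing to 1", {
  x <- rgmm3(1000, w = c(0.2, 0.3, 0.5), mu = c(0.7, 0.3, 0.5),
             sig = rep(0.05, 3), seed = 33)
  fit <- fit_ratio_mixture(x)
  expect_false(is.unsorted(fit$mu))
  expect_equal(sum(fit$lambda), 1, tolerance = 1e-9)
  expect_true(all(fit$sigma > 0))
})

test_that("fixed-means mode holds the component means at initialisation", {
  x <- rgmm3(1000, w = c(0.3, 0.4, 0.3), mu = c(0.26, 0.49, 0.74),
             sig = rep(0.04, 3), seed = 12)
  fit <- fit_ratio_mixture(x, fixed_means = TRUE)
  expect_identical(fit$mu, c(0.25, 0.5, 0.75))
})

test_that("degenerate inputs floor sigma and clear the convergence flag", {
  x <- c(rep(0.5, 400), 0.25, 0.75)
  fit <- fit_ratio_mixture(x)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(all(fit$sigma >= 1e-4))
})

test_that("peak_ratio implements the minor/central weight ratio", {
  expect_equal(peak_ratio(mixture_shell(c(1, 1, 1) / 3)), 1.0)
  expect_equal(peak_ratio(mixture_shell(c(0.1, 0.8, 0.1))), 0.125)
  expect_equal(peak_ratio(mixture_shell(c(0.4, 0.2, 0.4))), 2.0)
  expect_equal(peak_ratio(mixture_shell(c(0.1, 0.8, 0.1)), inverse = TRUE),
               8.0)
  expect_warning(pr <- peak_ratio(mixture_shell(c(0.5, 0, 0.5))), "zero")
  expect_identical(pr, Inf)
})

test_that("peak_ratio is invariant under reflecting ratios about one half", {
  x <- rgmm3(2000, w = c(0.15, 0.55, 0.3), mu = c(0.25, 0.5, 0.75),
             sig = rep(0.05, 3), seed = 77)
  f1 <- fit_ratio_mixture(x)
  f2 <- fit_ratio_mixture(1 - x)
  expect_equal(peak_ratio(f1), peak_ratio(f2), tolerance = 1e-6)
})

test_that("species averaging and classification follow the group ranges", {
  expect_equal(species_ratio(c(1.02, 1.18)), 1.10)
  expect_equal(species_ratio(0.7), 0.7)
  expect_equal(species_ratio(c(0.25, 0.35)), 0.30)
  expect_error(species_ratio(numeric()), "one individual")
  expect_equal(classify_ploidy(0.30), "diploid-like")
  expect_equal(classify_ploidy(0.60), "intermediate")
  expect_equal(classify_ploidy(1.10), "tetraploid-like")
  expect_equal(classify_ploidy(c(0.1, 0.5, 2)),
               c("diploid-like", "intermediate", "tetraploid-like"))
  expect_error(classify_ploidy(-0.1), "non-negative")
})

test_that("mixture methods expose coefficients, likelihood and simulation", {
  x <- rgmm3(1000, w = c(0.3, 0.4, 0.3), mu = c(0.25, 0.5, 0.75),
             sig = rep(0.04, 3), seed = 2)
  fit <- fit_ratio_mixture(x)
  expect_length(coef(fit), 9)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  s1 <- simulate(fit, nsim = 50, seed = 4)
  expect_identical(s1, simulate(fit, nsim = 50, seed = 4))
  expect_length(s1, 50)
  expect_output(print(fit), "peak ratio")
  expect_s3_class(summary(fit), "summary.ratio_mixture")
})
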