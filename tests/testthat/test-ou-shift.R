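# Shared fixtures: a 32-tip balanced unit-height tree; the "deep" shift
# branch subtends 8 tips and starts at depth 0.2; effect sizes are in
# multiples of the stationary marginal standard deviation.
tr32 <- balanced_tree(32)
tips32 <- ploidyshift:::edge_tip_sets(tr32)
tt32 <- ploidyshift:::tree_times(tr32)
deep_edge <- which(lengths(tips32) == 8 & abs(tt32$t_start - 0.2) < 1e-9)[1]
sd_marg <- sqrt((1 - exp(-4)) / 4) # alpha = 2, sigma2 = 1, height 1

test_that("identical traits give an empty shift set and vanishing noise", {
  y <- stats::setNames(rep(2.5, 32), tr32$tip.label)
  fit <- detect_shifts(tr32, y)
  expect_length(fit$shift_edges, 0)
  expect_lt(fit$sigma2, 1e-12)
  expect_equal(unname(fit$theta0), 2.5, tolerance = 1e-6)
})

test_that("input contracts are enforced", {
  y <- stats::setNames(rnorm(3), letters[1:3])
  tr3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(detect_shifts(tr3, y), "4 tips")
  y32 <- stats::setNames(rnorm(32), tr32$tip.label)
  expect_error(detect_shifts(tr32, unname(y32)), "named")
  expect_error(detect_shifts(tr32, y32[1:10]), "named|cover")
})

test_that("a strong optimum shift is recovered on its branch", {
  for (seed in c(301, 302, 303)) {
    y <- simulate_ou_traits(ou_sim_config(
      tr32, shift_edges = deep_edge, offsets = 6 * sd_marg,
      alpha = 2, sigma2 = 1, seed = seed))
    fit <- detect_shifts(tr32, y)
    expect_true(shift_recovered(fit, deep_edge))
  }
})

test_that("detection agrees with exhaustive single-shift enumeration", {
  y <- simulate_ou_traits(ou_sim_config(
    tr32, shift_edges = deep_edge, offsets = 6 * sd_marg,
    alpha = 2, sigma2 = 1, seed = 310))
  fit <- detect_shifts(tr32, y)
  expect_length(fit$shift_edges, 1)
  # oracle: GLS over every (edge, alpha) pair on the same grid
  yv <- as.numeric(y[tr32$tip.label])
  best_edge <- NA_integer_
  best_ll <- -Inf
  for (alpha in fit$settings$alpha_grid) {
    V0 <- ou_covariance(tr32, alpha)
    U <- chol(V0)
    logdet <- 2 * sum(log(diag(U)))
    X <- ou_design(tr32, alpha)
    yw <- backsolve(U, yv, transpose = TRUE)
    ones <- backsolve(U, rep(1, 32), transpose = TRUE)
    for (e in seq_len(nrow(tr32$edge))) {
      Z <- cbind(ones, backsolve(U, X[, e], transpose = TRUE))
      rss <- sum(stats::lm.fit(Z, yw)$residuals^2)
      ll <- -16 * log(2 * pi * rss / 32) - logdet / 2 - 16
      if (ll > best_ll) {
        best_ll <- ll
        best_edge <- e
      }
    }
  }
  same_set <- identical(tips32[[best_edge]], tips32[[fit$shift_edges]]) ||
    identical(tips32[[best_edge]],
              sort(setdiff(1:32, tips32[[fit$shift_edges]])))
  expect_true(same_set)
  expect_equal(fit$loglik, best_ll, tolerance = 1e-6)
})

test_that("a reported shift always improves on the no-shift score", {
  for (seed in c(301, 302)) {
    y <- simulate_ou_traits(ou_sim_config(
      tr32, shift_edges = deep_edge, offsets = 6 * sd_marg,
      alpha = 2, sigma2 = 1, seed = seed))
    fit <- detect_shifts(tr32, y)
    null_fit <- detect_shifts(tr32, y, max_shifts = 0)
    expect_length(null_fit$shift_edges, 0)
    if (length(fit$shift_edges)) expect_lt(fit$score, null_fit$score)
  }
})

test_that("detection is deterministic and plain BIC is more permissive", {
  y <- simulate_ou_traits(ou_sim_config(
    tr32, shift_edges = deep_edge, offsets = 4 * sd_marg,
    alpha = 2, sigma2 = 1, seed = 320))
  f1 <- detect_shifts(tr32, y)
  f2 <- detect_shifts(tr32, y)
  expect_identical(f1$shift_edges, f2$shift_edges)
  expect_identical(f1$score, f2$score)
  fb <- detect_shifts(tr32, y, criterion = "bic")
  expect_gte(length(fb$shift_edges), length(f1$shift_edges))
})

test_that("bootstrap support is seed-deterministic and high for strong shifts", {
  y <- simulate_ou_traits(ou_sim_config(
    tr32, shift_edges = deep_edge, offsets = 6 * sd_marg,
    alpha = 2, sigma2 = 1, seed = 301))
  fit <- detect_shifts(tr32, y)
  b1 <- bootstrap_support(fit, n_boot = 20, seed = 7)
  b2 <- bootstrap_support(fit, n_boot = 20, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_gte(b1$support[1], 0.8)
  expect_error(bootstrap_support(fit, n_boot = 1), "n_boot")
})

test_that("bootstrap edge frequencies stay low on shift-free traits", {
  y <- simulate_ou_traits(ou_sim_config(tr32, alpha = 2, sigma2 = 1,
                                        seed = 330))
  fit <- detect_shifts(tr32, y)
  b <- bootstrap_support(fit, n_boot = 20, seed = 3)
  freq <- attr(b$support, "edge_frequency")
  expect_gte(mean(freq < 0.5), 0.95)
})

test_that("shift-model methods report coefficients and simulate traits", {
  y <- simulate_ou_traits(ou_sim_config(
    tr32, shift_edges = deep_edge, offsets = 6 * sd_marg,
    alpha = 2, sigma2 = 1, seed = 301))
  fit <- detect_shifts(tr32, y)
  expect_named(coef(fit)[1], "theta0")
  expect_equal(fit$fitted + fit$residuals,
               stats::setNames(as.numeric(y[tr32$tip.label]),
                               tr32$tip.label))
  sims <- simulate(fit, nsim = 5, seed = 2)
  expect_identical(dim(sims), c(32L, 5L))
  expect_identical(sims, simulate(fit, nsim = 5, seed = 2))
  expect_output(print(fit), "OU optimum-shift")
  expect_s3_class(summary(fit), "summary.ou_shift_fit")
})
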