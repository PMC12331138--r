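test_that("an overwhelming penalty zeroes the statistics", {
  d <- make_knockoff_data(n = 80, p = 10, k = 3, seed = 4)
  W <- stat_lasso_coefdiff(d$XXk, d$y, lambda = 1e6)
  expect_equal(W$W, rep(0, 10))
})

test_that("lasso statistics obey the flip-sign contract at fixed tuning", {
  d <- make_knockoff_data(n = 120, p = 15, k = 4, seed = 7)
  lam <- 0.05
  W <- stat_lasso_coefdiff(d$XXk, d$y, lambda = lam)
  for (j in c(2, 9)) {
    W_sw <- stat_lasso_coefdiff(swap_pairs(d$XXk, j), d$y, lambda = lam)
    expect_lt(abs(W_sw$W[j] + W$W[j]), 1e-5)
    expect_lt(max(abs(W_sw$W[-j] - W$W[-j])), 1e-5)
  }

  phi <- prior_weights(rnorm(30, sd = 0.2))
  Wwl <- stat_weighted_lasso(d$XXk, d$y, phi, lambda = lam, gamma = 0.4)
  W_sw <- stat_weighted_lasso(swap_pairs(d$XXk, 5), d$y, phi,
                              lambda = lam, gamma = 0.4)
  expect_lt(abs(W_sw$W[5] + Wwl$W[5]), 1e-5)
  expect_lt(max(abs(W_sw$W[-5] - Wwl$W[-5])), 1e-5)
})

test_that("a strong signal yields a positive statistic in nearly all replicates", {
  hits <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    d <- make_knockoff_data(n = 500, p = 20, k = 1, effect = 1, seed = 100 + i)
    W <- stat_lasso_coefdiff(d$XXk, d$y, cv_folds = 5, seed = i, nlambda = 50)
    hits <- hits + (W$W[d$support] > 0)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("prior weights follow 1/(eps + |b_j| + |b_{j+p}|)", {
  expect_equal(prior_weights(rep(0, 10)), rep(20, 5))
  expect_equal(prior_weights(c(0.5, 0.15)), 1 / 0.7)
  b <- rnorm(20)
  expect_true(all(prior_weights(2 * b) < prior_weights(b) + 1e-12))
  expect_error(prior_weights(rnorm(7)), "even length")
  # simpler alternative without the knockoff coefficients
  expect_equal(prior_weights(c(0.5, 0.15), include_knockoffs = FALSE), 1 / 0.55)
})

test_that("gamma = 0 and constant weights reduce to the plain lasso", {
  d <- make_knockoff_data(n = 120, p = 15, k = 4, seed = 12)
  phi <- prior_weights(rnorm(30))
  W0 <- stat_lasso_coefdiff(d$XXk, d$y, cv_folds = 5, seed = 3, nlambda = 40)
  Wg0 <- stat_weighted_lasso(d$XXk, d$y, phi, gamma_grid = 0, cv_folds = 5,
                             seed = 3, nlambda = 40)
  expect_equal(Wg0$W, W0$W)
  expect_equal(Wg0$lambda, W0$lambda)

  # phi constant at 1: any gamma collapses to a single common penalty
  Wc <- stat_weighted_lasso(d$XXk, d$y, rep(1, 15), lambda = 0.08, gamma = 0.7)
  Wu <- stat_lasso_coefdiff(d$XXk, d$y, lambda = 0.08)
  expect_equal(Wc$W, Wu$W, tolerance = 1e-8)
})

test_that("informative prior weights do not hurt the signal statistics", {
  reps <- 25
  diff_sum <- 0
  for (i in seq_len(reps)) {
    d <- make_knockoff_data(n = 200, p = 60, k = 8, effect = 0.3,
                            seed = 300 + i)
    phi <- ifelse(seq_len(60) %in% d$support, 0.5, 20)
    Ww <- stat_weighted_lasso(d$XXk, d$y, phi, gamma_grid = c(0, 0.5, 1),
                              cv_folds = 5, seed = i, nlambda = 40)
    Wu <- stat_lasso_coefdiff(d$XXk, d$y, cv_folds = 5, seed = i, nlambda = 40)
    diff_sum <- diff_sum + mean(Ww$W[d$support]) - mean(Wu$W[d$support])
  }
  expect_gt(diff_sum / reps, 0)
})

test_that("pooled coefficients are invariant to dataset order and duplication", {
  d1 <- make_knockoff_data(n = 90, p = 12, k = 3, seed = 21)
  d2 <- make_knockoff_data(n = 110, p = 12, k = 3, seed = 22)

  single <- pooled_coefficients(list(d1$XXk), list(d1$y), cv_folds = 5, seed = 5)
  alone <- stat_lasso_coefdiff(d1$XXk, d1$y, cv_folds = 5, seed = 5)
  expect_equal(single, alone$coef)

  lam <- 0.05
  ab <- pooled_coefficients(list(d1$XXk, d2$XXk), list(d1$y, d2$y), lambda = lam)
  ba <- pooled_coefficients(list(d2$XXk, d1$XXk), list(d2$y, d1$y), lambda = lam)
  expect_equal(ab, ba, tolerance = 1e-7)

  dup <- pooled_coefficients(list(d1$XXk, d1$XXk), list(d1$y, d1$y), lambda = lam)
  one <- pooled_coefficients(list(d1$XXk), list(d1$y), lambda = lam)
  expect_equal(dup, one, tolerance = 1e-6)

  expect_error(pooled_coefficients(list(), list()), "non-empty")
  expect_error(pooled_coefficients(list(d1$XXk, d2$XXk[, 1:10]),
                                   list(d1$y, d2$y)), "same p")
})

test_that("multi-source priors combine by the entrywise mean", {
  v <- rnorm(10)
  expect_equal(combine_priors(list(v)), v)
  expect_equal(combine_priors(list(rep(0, 4), rep(1, 4))), rep(0.5, 4))
  expect_equal(combine_priors(list(v, v, v)), v)
  expect_error(combine_priors(list(v, rnorm(9))), "length")
  expect_error(combine_priors(list()), "non-empty")
})

test_that("degenerate inputs are rejected", {
  d <- make_knockoff_data(n = 30, p = 5, seed = 31)
  expect_error(stat_lasso_coefdiff(d$XXk, rep(1, 30)), "constant")
  expect_error(stat_lasso_coefdiff(d$XXk, d$y, cv_folds = 40), "cv_folds")
  expect_error(stat_weighted_lasso(d$XXk, d$y, rep(-1, 5)), "positive")
  expect_error(stat_weighted_lasso(d$XXk, d$y, rep(1, 5),
                                   gamma_grid = c(0, 1.5)), "\\[0, 1\\]")
})
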