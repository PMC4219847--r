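test_that("lognormal MLE recovers generating parameters", {
  set.seed(21)
  x <- rlnorm(50, meanlog = -7, sdlog = 0.5)
  fit <- fit_parametric(x, "lognormal")
  se_mu <- 0.5 / sqrt(50)
  se_sd <- 0.5 / sqrt(2 * 50)
  expect_lt(abs(fit$estimate[["meanlog"]] + 7), 3 * se_mu)
  expect_lt(abs(fit$estimate[["sdlog"]] - 0.5), 3 * se_sd)
  expect_true(is.finite(fit$loglik))
})

test_that("likelihood prefers the generating family for exponential data", {
  set.seed(22)
  wins <- 0L
  for (i in 1:100) {
    x <- rexp(50, rate = 1000)
    le <- fit_parametric(x, "exponential")$loglik
    ll <- fit_parametric(x, "lognormal")$loglik
    if (le >= ll) wins <- wins + 1L
  }
  expect_gte(wins, 80L)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_parametric(rep(2, 10)), "degenerate")
  expect_error(fit_parametric(c(1, 2)), "at least 3")
  expect_error(fit_parametric(c(1, -2, 3)), "positive")
  expect_error(lognormal_average(c(1, 0)), "positive")
  expect_error(split_half_likelihood(c(1, 2, 3, 4)), "even-sized")
})

test_that("split-half likelihoods agree under a common distribution", {
  set.seed(23)
  x <- rlnorm(100, -7, 0.5)
  L <- split_half_likelihood(x, "lognormal")
  # per-observation likelihoods of the two halves agree within sampling
  # error of the mean log-density (sd of a lognormal log-density ~ 1)
  expect_lt(abs(L[1] - L[2]) / 50, 3 * sqrt(2 / 50))
  # a gross shift in the holdout half collapses its likelihood
  y <- c(x[1:50], x[51:100] * 100)
  L2 <- split_half_likelihood(y, "lognormal")
  expect_lt(L2[2], L[2] - 100)
})

test_that("rank-sum decisions match expectations at the design sizes", {
  set.seed(24)
  x <- rlnorm(50, -7, 0.5)
  expect_identical(rank_sum_decision(x, x)$decision, 0L)
  y <- rlnorm(10, -7, 0.5) * 100
  expect_identical(rank_sum_decision(x, y)$decision, 1L)
})

test_that("rank-sum type-I error is near the nominal 5% level", {
  set.seed(25)
  rejections <- 0L
  n_trials <- 2000L
  for (i in seq_len(n_trials)) {
    x <- rlnorm(50, -7, 0.5)
    y <- rlnorm(10, -7, 0.5)
    rejections <- rejections + rank_sum_decision(x, y)$decision
  }
  rate <- rejections / n_trials
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("lognormal average follows the chosen moment convention", {
  expect_equal(lognormal_average(rep(3, 5)), 3)
  x <- c(exp(-1), exp(1))
  s2 <- var(log(x))      # unbiased: 2
  expect_equal(lognormal_average(x), exp(0 + s2 / 2))
  expect_equal(lognormal_average(x, type = "median"), 1)
  set.seed(26)
  x <- rlnorm(40, -5, 1)
  expect_equal(lognormal_average(x), lognormal_average(sample(x)))
})

test_that("ensemble refit returns one constant set per successful run", {
  kt <- battle_constants("expT")
  ps <- ensemble_refit(kt, n_runs = 4,
                       fit_options = list(free = c(1, 2), grid_step = 300,
                                          control = list(maxit = 150)),
                       seed = 31)
  expect_s3_class(ps, "param_sample")
  expect_identical(dim(ps$samples), c(4L, 15L))
  expect_true(all(ps$samples[, 1:2] > 0))
  expect_identical(ps$n_failed, 0L)
  # reproducible end to end
  ps2 <- ensemble_refit(kt, n_runs = 4,
                        fit_options = list(free = c(1, 2), grid_step = 300,
                                           control = list(maxit = 150)),
                        seed = 31)
  expect_identical(ps$samples, ps2$samples)
  # an ensemble with zero rates has no events and fails loudly
  expect_error(ensemble_refit(rep(0, 15), n_runs = 2, seed = 1), "failed")
})

test_that("validation pipeline is dominated by 0 decisions under the null", {
  set.seed(27)
  # synthetic ensembles: both drawn from the same lognormal per reaction
  mu <- log(battle_constants("expT"))
  sim <- sapply(1:15, function(i) rlnorm(100, mu[i], 0.4))
  exp_ <- sapply(1:15, function(i) rlnorm(20, mu[i], 0.4))
  colnames(sim) <- colnames(exp_) <- paste0("k", 1:15)
  rep_ <- validation_report(sim, exp_)
  expect_identical(nrow(rep_), 15L)
  expect_true(all(is.finite(as.matrix(rep_[, 2:5]))))
  decisions <- as.matrix(rep_[, c("W1", "W2", "W3", "W4")])
  expect_gte(mean(decisions == 0), 0.8)
})
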