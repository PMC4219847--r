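test_that("zero rates produce no events", {
  es <- ssa_run(c(10, 10, 0, 0, 0), rep(0, 15), t_max = 100, seed = 1)
  expect_identical(nrow(es), 1L)
  expect_equal(unname(attr(es, "final")), c(10, 10, 0, 0, 0),
               ignore_attr = TRUE)
})

test_that("single-pair waiting time is exponential with rate k1", {
  k1 <- 1e-3
  k <- only_k(1, k1)
  n <- 1e4
  set.seed(5)
  seeds <- sample.int(.Machine$integer.max, n)
  times <- vapply(seeds, function(s) {
    es <- ssa_run(c(1, 1, 0, 0, 0), k, t_max = 1e7, seed = s)
    expect_identical(nrow(es), 2L)  # exactly one event, then absorption
    es$time[2]
  }, numeric(1))
  se <- (1 / k1) / sqrt(n)
  expect_lt(abs(mean(times) - 1 / k1), 3 * se)
})

test_that("same seed reproduces the event series bit for bit", {
  k <- battle_constants("expT")
  a <- ssa_run(c(10, 10, 0, 0, 0), k, t_max = 3600, seed = 99)
  b <- ssa_run(c(10, 10, 0, 0, 0), k, t_max = 3600, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- ssa_run(c(10, 10, 0, 0, 0), k, t_max = 3600, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("totals decrease only at the five casualty channels", {
  k <- battle_constants("expM")
  es <- ssa_run(c(10, 10, 0, 0, 0), k, t_max = 18000, seed = 17)
  tot <- population_totals(es[, species_cols])
  dA <- diff(tot[, "totalA"])
  dB <- diff(tot[, "totalB"])
  ch <- es$channel[-1]
  expect_true(all(dA <= 0) && all(dB <= 0))
  expect_true(all(ch[dA < 0] %in% c(3, 8, 13)))
  expect_true(all(ch[dB < 0] %in% c(4, 7)))
  expect_true(all(dA[ch %in% c(3, 8, 13)] == -1))
  expect_true(all(dB[ch %in% c(4, 7)] == -1))
})

test_that("every transition applies one registry stoichiometry", {
  S <- antbattle:::stoich_matrix()
  es <- ssa_run(c(10, 10, 0, 0, 0), battle_constants("expT"),
                t_max = 3600, seed = 23)
  st <- as.matrix(es[, species_cols])
  for (i in seq_len(nrow(es) - 1L)) {
    expect_equal(unname(st[i + 1L, ] - st[i, ]),
                 unname(S[, es$channel[i + 1L]]))
  }
  expect_true(all(diff(es$time) > 0))
})

test_that("absorption leaves zero total propensity", {
  k <- battle_constants("expM")
  es <- ssa_run(c(3, 3, 0, 0, 0), k, t_max = 1e12, seed = 31)
  expect_true(attr(es, "absorbed"))
  fin <- attr(es, "final")
  expect_equal(sum(propensities(fin, k)), 0)
  tot <- population_totals(fin)
  expect_true(tot["totalA"] == 0 || tot["totalB"] == 0)
})

test_that("ensemble of one run has zero variance and equals the run", {
  k <- battle_constants("expT")
  ens <- ssa_ensemble(c(10, 10, 0, 0, 0), k, t_max = 600, n_runs = 1,
                      grid_step = 60, seed = 3)
  expect_true(all(ens$var == 0))
  set.seed(3)
  s1 <- sample.int(.Machine$integer.max, 1)
  es <- ssa_run(c(10, 10, 0, 0, 0), k, t_max = 600, seed = s1)
  held <- antbattle:::hold_states(es, ens$time)
  expect_equal(unname(ens$mean[, species_cols]), unname(held))
})

test_that("relative gap to the mean field shrinks with population size", {
  k_small <- battle_constants("expT")
  # rescale encounter rates so the large battle is the small one scaled
  # 20-fold in abundance: bimolecular / 20, termolecular / 400
  ord <- vapply(reaction_registry(), `[[`, numeric(1), "order")
  k_large <- k_small / 20^(ord - 1)
  gap <- function(n0, k, n_runs, seed) {
    grid <- seq(0, 3600, 300)
    ens <- ssa_ensemble(c(n0, n0, 0, 0, 0), k, t_max = 3600,
                        n_runs = n_runs, grid_step = 300, seed = seed)
    y <- antbattle:::integrate_states(c(n0, n0, 0, 0, 0), k, grid)
    sqrt(sum((ens$mean[, species_cols] - y)^2)) / n0
  }
  g10 <- gap(10, k_small, 40, seed = 2)
  g200 <- gap(200, k_large, 40, seed = 2)
  expect_lt(g200, g10)
})
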