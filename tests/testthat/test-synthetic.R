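test_that("interaction generator matches the study design and reproduces", {
  k <- battle_constants("expT")
  logs <- generate_interaction_dataset(k, n_experiments = 20, seed = 41)
  expect_length(logs, 20L)
  for (es in logs) {
    tot0 <- population_totals(es[1, species_cols])
    expect_equal(as.numeric(tot0), c(10, 10))
    expect_lte(max(es$time), 3600)
  }
  logs2 <- generate_interaction_dataset(k, n_experiments = 20, seed = 41)
  expect_identical(lapply(logs, as.data.frame), lapply(logs2, as.data.frame))
  # zero rates: logs contain only the initial row
  quiet <- generate_interaction_dataset(rep(0, 15), n_experiments = 2,
                                        seed = 1)
  expect_true(all(vapply(quiet, nrow, integer(1)) == 1L))
})

test_that("every generated log passes the reader's schema checks", {
  k <- battle_constants("expM")
  logs <- generate_interaction_dataset(k, n_experiments = 5, seed = 42)
  path <- tempfile(fileext = ".csv")
  for (es in logs) {
    write_event_table(es, path)
    expect_no_error(read_event_table(path))
  }
  unlink(path)
})

test_that("mortality generator produces the seven-set hourly design", {
  k <- battle_constants("expM")
  mort <- generate_mortality_dataset(k, n_replicates = 5, seed = 43)
  expect_length(mort, 7L)
  starts <- list(c(10, 10), c(5, 10), c(5, 11), c(5, 12), c(5, 13),
                 c(5, 14), c(5, 15))
  for (i in 1:7) {
    m <- mort[[i]]
    expect_equal(m$time_s, seq(0, 18000, 3600))
    expect_equal(c(m$survivors_A[1], m$survivors_B[1]), starts[[i]])
    # survivor means are non-increasing in time (pure attrition)
    expect_true(all(diff(m$survivors_A) <= 0))
    expect_true(all(diff(m$survivors_B) <= 0))
  }
  # fractional means arise from replicate averaging
  vals <- unlist(lapply(mort, function(m) c(m$survivors_A, m$survivors_B)))
  expect_true(any(vals != round(vals)))
  # no casualties, no attrition
  k0 <- battle_constants("expT")
  k0[c(3, 4, 7, 8, 13)] <- 0
  m0 <- generate_mortality_dataset(k0, initial_sets = list(c(5, 5)),
                                   n_replicates = 2, seed = 1)
  expect_true(all(m0$set1$survivors_A == 5) && all(m0$set1$survivors_B == 5))
  expect_error(generate_mortality_dataset(k, interval_s = 7000), "divide")
})

test_that("a synthetic study materialises on disk in the package schemas", {
  dir <- tempfile("study")
  make_synthetic_study(dir, seed = 2, n_experiments = 3, n_replicates = 2)
  expect_length(list.files(dir, pattern = "^interaction_"), 3L)
  expect_length(list.files(dir, pattern = "^mortality_"), 7L)
  expect_no_error(read_event_table(file.path(dir, "interaction_01.csv")))
  expect_equal(read_constants(file.path(dir, "constants_true.json")),
               battle_constants("expM"))
  unlink(dir, recursive = TRUE)
})

test_that("noise-free round trip recovers the generating trajectory", {
  rec <- parameter_recovery_experiment(battle_constants("expT"),
                                       free = c(1, 2, 6), ssa = FALSE,
                                       grid_step = 300,
                                       control = list(maxit = 400), seed = 5)
  expect_lt(rec$trajectory_rel_l2, 1e-3)
  expect_true(all(is.finite(rec$ratio) & rec$ratio > 0))
})

test_that("pooled stochastic round trip reports finite positive ratios", {
  rec <- parameter_recovery_experiment(battle_constants("expT"),
                                       n_experiments = 5, free = c(1, 2),
                                       grid_step = 300, ssa = TRUE,
                                       control = list(maxit = 200), seed = 6)
  expect_true(all(is.finite(rec$ratio) & rec$ratio > 0))
  # the duel-formation channels are identifiable from event-rich data
  expect_lt(abs(log10(rec$ratio[1])), 1)
  expect_lt(abs(log10(rec$ratio[2])), 1)
})
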