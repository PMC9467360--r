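test_that("trial_config validates inputs", {
  expect_error(trial_config("CB", p0 = 0.5, p1 = 0.5, pm0 = 0.6, n = 10),
               "pm0")
  expect_error(trial_config("XX", p0 = 0.5, p1 = 0.5, n = 10))
  cfg <- trial_config("CB", p0 = 0.5, p1 = 0.5, n = 10, seed = 1)
  expect_s3_class(cfg, "trial_config")
})

test_that("outcome generation is Bernoulli with independent MAR masking", {
  cfg <- trial_config("FR", p0 = 1, p1 = 0.9, pm0 = 0, pm1 = 0.5, n = 10,
                      seed = 1)
  set.seed(1)
  for (i in 1:20) {
    o <- generate_outcome(0L, cfg)
    expect_true(o$success)   # p0 = 1
    expect_false(o$missing)  # pm0 = 0
  }
  # arm 1: empirical frequencies and outcome/missingness independence
  set.seed(2)
  draws <- t(replicate(8000, unlist(generate_outcome(1L, cfg))))
  expect_equal(mean(draws[, "success"]), 0.9, tolerance = 0.02)
  expect_equal(mean(draws[, "missing"]), 0.5, tolerance = 0.03)
  chi <- suppressWarnings(
    stats::chisq.test(table(draws[, "success"], draws[, "missing"])))
  expect_gt(chi$p.value, 1e-4)
})

test_that("mean imputation draws at the observed success rate", {
  cfg <- trial_config("FR", p0 = 0.5, p1 = 0.5, pm0 = 0.3, pm1 = 0.3,
                      n = 10, imputation = "mean", seed = 1)
  set.seed(5)
  # no observations yet: default initial estimate 0.5
  v <- replicate(4000, impute_missing(0L, 0L, cfg))
  expect_equal(mean(v), 0.5, tolerance = 0.03)
  # S = 3, F = 1: Bernoulli(0.75)
  v <- replicate(4000, impute_missing(3L, 1L, cfg))
  expect_equal(mean(v), 0.75, tolerance = 0.03)
  # deterministic extremes
  expect_true(all(replicate(50, impute_missing(4L, 0L, cfg))))
  expect_false(any(replicate(50, impute_missing(0L, 4L, cfg))))
  # variant: a large initial estimate
  cfg9 <- trial_config("FR", p0 = 0.5, p1 = 0.5, pm0 = 0.3, pm1 = 0.3,
                       n = 10, imputation = "mean", impute_initial = 0.9)
  v <- replicate(4000, impute_missing(0L, 0L, cfg9))
  expect_equal(mean(v), 0.9, tolerance = 0.03)
  # variant: no imputation before the first observed outcome
  cfga <- trial_config("FR", p0 = 0.5, p1 = 0.5, pm0 = 0.3, pm1 = 0.3,
                       n = 10, imputation = "mean", impute_after_first = TRUE)
  expect_true(is.na(impute_missing(0L, 0L, cfga)))
})

test_that("vectorized engine reproduces the scalar reference step for step", {
  tab <- cached_gittins_table(0.99, 40)
  for (alg in bandit_policies()) {
    for (imp in c("off", "mean")) {
      cfg <- trial_config(alg, p0 = 0.6, p1 = 0.4, pm0 = 0.2, pm1 = 0.4,
                          n = 34, imputation = imp, seed = 902L)
      set.seed(cfg$seed)
      ref <- run_trial_scalar(cfg, gittins = tab)
      rec <- run_trial(cfg, gittins = tab)
      expect_identical(rec$assignments, ref$assignments,
                       label = paste(alg, imp, "assignments"))
      expect_identical(rec$outcomes_true, ref$outcomes_true)
      expect_identical(rec$missing_mask, ref$missing_mask)
      expect_identical(rec$imputed_values, ref$imputed_values)
      expect_equal(unname(rec$trajectory), unname(ref$trajectory),
                   tolerance = 1e-12, label = paste(alg, imp, "trajectory"))
      expect_identical(unclass(rec$arms$arm0), unclass(ref$arms$arm0))
      expect_identical(unclass(rec$arms$arm1), unclass(ref$arms$arm1))
    }
  }
})

test_that("ledgers balance: allocations, observations and missing counts", {
  tab <- cached_gittins_table(0.99, 40)
  for (alg in c("CB", "UCB", "RPW", "GI", "TTS")) {
    cfg <- trial_config(alg, p0 = 0.3, p1 = 0.5, pm0 = 0.25, pm1 = 0.10,
                        n = 36, seed = 11L)
    sims <- run_replications(cfg, R = 50, gittins = tab)
    r <- sims$reps
    expect_true(all(r$N0 + r$N1 == 36L))
    expect_true(all(r$S0 + r$F0 + r$M0 == r$N0))
    expect_true(all(r$S1 + r$F1 + r$M1 == r$N1))
    expect_true(all(r$S_imp0 + r$F_imp0 == 0L))  # imputation off
  }
  # with imputation on, imputed counts stay within the missing counts
  cfg <- trial_config("CB", p0 = 0.3, p1 = 0.5, pm0 = 0.25, pm1 = 0.10,
                      n = 36, imputation = "mean", seed = 11L)
  r <- run_replications(cfg, R = 50)$reps
  expect_true(all(r$S_imp0 + r$F_imp0 <= r$M0))
  expect_true(all(r$S_imp1 + r$F_imp1 <= r$M1))
})

test_that("same seed gives bit-identical runs; R = 1 equals run_trial", {
  cfg <- trial_config("RBI", p0 = 0.4, p1 = 0.6, pm0 = 0.1, pm1 = 0.3,
                      n = 40, seed = 77L)
  s1 <- run_replications(cfg, R = 200)
  s2 <- run_replications(cfg, R = 200)
  expect_identical(s1$reps, s2$reps)
  rec <- run_trial(cfg)
  one <- run_replications(cfg, R = 1, record_trajectory = TRUE)
  expect_identical(rec$assignments, one$records[[1]]$assignments)
})

test_that("without missingness, imputation settings change nothing", {
  for (alg in c("CB", "RTS", "UCB")) {
    base <- trial_config(alg, p0 = 0.7, p1 = 0.7, pm0 = 0, pm1 = 0,
                         n = 50, seed = 33L)
    imp <- trial_config(alg, p0 = 0.7, p1 = 0.7, pm0 = 0, pm1 = 0,
                        n = 50, imputation = "mean", seed = 33L)
    expect_identical(run_replications(base, R = 100)$reps,
                     run_replications(imp, R = 100)$reps)
  }
})

test_that("imputation toggling preserves the outcome stream (common random numbers)", {
  off <- trial_config("UCB", p0 = 0.5, p1 = 0.5, pm0 = 0.4, pm1 = 0.4,
                      n = 30, imputation = "off", seed = 5L)
  on <- trial_config("UCB", p0 = 0.5, p1 = 0.5, pm0 = 0.4, pm1 = 0.4,
                     n = 30, imputation = "mean", seed = 5L)
  ro <- run_trial(off); ri <- run_trial(on)
  # allocations may diverge after the first imputation, but draws up to the
  # first missing outcome coincide
  first_miss <- which(ro$missing_mask)[1]
  expect_identical(ro$assignments[seq_len(first_miss)],
                   ri$assignments[seq_len(first_miss)])
  expect_identical(ro$outcomes_true[seq_len(first_miss)],
                   ri$outcomes_true[seq_len(first_miss)])
})

test_that("per-arm missingness frequencies match their probabilities", {
  cfg <- trial_config("FR", p0 = 0.6, p1 = 0.6, pm0 = 0.1, pm1 = 0.4,
                      n = 100, seed = 9L)
  r <- run_replications(cfg, R = 2000)$reps
  expect_equal(sum(r$M0) / sum(r$N0), 0.1, tolerance = 0.01)
  expect_equal(sum(r$M1) / sum(r$N1), 0.4, tolerance = 0.01)
})

test_that("fixed randomization under the null allocates half on average", {
  cfg <- trial_config("FR", p0 = 0.4, p1 = 0.4, pm0 = 0.2, pm1 = 0.5,
                      n = 100, seed = 123L)
  sims <- run_replications(cfg, R = 2000)
  s <- summarize_replications(sims)
  expect_lt(abs(s$mean_pstar - 0.5), 3 * s$se_pstar + 1e-9)
})

test_that("label symmetry: swapping arms mirrors the allocation proportion", {
  tab <- cached_gittins_table(0.99, 65)
  for (alg in bandit_policies()) {
    R <- if (alg == "TTS") 400 else 1500
    a <- trial_config(alg, p0 = 0.3, p1 = 0.6, pm0 = 0.4, pm1 = 0.1,
                      n = 60, seed = 21L)
    b <- trial_config(alg, p0 = 0.6, p1 = 0.3, pm0 = 0.1, pm1 = 0.4,
                      n = 60, seed = 22L)
    sa <- summarize_replications(run_replications(a, R = R, gittins = tab))
    sb <- summarize_replications(run_replications(b, R = R, gittins = tab))
    se <- sqrt(sa$se_pstar^2 + sb$se_pstar^2)
    expect_lt(abs(sa$mean_pstar - (1 - sb$mean_pstar)), 4 * se + 1e-9,
              label = paste("label symmetry for", alg))
  }
})

test_that("trajectory recording is refused for large R", {
  cfg <- trial_config("FR", p0 = 0.5, p1 = 0.5, n = 10, seed = 1)
  expect_error(run_replications(cfg, R = 500, record_trajectory = TRUE),
               "R <= 100")
})
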