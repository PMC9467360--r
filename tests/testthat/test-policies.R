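test_that("posterior mean uses prior plus observed plus imputed counts", {
  expect_equal(posterior_mean(arm_state()), 0.5)
  expect_equal(posterior_mean(arm_state(S = 3, F = 1)), 4 / 6)
  expect_equal(posterior_mean(arm_state(S = 198, F = 0)), 199 / 200)
  # imputed outcomes are folded into the policy-facing counts
  expect_equal(posterior_mean(arm_state(S = 2, F = 1, M = 2, S_imp = 1,
                                        F_imp = 1)),
               4 / 7)
})

test_that("arm_state validates its fields", {
  expect_error(arm_state(S = -1), "non-negative")
  expect_error(arm_state(s0 = 0), "s0, f0")
  expect_error(arm_state(M = 1, S_imp = 1, F_imp = 1), "imputed")
})

test_that("prob_arm_best matches the quadrature oracle on small states", {
  expect_equal(prob_arm_best(arm_state(S = 2, F = 3), arm_state(S = 2, F = 3)),
               0.5)
  expect_equal(prob_arm_best(arm_state(S = 1), arm_state()), 2 / 3)
  expect_equal(prob_arm_best(arm_state(F = 1), arm_state()), 1 / 3)
  # sum-to-one contract and oracle agreement on a sample of integer states
  set.seed(42)
  for (i in 1:25) {
    ab <- sample(1:12, 4, replace = TRUE)
    p <- beta_prob_greater(ab[1], ab[2], ab[3], ab[4])
    expect_equal(p, oracle_prob_greater(ab[1], ab[2], ab[3], ab[4]),
                 tolerance = 1e-10)
    expect_equal(p + beta_prob_greater(ab[3], ab[4], ab[1], ab[2]), 1,
                 tolerance = 1e-12)
  }
})

test_that("single-observation recurrence reproduces the direct finite sum", {
  set.seed(7)
  for (i in 1:40) {
    ab <- sample(1:30, 4, replace = TRUE)
    a1 <- ab[1]; b1 <- ab[2]; a0 <- ab[3]; b0 <- ab[4]
    q <- beta_prob_greater(a1, b1, a0, b0)
    expect_equal(beta_prob_greater_step(q, a1, b1, a0, b0, 1L, TRUE),
                 beta_prob_greater(a1 + 1, b1, a0, b0), tolerance = 1e-12)
    expect_equal(beta_prob_greater_step(q, a1, b1, a0, b0, 1L, FALSE),
                 beta_prob_greater(a1, b1 + 1, a0, b0), tolerance = 1e-12)
    expect_equal(beta_prob_greater_step(q, a1, b1, a0, b0, 0L, TRUE),
                 beta_prob_greater(a1, b1, a0 + 1, b0), tolerance = 1e-12)
    expect_equal(beta_prob_greater_step(q, a1, b1, a0, b0, 0L, FALSE),
                 beta_prob_greater(a1, b1, a0, b0 + 1), tolerance = 1e-12)
  }
})

test_that("thompson allocation probabilities cover FR, RTS and TTS", {
  s <- list(arm_state(S = 5, F = 2), arm_state(S = 1, F = 4))
  expect_equal(thompson_allocation_probs(s, c = 0), c(0.5, 0.5))
  sym <- list(arm_state(S = 3, F = 3), arm_state(S = 3, F = 3))
  expect_equal(thompson_allocation_probs(sym, c = 1), c(0.5, 0.5))
  # c = 1 is the identity on the normalized best-arm probabilities
  q1 <- prob_arm_best(s[[1]], s[[2]])
  expect_equal(thompson_allocation_probs(s, c = 1), c(q1, 1 - q1))
  expect_equal(sum(thompson_allocation_probs(s, c = 0.37)), 1)
})

test_that("UCB index follows the printed formula and is increasing in t", {
  expect_equal(index_ucb(arm_state(), t = 1), 0.5)
  expect_equal(index_ucb(arm_state(S = 1), t = 3),
               2 / 3 + 2 * log(3) / 3)
  expect_equal(index_ucb(arm_state(), t = 10),
               0.5 + 2 * log(10) / 2)
  ts <- 1:30
  vals <- vapply(ts, function(t) index_ucb(arm_state(S = 2, F = 1), t),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  # more observations at fixed mean shrink the bonus
  expect_lt(index_ucb(arm_state(S = 9, F = 9), t = 5),
            index_ucb(arm_state(S = 1, F = 1), t = 5))
  expect_error(index_ucb(arm_state(), t = 0), "t")
})

test_that("RandUCB reduces to UCB at M = 1 and stays within its support", {
  st <- arm_state(S = 2, F = 5)
  beta3 <- 2 * log(3)
  expect_equal(index_randucb(st, M_points = 1, L = beta3, U = beta3),
               index_ucb(st, t = 3))
  expect_equal(index_randucb(st, z = 0), posterior_mean(st))
  set.seed(1)
  v <- replicate(200, index_randucb(arm_state(), M_points = 20, L = 0, U = 1))
  expect_true(all(v >= 0.5 & v <= 1.0))
  # support points are equally spaced over [L, U]
  z <- sort(unique(round((v - 0.5) * 2, 10)))
  expect_true(all(z %in% round(seq(0, 1, length.out = 20), 10)))
})

test_that("perturbed indices add exponential noise above their base", {
  st <- arm_state(S = 4, F = 2)
  expect_equal(index_perturbed(st, "belief", z = 0), posterior_mean(st))
  expect_equal(index_perturbed(arm_state(), "belief", z = 1), 1.5)
  tab <- compute_gittins_table(d = 0.3, max_total = 10, tol = 1e-8)
  expect_equal(index_perturbed(arm_state(), "gittins", table = tab, z = 0),
               gittins_lookup(tab, 1, 1))
  expect_error(index_perturbed(st, "gittins"), "gittins_table")
  set.seed(2)
  v <- replicate(100, index_perturbed(st, "belief"))
  expect_true(all(v > posterior_mean(st)))
})

test_that("play-the-winner urn draws and updates follow the classical rule", {
  set.seed(3)
  draws <- replicate(4000, rpw_draw(c(3L, 1L)))
  expect_equal(mean(draws == 0L), 0.75, tolerance = 0.03)
  expect_equal(rpw_draw(c(0L, 5L)), 1L)
  expect_error(rpw_draw(c(0L, 0L)), "empty")
  expect_equal(rpw_update(c(1L, 1L), 1L, "success"), c(1L, 2L))
  expect_equal(rpw_update(c(1L, 1L), 1L, "failure"), c(2L, 1L))
  expect_equal(rpw_update(c(2L, 3L), 0L, "missing"), c(2L, 3L))
})

test_that("select_arm breaks exact ties uniformly and samples correctly", {
  set.seed(4)
  expect_equal(select_arm(c(0.7, 0.5), "argmax"), 0L)
  expect_equal(select_arm(c(0.5, 0.7), "argmax"), 1L)
  ties <- replicate(4000, select_arm(c(0.5, 0.5), "argmax"))
  expect_equal(mean(ties), 0.5, tolerance = 0.03)
  samp <- replicate(4000, select_arm(c(0.3, 0.7), "sample"))
  expect_equal(mean(samp == 1L), 0.7, tolerance = 0.03)
  expect_error(select_arm(c(NaN, 0.5), "argmax"), "finite")
  expect_error(select_arm(c(0.4, 0.4), "sample"), "sum to 1")
})

test_that("exchanging arm states exchanges every rule's decision distribution", {
  st_a <- arm_state(S = 6, F = 1)
  st_b <- arm_state(S = 2, F = 3)
  # randomized rules: probabilities swap exactly
  p <- thompson_allocation_probs(list(st_a, st_b), c = 1)
  p_sw <- thompson_allocation_probs(list(st_b, st_a), c = 1)
  expect_equal(p, rev(p_sw))
  # index rules: index values are a function of the own-arm state only
  expect_equal(index_cb(st_a), posterior_mean(st_a))
  tab <- compute_gittins_table(d = 0.3, max_total = 15, tol = 1e-8)
  expect_equal(index_gi(st_a, tab), gittins_lookup(tab, 7, 2))
})
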