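# Scalar reference engine: one replication simulated step by step through
# the exported policy operations, consuming the RNG stream in exactly the
# order the vectorized engine does (perturbation draws, allocation draw,
# outcome draw, missingness draw, imputation draw — the last always drawn).
# Used to pin the vectorized engine to the documented per-step semantics.
run_trial_scalar <- function(config, gittins = NULL) {
  n <- config$n
  alg <- config$algorithm
  st0 <- arm_state(s0 = config$s0, f0 = config$f0)
  st1 <- arm_state(s0 = config$s0, f0 = config$f0)
  urn <- c(1L, 1L)
  assignments <- integer(n)
  outcomes <- logical(n)
  missing_mask <- logical(n)
  imputed <- rep(NA, n)
  traj <- matrix(NA_real_, n, 2L)

  for (t in seq_len(n)) {
    if (alg %in% c("FR", "TTS", "RTS", "RPW")) {
      probs <- switch(alg,
        FR = c(0.5, 0.5),
        RTS = thompson_allocation_probs(list(st0, st1), c = 1),
        TTS = thompson_allocation_probs(list(st0, st1), c = (t - 1) / (2 * n)),
        RPW = urn / sum(urn))
      traj[t, ] <- probs
      arm <- select_arm(probs, mode = "sample")
    } else {
      vals <- switch(alg,
        CB = c(index_cb(st0), index_cb(st1)),
        GI = c(index_gi(st0, gittins), index_gi(st1, gittins)),
        UCB = c(index_ucb(st0, t), index_ucb(st1, t)),
        RandUCB = c(
          index_randucb(st0, config$M_points, config$L, config$U),
          index_randucb(st1, config$M_points, config$L, config$U)),
        RBI = c(index_perturbed(st0, "belief"),
                index_perturbed(st1, "belief")),
        RGI = c(index_perturbed(st0, "gittins", table = gittins),
                index_perturbed(st1, "gittins", table = gittins)))
      traj[t, ] <- vals
      arm <- select_arm(vals, mode = "argmax")
    }
    out <- generate_outcome(arm, config)
    y <- out$success; miss <- out$missing
    uimp <- stats::runif(1L)  # always consumed, as in the engine
    st <- if (arm == 1L) st1 else st0
    if (!miss) {
      if (y) st$S <- st$S + 1L else st$F <- st$F + 1L
      urn <- rpw_update(urn, arm, if (y) "success" else "failure")
    } else {
      st$M <- st$M + 1L
      filled <- identical(config$impute_source, "filled")
      iS <- st$S + if (filled) st$S_imp else 0L
      iF <- st$F + if (filled) st$F_imp else 0L
      if (config$imputation == "mean" &&
          (!config$impute_after_first || st$S + st$F > 0L)) {
        phat <- if (iS + iF == 0L) config$impute_initial
                else iS / (iS + iF)
        yi <- uimp < phat
        if (yi) st$S_imp <- st$S_imp + 1L else st$F_imp <- st$F_imp + 1L
        imputed[t] <- yi
        urn <- rpw_update(urn, arm, if (yi) "success" else "failure")
      } else {
        urn <- rpw_update(urn, arm, "missing")
      }
    }
    if (arm == 1L) st1 <- st else st0 <- st
    assignments[t] <- arm
    outcomes[t] <- y
    missing_mask[t] <- miss
  }
  list(assignments = assignments, outcomes_true = outcomes,
       missing_mask = missing_mask, imputed_values = imputed,
       trajectory = traj, arms = list(arm0 = st0, arm1 = st1))
}
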