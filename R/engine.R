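# Vectorized trial engine: all R replications advance in lockstep, one
# patient at a time. Per-replication state lives in plain vectors; every
# per-patient random quantity is drawn in a fixed order (perturbations,
# allocation, outcome, missingness, imputation) regardless of which values a
# policy actually uses, so that configurations differing only in the
# imputation setting see identical outcome/missingness streams.
#
# Two ledgers per arm: the observed-only ledger (S, F) feeds the metrics and
# the imputation estimate p-hat; the policy-facing ledger adds the imputed
# counts (S + S_imp, F + F_imp). Missing outcomes' true values are tallied
# separately (TS) for the expected-number-of-successes oracle and never
# reach any policy.

sim_engine <- function(config, R, gittins = NULL, record_trajectory = FALSE) {
  alg <- config$algorithm
  n <- config$n
  p0 <- config$p0; p1 <- config$p1
  pm0 <- config$pm0; pm1 <- config$pm1
  s0 <- config$s0; f0 <- config$f0
  impute <- config$imputation == "mean"
  imp_init <- config$impute_initial
  imp_after <- config$impute_after_first
  imp_filled <- identical(config$impute_source, "filled")

  zero <- integer(R)
  S0 <- zero; F0 <- zero; S1 <- zero; F1 <- zero      # observed
  M0 <- zero; M1 <- zero                              # missing (all)
  Si0 <- zero; Fi0 <- zero; Si1 <- zero; Fi1 <- zero  # imputed
  TS0 <- zero; TS1 <- zero                            # true successes
  N0 <- zero; N1 <- zero

  randomized <- alg %in% c("FR", "TTS", "RTS", "RPW")
  thompson <- alg %in% c("TTS", "RTS")
  if (thompson) {
    q <- rep(beta_prob_greater(s0, f0, s0, f0), R)  # P(p1 > p0) at the prior
  }
  if (alg == "RPW") { B0 <- rep(1L, R); B1 <- rep(1L, R) }
  if (alg %in% c("GI", "RGI")) {
    Gv <- gittins$values
    gsz <- nrow(Gv)
  }

  if (record_trajectory) {
    traj0 <- matrix(NA_real_, n, R); traj1 <- matrix(NA_real_, n, R)
    armmat <- matrix(NA_integer_, n, R)
    ymat <- matrix(NA, n, R); missmat <- matrix(NA, n, R)
    impmat <- matrix(NA, n, R)
  }

  for (t in seq_len(n)) {
    # policy-facing Beta parameters
    a0 <- s0 + S0 + Si0; b0 <- f0 + F0 + Fi0
    a1 <- s0 + S1 + Si1; b1 <- f0 + F1 + Fi1

    if (randomized) {
      pi1 <- switch(alg,
        FR = rep(0.5, R),
        RTS = q,
        TTS = {
          cc <- (t - 1) / (2 * n)
          qc <- pmin(pmax(q, 1e-15), 1 - 1e-15)
          w1 <- qc^cc
          w0 <- (1 - qc)^cc
          w1 / (w0 + w1)
        },
        RPW = B1 / (B0 + B1))
      ualloc <- stats::runif(R)
      arm <- as.integer(ualloc >= 1 - pi1)
      if (record_trajectory) { traj0[t, ] <- 1 - pi1; traj1[t, ] <- pi1 }
    } else {
      v0 <- switch(alg,
        CB = a0 / (a0 + b0),
        GI = Gv[a0 + (b0 - 1L) * gsz],
        UCB = a0 / (a0 + b0) + 2 * log(t) / (a0 + b0),
        RandUCB = a0 / (a0 + b0) +
          randucb_draw(R, config$M_points, config$L, config$U) / (a0 + b0),
        RBI = a0 / (a0 + b0) + stats::rexp(R, rate = 0.5) * 2 / (a0 + b0),
        RGI = Gv[a0 + (b0 - 1L) * gsz] +
          stats::rexp(R, rate = 0.5) * 2 / (a0 + b0))
      v1 <- switch(alg,
        CB = a1 / (a1 + b1),
        GI = Gv[a1 + (b1 - 1L) * gsz],
        UCB = a1 / (a1 + b1) + 2 * log(t) / (a1 + b1),
        RandUCB = a1 / (a1 + b1) +
          randucb_draw(R, config$M_points, config$L, config$U) / (a1 + b1),
        RBI = a1 / (a1 + b1) + stats::rexp(R, rate = 0.5) * 2 / (a1 + b1),
        RGI = Gv[a1 + (b1 - 1L) * gsz] +
          stats::rexp(R, rate = 0.5) * 2 / (a1 + b1))
      ualloc <- stats::runif(R)
      arm <- ifelse(v1 > v0, 1L, ifelse(v1 < v0, 0L, as.integer(ualloc < 0.5)))
      if (record_trajectory) { traj0[t, ] <- v0; traj1[t, ] <- v1 }
    }

    uout <- stats::runif(R)
    y <- uout < p0 + (p1 - p0) * arm
    umiss <- stats::runif(R)
    miss <- umiss < pm0 + (pm1 - pm0) * arm
    uimp <- stats::runif(R)  # always drawn: common random numbers

    is1 <- arm == 1L
    observed <- !miss
    if (impute) {
      obs_tot <- ifelse(is1, S1 + F1, S0 + F0)
      if (imp_filled) {
        Sarm <- ifelse(is1, S1 + Si1, S0 + Si0)
        Farm <- ifelse(is1, F1 + Fi1, F0 + Fi0)
      } else {
        Sarm <- ifelse(is1, S1, S0)
        Farm <- ifelse(is1, F1, F0)
      }
      tot <- Sarm + Farm
      phat <- ifelse(tot > 0L, Sarm / pmax(tot, 1L), imp_init)
      # the after-first-observation gate always refers to observed outcomes
      do_imp <- miss & (!imp_after | obs_tot > 0L)
      yimp <- uimp < phat
    } else {
      do_imp <- rep(FALSE, R)
      yimp <- rep(NA, R)
    }

    # policy-facing observation events and their outcome values
    upd <- observed | do_imp
    yy <- ifelse(observed, y, yimp)

    if (thompson && any(upd)) {
      q[upd] <- beta_prob_greater_step(q[upd], a1[upd], b1[upd],
                                       a0[upd], b0[upd],
                                       arm[upd], yy[upd])
    }
    if (alg == "RPW") {
      B1 <- B1 + (upd & ((is1 & yy) | (!is1 & !yy)))
      B0 <- B0 + (upd & ((!is1 & yy) | (is1 & !yy)))
    }

    S1 <- S1 + (is1 & observed & y);  F1 <- F1 + (is1 & observed & !y)
    S0 <- S0 + (!is1 & observed & y); F0 <- F0 + (!is1 & observed & !y)
    M1 <- M1 + (is1 & miss);          M0 <- M0 + (!is1 & miss)
    Si1 <- Si1 + (is1 & do_imp & yimp);  Fi1 <- Fi1 + (is1 & do_imp & !yimp)
    Si0 <- Si0 + (!is1 & do_imp & yimp); Fi0 <- Fi0 + (!is1 & do_imp & !yimp)
    TS1 <- TS1 + (is1 & y); TS0 <- TS0 + (!is1 & y)
    N1 <- N1 + is1; N0 <- N0 + !is1

    if (record_trajectory) {
      armmat[t, ] <- arm
      ymat[t, ] <- y
      missmat[t, ] <- miss
      impmat[t, ] <- ifelse(do_imp, yimp, NA)
    }
  }

  reps <- data.frame(
    N0 = N0, N1 = N1, S0 = S0, F0 = F0, S1 = S1, F1 = F1,
    M0 = M0, M1 = M1, S_imp0 = Si0, F_imp0 = Fi0,
    S_imp1 = Si1, F_imp1 = Fi1, TS0 = TS0, TS1 = TS1,
    pstar = N1 / n)

  out <- list(reps = reps, config = config, R = R)
  if (record_trajectory) {
    out$records <- lapply(seq_len(R), function(r) {
      list(assignments = armmat[, r],
           outcomes_true = ymat[, r],
           missing_mask = missmat[, r],
           imputed_values = impmat[, r],
           trajectory = cbind(arm0 = traj0[, r], arm1 = traj1[, r]),
           arms = list(
             arm0 = arm_state(S = S0[r], F = F0[r], M = M0[r],
                              S_imp = Si0[r], F_imp = Fi0[r],
                              s0 = s0, f0 = f0),
             arm1 = arm_state(S = S1[r], F = F1[r], M = M1[r],
                              S_imp = Si1[r], F_imp = Fi1[r],
                              s0 = s0, f0 = f0)))
    })
  }
  class(out) <- "bandit_sims"
  out
}
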