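#' Posterior/counting state of one treatment arm
#'
#' Bookkeeping for a single Bernoulli arm under a Beta prior: prior
#' pseudo-counts, observed successes and failures, missing outcomes, and
#' (when mean imputation is used) imputed successes and failures. Allocation
#' rules see the *policy-facing* counts, i.e. prior + observed + imputed;
#' missing outcomes never enter the posterior.
#'
#' @param S,F observed success / failure counts.
#' @param M number of missing outcomes (imputed or not).
#' @param S_imp,F_imp imputed success / failure counts (a subset of the
#'   missing outcomes).
#' @param s0,f0 prior pseudo-counts; both must be >= 1 so the posterior mean
#'   is always defined. The default Beta(1, 1) is the uniform prior.
#' @return an object of class \code{"arm_state"}.
#' @examples
#' arm_state(S = 3, F = 1)
#' posterior_mean(arm_state(S = 3, F = 1))
#' @export
arm_state <- function(S = 0L, F = 0L, M = 0L, S_imp = 0L, F_imp = 0L,
                      s0 = 1L, f0 = 1L) {
  x <- list(S = as.integer(S), F = as.integer(F), M = as.integer(M),
            S_imp = as.integer(S_imp), F_imp = as.integer(F_imp),
            s0 = as.integer(s0), f0 = as.integer(f0))
  vals <- unlist(x)
  if (any(is.na(vals)) || any(vals < 0L))
    stop("arm_state fields must be non-negative integers")
  if (x$s0 < 1L || x$f0 < 1L)
    stop("prior pseudo-counts s0, f0 must be >= 1")
  if (x$S_imp + x$F_imp > x$M)
    stop("imputed counts cannot exceed the number of missing outcomes")
  class(x) <- "arm_state"
  x
}

#' @export
print.arm_state <- function(x, ...) {
  cat(sprintf(
    "arm_state: Beta(%d, %d) prior; observed %d/%d successes, %d missing (%d imputed)\n",
    x$s0, x$f0, x$S, x$S + x$F, x$M, x$S_imp + x$F_imp))
  invisible(x)
}

# policy-facing Beta parameters: prior + observed + imputed
policy_beta <- function(state) {
  c(a = state$s0 + state$S + state$S_imp,
    b = state$f0 + state$F + state$F_imp)
}

#' Posterior mean success probability of an arm
#'
#' The Beta posterior mean \eqn{(s_0 + S)/(s_0 + f_0 + S + F)} computed on
#' the policy-facing counts (imputed outcomes included when imputation is
#' in use). This is the current-belief index.
#'
#' @param state an [arm_state()].
#' @return a probability in (0, 1).
#' @export
posterior_mean <- function(state) {
  ab <- policy_beta(state)
  unname(ab["a"] / (ab["a"] + ab["b"]))
}

#' Posterior probability that one arm beats another
#'
#' \eqn{P(p_a > p_b)} for independent posteriors \eqn{p_a \sim} Beta(a1, b1)
#' and \eqn{p_b \sim} Beta(a2, b2), evaluated with the exact finite-sum
#' identity for integer parameters (log-space for numerical stability).
#' Posterior ties have probability zero, so
#' \code{prob_arm_best(a, b) + prob_arm_best(b, a) == 1}.
#'
#' @param state_a,state_b [arm_state()] objects.
#' @return \eqn{P(p_a > p_b)} in \eqn{[0, 1]}.
#' @examples
#' prob_arm_best(arm_state(S = 1), arm_state())  # Beta(2,1) vs Beta(1,1): 2/3
#' @export
prob_arm_best <- function(state_a, state_b) {
  pa <- policy_beta(state_a)
  pb <- policy_beta(state_b)
  beta_prob_greater(pa["a"], pa["b"], pb["a"], pb["b"])
}

# P(X > Y), X ~ Beta(a1, b1), Y ~ Beta(a2, b2), integer parameters.
# Finite sum over i = 0..a1-1 of
#   B(a2 + i, b2 + b1) / ((b1 + i) B(1 + i, b1) B(a2, b2)),
# evaluated in log space. Vectorized over equal-length parameter vectors.
beta_prob_greater <- function(a1, b1, a2, b2) {
  n <- max(length(a1), length(b1), length(a2), length(b2))
  a1 <- rep_len(a1, n); b1 <- rep_len(b1, n)
  a2 <- rep_len(a2, n); b2 <- rep_len(b2, n)
  out <- numeric(n)
  for (j in seq_len(n)) {
    i <- seq_len(a1[j]) - 1
    out[j] <- sum(exp(
      lbeta(a2[j] + i, b2[j] + b1[j]) - log(b1[j] + i) -
        lbeta(1 + i, b1[j]) - lbeta(a2[j], b2[j])))
  }
  pmin(pmax(out, 0), 1)
}

# One-observation update of q = P(p1 > p0): when a single Beta parameter of
# either arm increases by one, q changes by an exactly known term. With the
# pre-update parameters (a1, b1) and (a0, b0),
#   t = B(a1 + a0, b1 + b0) / (x B(a1, b1) B(a0, b0))
# where x is the parameter being incremented; the sign is + for arm-1
# success and arm-0 failure, - otherwise. Vectorized; used by the trial
# engine so Thompson-type rules cost O(1) per patient.
beta_prob_greater_step <- function(q, a1, b1, a0, b0, arm, success) {
  x <- ifelse(arm == 1L, ifelse(success, a1, b1), ifelse(success, a0, b0))
  term <- exp(lbeta(a1 + a0, b1 + b0) - log(x) - lbeta(a1, b1) - lbeta(a0, b0))
  sgn <- ifelse((arm == 1L) == success, 1, -1)
  pmin(pmax(q + sgn * term, 0), 1)
}

#' Thompson-sampling allocation probabilities
#'
#' Allocation probabilities proportional to the posterior probability of
#' being the best arm raised to a tuning exponent \eqn{c}:
#' \eqn{\pi_k = q_k^c / \sum_j q_j^c}. \eqn{c = 0} is fixed randomization
#' (uniform regardless of the data), \eqn{c = 1} raw Thompson sampling, and
#' \eqn{c = t/(2n)} the tuned variant used in trial designs.
#'
#' @param states list of two [arm_state()] objects.
#' @param c non-negative tuning exponent.
#' @return numeric vector of two probabilities summing to one.
#' @export
thompson_allocation_probs <- function(states, c) {
  stopifnot(length(states) == 2L, c >= 0)
  q1 <- prob_arm_best(states[[1L]], states[[2L]])
  q <- c(q1, 1 - q1)
  if (all(q == 0)) stop("degenerate posterior: both best-arm probabilities are zero")
  if (c == 0) return(c(0.5, 0.5))
  w <- q^c
  w / sum(w)
}

#' Index values of the deterministic and semi-randomized rules
#'
#' @description
#' \code{index_cb} — current belief: the posterior mean.
#'
#' \code{index_gi} — Gittins index of the policy-facing Beta state, looked
#' up in a precomputed table.
#'
#' \code{index_ucb} — posterior mean plus the optimism bonus
#' \eqn{\beta(t) \lambda} with \eqn{\beta(t) = 2 \log t} and
#' \eqn{\lambda = 1 / (s_0 + f_0 + S + F)}, where \eqn{t} is the 1-based
#' index of the patient about to be allocated (so the first patient gets no
#' bonus and both arms start at the prior mean).
#'
#' \code{index_randucb} — posterior mean plus \eqn{Z / (s_0+f_0+S+F)} with
#' \eqn{Z} drawn uniformly from \code{M_points} equally spaced support
#' points on \eqn{[L, U]}; \code{M_points = 1} with \eqn{L = U = \beta}
#' recovers UCB.
#'
#' \code{index_perturbed} — belief or Gittins index plus \eqn{Z \lambda}
#' with \eqn{Z \sim} Exp(rate \eqn{1/K}) (mean \eqn{K}) and
#' \eqn{\lambda = K/(s_0+f_0+S+F)}; these are the randomized belief (RBI)
#' and randomized Gittins (RGI) rules.
#'
#' @param state an [arm_state()].
#' @param table a \code{"gittins_table"} covering the state.
#' @param t 1-based index of the patient being allocated (UCB).
#' @param M_points,L,U RandUCB support: number of points and interval.
#' @param z optional perturbation value; drawn from the rule's distribution
#'   when \code{NULL}.
#' @param base \code{"belief"} or \code{"gittins"}.
#' @param K number of arms (scales the exponential perturbation).
#' @return a numeric index value.
#' @export
index_cb <- function(state) posterior_mean(state)

#' @rdname index_cb
#' @export
index_gi <- function(state, table) {
  ab <- policy_beta(state)
  gittins_lookup(table, ab["a"], ab["b"])
}

#' @rdname index_cb
#' @export
index_ucb <- function(state, t) {
  if (t < 1) stop("patient index t must be >= 1")
  ab <- policy_beta(state)
  unname(ab["a"] / sum(ab) + 2 * log(t) / sum(ab))
}

#' @rdname index_cb
#' @export
index_randucb <- function(state, M_points = 20L, L = 0, U = 1, z = NULL) {
  stopifnot(M_points >= 1L, L <= U)
  if (is.null(z)) z <- randucb_draw(1L, M_points, L, U)
  ab <- policy_beta(state)
  unname(ab["a"] / sum(ab) + z / sum(ab))
}

# uniform draw from M equally spaced points on [L, U] (the single point L
# when M = 1); uses one runif per draw so scalar and vectorized engines
# consume the RNG stream identically.
randucb_draw <- function(nn, M_points, L, U) {
  idx <- pmin(floor(stats::runif(nn) * M_points), M_points - 1)
  if (M_points == 1L) return(rep(L, nn))
  L + idx * (U - L) / (M_points - 1)
}

#' @rdname index_cb
#' @export
index_perturbed <- function(state, base = c("belief", "gittins"),
                            table = NULL, K = 2L, z = NULL) {
  base <- match.arg(base)
  if (base == "gittins" && is.null(table))
    stop("base = \"gittins\" requires a gittins_table")
  if (is.null(z)) z <- stats::rexp(1L, rate = 1 / K)
  ab <- policy_beta(state)
  b0 <- if (base == "belief") ab["a"] / sum(ab)
        else gittins_lookup(table, ab["a"], ab["b"])
  unname(b0 + z * K / sum(ab))
}

#' Randomized play-the-winner urn
#'
#' \code{rpw_draw} samples an arm with probability proportional to its ball
#' count; \code{rpw_update} applies the classical play-the-winner rule: an
#' observed success adds a ball of the treated arm's type, an observed
#' failure adds a ball of the other arm's type, and a missing outcome leaves
#' the urn unchanged.
#'
#' @param urn integer vector of two non-negative ball counts (arm 0, arm 1).
#' @param arm treated arm, 0 or 1.
#' @param outcome one of \code{"success"}, \code{"failure"},
#'   \code{"missing"}.
#' @return \code{rpw_draw}: an arm id (0 or 1); \code{rpw_update}: the
#'   updated urn.
#' @export
rpw_draw <- function(urn) {
  stopifnot(length(urn) == 2L, all(urn >= 0))
  if (sum(urn) == 0) stop("empty urn")
  as.integer(stats::runif(1L) >= urn[1L] / sum(urn))
}

#' @rdname rpw_draw
#' @export
rpw_update <- function(urn, arm, outcome = c("success", "failure", "missing")) {
  outcome <- match.arg(outcome)
  stopifnot(arm %in% c(0L, 1L))
  if (outcome == "success") urn[arm + 1L] <- urn[arm + 1L] + 1L
  if (outcome == "failure") urn[2L - arm] <- urn[2L - arm] + 1L
  urn
}

#' Select an arm from index values or allocation probabilities
#'
#' In \code{"argmax"} mode the arm with the strictly larger value is chosen
#' and exact ties are broken uniformly at random; in \code{"sample"} mode an
#' arm is drawn with the given probabilities.
#'
#' @param values numeric vector of two finite values; in sample mode they
#'   must sum to one.
#' @param mode \code{"argmax"} or \code{"sample"}.
#' @return an arm id (0 or 1).
#' @export
select_arm <- function(values, mode = c("argmax", "sample")) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) stop("non-finite index/probability values")
  u <- stats::runif(1L)
  if (mode == "argmax") {
    if (values[2L] > values[1L]) return(1L)
    if (values[1L] > values[2L]) return(0L)
    return(as.integer(u < 0.5))
  }
  if (abs(sum(values) - 1) > 1e-8) stop("sample-mode probabilities must sum to 1")
  as.integer(u >= values[1L])
}

#' Names of the implemented allocation rules
#'
#' @return character vector: FR, TTS, RTS, RPW, CB, GI, UCB, RandUCB, RBI,
#'   RGI.
#' @export
bandit_policies <- function() {
  c("FR", "TTS", "RTS", "RPW", "CB", "GI", "UCB", "RandUCB", "RBI", "RGI")
}
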