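#' Proportion of patients allocated to the experimental arm
#'
#' \eqn{p^* = N_{1,n}/n}, the share of the \eqn{n} enrolled patients
#' assigned to arm 1.
#'
#' @param x a \code{"bandit_sims"} object or a single
#'   \code{"replication_record"}.
#' @return numeric vector (one value per replication).
#' @export
allocation_proportion <- function(x) {
  if (inherits(x, "replication_record"))
    return(mean(x$assignments == 1L))
  stopifnot(inherits(x, "bandit_sims"))
  x$reps$pstar
}

#' Observed and oracle success counts
#'
#' ONS counts observed successes only (missing and imputed outcomes are
#' excluded); ENS additionally counts the true successes among missing
#' outcomes — the oracle total that would have been seen with complete data.
#'
#' @param x a \code{"bandit_sims"} object or a \code{"replication_record"}.
#' @return data frame with one row per replication and columns \code{ons},
#'   \code{ens}.
#' @export
success_counts <- function(x) {
  if (inherits(x, "replication_record")) {
    obs <- !x$missing_mask
    return(data.frame(ons = sum(x$outcomes_true & obs),
                      ens = sum(x$outcomes_true)))
  }
  stopifnot(inherits(x, "bandit_sims"))
  data.frame(ons = x$reps$S0 + x$reps$S1, ens = x$reps$TS0 + x$reps$TS1)
}

#' Bias of the arm-level sample means and the covariance identity
#'
#' Under adaptive sampling the terminal sample mean
#' \eqn{\hat p_k = S_k/(S_k + F_k)} is biased, and the bias obeys
#' \deqn{Cov[N_k, \hat p_k] / E[N_k] = p_k - E[\hat p_k],}
#' i.e. minus the bias. This function estimates both sides from the
#' replications, together with their discrepancy. \eqn{\hat p_k} is computed
#' from the observed-only ledger (no prior pseudo-counts, no imputed
#' values); replications in which an arm has no observed outcome are
#' excluded from that arm's summaries and counted in \code{n_excluded}.
#' Without missing data the identity is exact (conditionally on the included
#' replications); with missing outcomes the allocation count \eqn{N_k}
#' includes patients whose outcome was never observed and the identity is
#' only approximate.
#'
#' Monte-Carlo standard errors: the bias SE is the plain standard error of
#' \eqn{\hat p_k}; the identity-gap SE comes from the delta method
#' (influence functions of the three moments involved).
#'
#' @param sims a \code{"bandit_sims"} object with at least 2 replications.
#' @return data frame with one row per arm: \code{arm}, \code{p_true},
#'   \code{bias}, \code{bias_se}, \code{cov_ratio}
#'   (\eqn{Cov[N_k,\hat p_k]/E[N_k]}), \code{eq_gap}
#'   (\code{cov_ratio + bias}; ~0 when the identity holds), \code{eq_gap_se},
#'   \code{n_excluded}, \code{n_used}.
#' @export
bias_and_covariance <- function(sims) {
  stopifnot(inherits(sims, "bandit_sims"), sims$R >= 2L)
  reps <- sims$reps
  cfg <- sims$config
  one_arm <- function(k) {
    S <- reps[[paste0("S", k)]]
    F <- reps[[paste0("F", k)]]
    N <- reps[[paste0("N", k)]]
    p <- if (k == 0L) cfg$p0 else cfg$p1
    keep <- (S + F) > 0L
    if (!any(keep))
      stop("all replications have no observed outcome in arm ", k)
    S <- S[keep]; F <- F[keep]; N <- N[keep]
    phat <- S / (S + F)
    m <- length(phat)
    bias <- mean(phat) - p
    cov_ratio <- if (m >= 2L) stats::cov(N, phat) / mean(N) else NA_real_
    # delta-method SE of gap = cov(N, phat)/mean(N) + mean(phat) - p via the
    # influence functions of the three moments
    gap_se <- if (m >= 2L) {
      dN <- N - mean(N); dp <- phat - mean(phat)
      cv <- stats::cov(N, phat)
      infl <- (dN * dp - cv) / mean(N) - cv * dN / mean(N)^2 + dp
      stats::sd(infl) / sqrt(m)
    } else NA_real_
    data.frame(arm = k, p_true = p,
               bias = bias, bias_se = stats::sd(phat) / sqrt(m),
               cov_ratio = cov_ratio,
               eq_gap = cov_ratio + bias, eq_gap_se = gap_se,
               n_excluded = sum(!keep), n_used = m)
  }
  rbind(one_arm(0L), one_arm(1L))
}

#' Monte-Carlo summary of a set of replications
#'
#' Aggregates the operating characteristics of a simulation cell: the mean
#' allocation proportion \eqn{E[p^*]}, the observed number of successes
#' (ONS) and the oracle expected number of successes (ENS), each with its
#' Monte-Carlo standard error, plus the per-arm bias diagnostics.
#'
#' @param sims a \code{"bandit_sims"} object.
#' @return an object of class \code{"scenario_summary"}: list with
#'   \code{mean_pstar}, \code{se_pstar}, \code{ons}, \code{ons_se},
#'   \code{ens}, \code{ens_se}, \code{bias} (per-arm data frame, \code{NULL}
#'   when R < 2), \code{R} and \code{config}.
#' @export
summarize_replications <- function(sims) {
  stopifnot(inherits(sims, "bandit_sims"))
  sc <- success_counts(sims)
  ps <- sims$reps$pstar
  R <- sims$R
  se <- function(v) if (R >= 2L) stats::sd(v) / sqrt(R) else NA_real_
  structure(list(
    mean_pstar = mean(ps), se_pstar = se(ps),
    ons = mean(sc$ons), ons_se = se(sc$ons),
    ens = mean(sc$ens), ens_se = se(sc$ens),
    bias = if (R >= 2L) bias_and_covariance(sims) else NULL,
    R = R, config = sims$config), class = "scenario_summary")
}

#' @export
summary.bandit_sims <- function(object, ...) summarize_replications(object)

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("%s: E[p*] = %.4f (se %.4f), ONS = %.2f, ENS = %.2f, R = %d\n",
              x$config$algorithm, x$mean_pstar, x$se_pstar,
              x$ons, x$ens, x$R))
  if (!is.null(x$bias)) {
    cat("per-arm bias of the sample mean:\n")
    print(x$bias[, c("arm", "p_true", "bias", "bias_se", "cov_ratio",
                     "eq_gap", "n_excluded")], row.names = FALSE, digits = 4)
  }
  invisible(x)
}
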