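#' Configuration of one simulated trial cell
#'
#' Bundles everything that defines a simulation cell: the two arms' true
#' success probabilities, their missing-at-random probabilities, the trial
#' size, the allocation rule and its tuning parameters, the imputation
#' settings, and the RNG seed.
#'
#' @param algorithm allocation rule, one of [bandit_policies()].
#' @param p0,p1 true success probabilities of the control (arm 0) and
#'   experimental (arm 1) arm.
#' @param pm0,pm1 per-arm probabilities that an outcome is missing
#'   (missing at random within arm); must lie in \eqn{[0, 0.5]}.
#' @param n trial size (number of sequentially enrolled patients).
#' @param imputation \code{"off"} (missing outcomes are ignored: the arm
#'   state simply does not update) or \code{"mean"} (each missing outcome is
#'   replaced, at the time it goes missing, by a Bernoulli draw at the arm's
#'   current observed success rate \eqn{\hat p = S/(S+F)}).
#' @param impute_initial success probability used by mean imputation while
#'   an arm has no observed outcomes (\eqn{S + F = 0}); default 0.5.
#' @param impute_after_first if \code{TRUE}, missing outcomes are only
#'   imputed once the arm has at least one observed outcome (earlier missing
#'   outcomes stay missing).
#' @param impute_source counts used for the imputation estimate
#'   \eqn{\hat p}: \code{"observed"} (\eqn{S/(S+F)} from observed outcomes
#'   only, the default) or \code{"filled"} (imputed outcomes are fed back
#'   into \eqn{\hat p} as if observed).
#' @param seed integer RNG seed; \code{NULL} leaves the RNG state alone.
#' @param s0,f0 prior pseudo-counts of the Beta prior (uniform by default).
#' @param d discount factor for the Gittins-index rules.
#' @param M_points,L,U RandUCB support parameters.
#' @return an object of class \code{"trial_config"}.
#' @export
trial_config <- function(algorithm, p0, p1, pm0 = 0, pm1 = 0, n,
                         imputation = c("off", "mean"),
                         impute_initial = 0.5,
                         impute_after_first = FALSE,
                         impute_source = c("observed", "filled"),
                         seed = NULL, s0 = 1L, f0 = 1L,
                         d = 0.99, M_points = 20L, L = 0, U = 1) {
  algorithm <- match.arg(algorithm, bandit_policies())
  imputation <- match.arg(imputation)
  impute_source <- match.arg(impute_source)
  stopifnot(p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1,
            pm0 >= 0, pm0 <= 0.5, pm1 >= 0, pm1 <= 0.5,
            n >= 1, impute_initial >= 0, impute_initial <= 1,
            s0 >= 1, f0 >= 1, d > 0, d < 1, M_points >= 1, L <= U)
  structure(list(algorithm = algorithm, p0 = p0, p1 = p1,
                 pm0 = pm0, pm1 = pm1, n = as.integer(n),
                 imputation = imputation,
                 impute_initial = impute_initial,
                 impute_after_first = isTRUE(impute_after_first),
                 impute_source = impute_source,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 s0 = as.integer(s0), f0 = as.integer(f0),
                 d = d, M_points = as.integer(M_points), L = L, U = U),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf(
    "trial_config: %s, p = (%.2f, %.2f), pm = (%.2f, %.2f), n = %d, imputation %s\n",
    x$algorithm, x$p0, x$p1, x$pm0, x$pm1, x$n, x$imputation))
  invisible(x)
}

#' Draw one patient outcome with missing-at-random masking
#'
#' The outcome is Bernoulli with the assigned arm's true success
#' probability; independently, it is masked as missing with the arm's
#' missingness probability. The true value is always returned (it feeds the
#' expected-number-of-successes oracle) but a missing outcome never reaches
#' any allocation rule.
#'
#' @param arm assigned arm, 0 or 1.
#' @param config a [trial_config()].
#' @return list with logical elements \code{success} and \code{missing}.
#' @export
generate_outcome <- function(arm, config) {
  stopifnot(arm %in% c(0L, 1L))
  p <- if (arm == 1L) config$p1 else config$p0
  pm <- if (arm == 1L) config$pm1 else config$pm0
  list(success = stats::runif(1L) < p, missing = stats::runif(1L) < pm)
}

#' Mean-impute one missing binary outcome
#'
#' Draws a Bernoulli replacement at the arm's current observed success rate
#' \eqn{\hat p = S/(S+F)}, or at \code{impute_initial} while the arm has no
#' observed outcomes. With \code{impute_after_first = TRUE} and no observed
#' outcomes, no imputation occurs and \code{NA} is returned.
#'
#' @param S,F the arm's observed success and failure counts.
#' @param config a [trial_config()] with \code{imputation = "mean"}.
#' @return logical imputed outcome, or \code{NA} if imputation is skipped.
#' @export
impute_missing <- function(S, F, config) {
  stopifnot(config$imputation == "mean")
  if (S + F == 0L) {
    if (config$impute_after_first) return(NA)
    return(stats::runif(1L) < config$impute_initial)
  }
  stats::runif(1L) < S / (S + F)
}

#' Run one replication of a sequential bandit trial
#'
#' Simulates the trial patient by patient: compute each arm's allocation
#' probability or index value from its current policy-facing state, select
#' the arm, draw the outcome and its missingness, optionally impute, and
#' update the ledgers. Returns the full per-patient record, including the
#' per-step allocation probabilities or index values for trajectory plots.
#'
#' @param config a [trial_config()].
#' @param gittins a \code{"gittins_table"}; required for GI/RGI (computed and
#'   cached automatically when omitted).
#' @return an object of class \code{"replication_record"}: a list with
#'   \code{assignments} (0/1, length n), \code{outcomes_true} (logical
#'   true outcomes, including those that went missing), \code{missing_mask},
#'   \code{imputed_values} (logical, \code{NA} where not imputed),
#'   \code{trajectory} (n x 2 matrix of per-step probabilities/indices),
#'   \code{arms} (terminal per-arm ledgers) and \code{config}.
#' @export
run_trial <- function(config, gittins = NULL) {
  sims <- run_replications(config, R = 1L, gittins = gittins,
                           record_trajectory = TRUE)
  rec <- sims$records[[1L]]
  rec$config <- config
  class(rec) <- "replication_record"
  rec
}

#' @export
print.replication_record <- function(x, ...) {
  n <- length(x$assignments)
  cat(sprintf("replication_record: %s, n = %d, N1 = %d, %d missing (%d imputed)\n",
              x$config$algorithm, n, sum(x$assignments == 1L),
              sum(x$missing_mask), sum(!is.na(x$imputed_values))))
  invisible(x)
}

#' Run many independent replications of a trial cell
#'
#' Replications are simulated in lockstep (vectorized across replications),
#' drawing per patient in a fixed order — allocation, perturbations,
#' outcome, missingness, imputation — so that runs differing only in the
#' imputation setting share the same outcome and missingness sequences
#' (common random numbers). Results are bit-reproducible given
#' \code{config$seed}.
#'
#' @param config a [trial_config()].
#' @param R number of replications.
#' @param gittins optional precomputed \code{"gittins_table"} (GI/RGI).
#' @param record_trajectory keep per-patient records and per-step index /
#'   probability trajectories (memory-heavy; only allowed for R <= 100).
#' @return an object of class \code{"bandit_sims"}: list with
#'   \code{reps} (data frame, one row per replication: terminal ledgers
#'   \code{N0, N1, S0, F0, M0, S_imp0, F_imp0, ...}, true-success tallies
#'   \code{TS0, TS1}, and \code{pstar = N1/n}), \code{config}, \code{R},
#'   and (if recorded) \code{records}.
#' @export
run_replications <- function(config, R, gittins = NULL,
                             record_trajectory = FALSE) {
  stopifnot(inherits(config, "trial_config"), R >= 1)
  R <- as.integer(R)
  if (record_trajectory && R > 100L)
    stop("record_trajectory is limited to R <= 100")
  if (config$algorithm %in% c("GI", "RGI")) {
    need <- config$s0 + config$f0 + config$n + 2L
    if (is.null(gittins)) {
      gittins <- cached_gittins_table(config$d, need)
    } else if (gittins$max_total < need || gittins$d != config$d) {
      stop("supplied gittins table does not cover this trial (need d = ",
           config$d, ", max_total >= ", need, ")")
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sim_engine(config, R, gittins, record_trajectory)
}

#' @export
print.bandit_sims <- function(x, ...) {
  cat(sprintf("bandit_sims: %s, R = %d, mean p* = %.4f\n",
              x$config$algorithm, x$R, mean(x$reps$pstar)))
  invisible(x)
}

# in-session cache of Gittins tables keyed by discount/tolerance; a cached
# table is reused whenever its coverage is at least the requested one
.gittins_cache <- new.env(parent = emptyenv())

#' Compute or reuse a cached Gittins table
#'
#' Tables are expensive; within a session the last table per
#' (d, tol) pair is kept and reused whenever its coverage suffices.
#'
#' @inheritParams compute_gittins_table
#' @return a \code{"gittins_table"}.
#' @export
cached_gittins_table <- function(d, max_total, tol = 1e-5) {
  key <- sprintf("d%.17g_tol%.17g", d, tol)
  tab <- .gittins_cache[[key]]
  if (is.null(tab) || tab$max_total < max_total) {
    tab <- compute_gittins_table(d = d, max_total = max_total, tol = tol)
    .gittins_cache[[key]] <- tab
  }
  tab
}
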