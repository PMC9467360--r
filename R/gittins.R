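#' Gittins indices for a Bernoulli arm with a Beta prior
#'
#' Computes the Gittins index \eqn{G[s, f]} of a Bernoulli bandit arm in
#' posterior state Beta(\eqn{s}, \eqn{f}) under geometric discounting with
#' factor \eqn{d}, for every integer state with \eqn{s, f \ge 1} and
#' \eqn{s + f \le} \code{max_total}. The index of a state is the retirement
#' value \eqn{\lambda} at which continuing to play the arm and retiring on a
#' constant reward \eqn{\lambda} are equally valuable (retirement-value
#' calibration). The calibration problem is solved by backward induction on
#' a state space truncated at a horizon \eqn{T} chosen so that the
#' truncation error \eqn{d^T/(1-d)} is below \code{tol}.
#'
#' A single backward-induction pass at a fixed \eqn{\lambda} yields the
#' continuation value of every table state at once — and, propagated
#' alongside it, its derivative in \eqn{\lambda} — so the per-state root is
#' found by a shared ascending sweep over a \eqn{\lambda} grid that brackets
#' every state simultaneously. The calibration gap is a convex, decreasing,
#' piecewise-linear function of \eqn{\lambda}: its Newton tangents at the
#' bracket ends bound the root from below and its chord bounds it from
#' above, giving a certified enclosure for every state from the sweep alone.
#' States whose enclosure is wider than \code{refine_tol} (a kink close to
#' the root) are re-solved by synchronized bisection, states sharing a
#' bracket sharing passes.
#'
#' @param d discount factor in (0, 1); 0.99 is the conventional choice in
#'   the clinical-trials bandit literature.
#' @param max_total largest \eqn{s + f} covered by the table. For a trial of
#'   size \eqn{n} with a Beta(1, 1) prior, \code{n + 4} covers every
#'   reachable state with margin.
#' @param tol truncation tolerance of the dynamic program; the horizon is
#'   the smallest \eqn{T} with \eqn{d^T/(1-d) \le} \code{tol}.
#' @param grid_size number of intervals in the bracketing sweep.
#' @param refine_tol interpolation tolerance: states whose certified root
#'   enclosure is wider than this are refined by bisection.
#' @param max_refine_passes safety cap on the number of refinement passes.
#' @param verbose print progress.
#'
#' @return An object of class \code{"gittins_table"}: a list with elements
#'   \code{values} (matrix, \code{values[s, f]} is the index of state
#'   \eqn{(s, f)}), \code{d}, \code{max_total}, \code{tol}, and
#'   \code{precision} — half the widest certified enclosure left in the
#'   table, i.e. a bound on the interpolation error of any entry (the
#'   truncation error \code{tol} comes on top). Shallow states are far more
#'   accurate than the bound (the uniform-prior state is good to ~1e-6);
#'   the bound is attained only at deep states near the \eqn{s = 1} or
#'   \eqn{f = 1} edges, where neighbouring index values differ by far more
#'   than the bound.
#'
#' @examples
#' tab <- compute_gittins_table(d = 0.6, max_total = 12, tol = 1e-6)
#' gittins_lookup(tab, 1, 1)
#' @export
compute_gittins_table <- function(d, max_total, tol = 1e-5,
                                  grid_size = 512L, refine_tol = 5e-4,
                                  max_refine_passes = 600L,
                                  verbose = FALSE) {
  stopifnot(d > 0, d < 1, max_total >= 2, tol > 0)
  horizon <- gittins_horizon(d, tol)
  sz <- max_total - 1L
  smat <- matrix(rep(seq_len(sz), sz), sz, sz)
  fmat <- t(smat)
  mu <- smat / (smat + fmat)
  mu[smat + fmat > max_total] <- NA_real_

  # ascending sweep: keep the gap and its derivative at the two grid points
  # straddling each state's root. analytic endpoints: at lambda = 0 the arm
  # is never retired (gap = mu/(1-d), slope = -1/(1-d)); at lambda = 1
  # retirement is immediate after one pull (gap = mu - 1, slope = -1).
  lo <- matrix(0, sz, sz);  glo <- mu / (1 - d); plo <- glo * 0 - 1 / (1 - d)
  hi <- matrix(1, sz, sz);  ghi <- mu - 1;       phi <- ghi * 0 - 1
  grid <- seq_len(grid_size - 1L) / grid_size
  for (i in seq_along(grid)) {
    lam <- grid[i]
    pass <- gittins_dp_pass(lam, d, max_total, horizon, deriv = TRUE)
    g <- pass$cont - lam / (1 - d)
    gp <- pass$dcont - 1 / (1 - d)
    below <- !is.na(g) & g >= 0
    first_above <- !is.na(g) & g < 0 & hi == 1
    lo[below] <- lam; glo[below] <- g[below]; plo[below] <- gp[below]
    hi[first_above] <- lam; ghi[first_above] <- g[first_above]
    phi[first_above] <- gp[first_above]
    if (verbose && i %% 128L == 0L)
      message(sprintf("sweep %d/%d", i, grid_size - 1L))
  }

  enc <- root_enclosure(lo, glo, plo, hi, ghi, phi)
  G <- (enc$lower + enc$upper) / 2
  width <- enc$upper - enc$lower

  flagged <- which(!is.na(G) & width > refine_tol)
  if (length(flagged)) {
    if (verbose)
      message(sprintf("refining %d of %d states", length(flagged), sum(!is.na(G))))
    rf <- refine_states(d, max_total, horizon, flagged,
                        lo[flagged], glo[flagged], plo[flagged],
                        hi[flagged], ghi[flagged], phi[flagged],
                        width_target = refine_tol,
                        max_pass = max_refine_passes,
                        verbose = verbose)
    G[flagged] <- rf$val
    width[flagged] <- rf$w
  }

  structure(list(values = G, d = d, max_total = as.integer(max_total),
                 tol = tol,
                 precision = max(width, na.rm = TRUE) / 2),
            class = "gittins_table")
}

#' Look up Gittins indices in a precomputed table
#'
#' @param table a \code{"gittins_table"} from [compute_gittins_table()].
#' @param s,f integer vectors of Beta state parameters (prior pseudo-counts
#'   included), recycled to a common length.
#' @return numeric vector of index values.
#' @export
gittins_lookup <- function(table, s, f) {
  stopifnot(inherits(table, "gittins_table"))
  n <- max(length(s), length(f))
  s <- rep_len(as.integer(s), n); f <- rep_len(as.integer(f), n)
  bad <- s < 1L | f < 1L | s + f > table$max_total
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "state (s = %d, f = %d) outside table coverage (1 <= s, f; s + f <= %d)",
      s[i], f[i], table$max_total))
  }
  table$values[cbind(s, f)]
}

#' @export
print.gittins_table <- function(x, ...) {
  cat(sprintf(
    "Gittins index table: d = %g, states s + f <= %d, truncation tol = %g\n",
    x$d, x$max_total, x$tol))
  if (!is.null(x$precision))
    cat(sprintf("certified interpolation precision: %.2g\n", x$precision))
  cat(sprintf("G[1, 1] = %.4f\n", x$values[1L, 1L]))
  invisible(x)
}

#' Write / read a Gittins table as a plain-text file
#'
#' The file is tab-separated with a commented header recording the discount
#' factor, coverage and truncation tolerance, so a table computed once can
#' be reused across simulation runs.
#'
#' @param table a \code{"gittins_table"}.
#' @param path file path.
#' @return \code{write_gittins_table} returns \code{path} invisibly;
#'   \code{read_gittins_table} returns the reconstructed table.
#' @export
write_gittins_table <- function(table, path) {
  stopifnot(inherits(table, "gittins_table"))
  idx <- which(!is.na(table$values), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gittins_table d=%.17g max_total=%d tol=%.17g precision=%.17g",
                     table$d, table$max_total, table$tol,
                     if (is.null(table$precision)) NA_real_ else table$precision),
             con)
  writeLines("s\tf\tindex", con)
  writeLines(sprintf("%d\t%d\t%.17g", idx[, 1L], idx[, 2L],
                     table$values[idx]), con)
  invisible(path)
}

#' @rdname write_gittins_table
#' @export
read_gittins_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "^# gittins_table d=([^ ]+) max_total=([0-9]+) tol=([^ ]+)( precision=([^ ]+))?$",
    hdr))[[1L]]
  if (length(m) < 4L) stop("not a gittins_table file: ", path)
  d <- as.numeric(m[2L]); max_total <- as.integer(m[3L]); tol <- as.numeric(m[4L])
  prec <- if (length(m) >= 6L && !is.na(m[6L]) && nzchar(m[6L]))
    as.numeric(m[6L]) else NULL
  dat <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  sz <- max_total - 1L
  values <- matrix(NA_real_, sz, sz)
  values[cbind(dat$s, dat$f)] <- dat$index
  structure(list(values = values, d = d, max_total = max_total, tol = tol,
                 precision = prec),
            class = "gittins_table")
}

# ---- internals ---------------------------------------------------------

# horizon such that d^T / (1 - d) <= tol
gittins_horizon <- function(d, tol) {
  as.integer(ceiling(log(tol * (1 - d)) / log(d)))
}

# One backward-induction pass of the calibration dynamic program at
# retirement value `lambda`. Returns the continuation value of every state
# (s, f) with s + f <= max_total (matrix indexed [s, f]) and, if deriv, its
# derivative with respect to lambda (retired states contribute 1/(1 - d),
# continued states propagate the discounted expectation). Diagonals
# N = s + f run from max_total + horizon down to 2; V holds the previous
# diagonal, indexed by s.
gittins_dp_pass <- function(lambda, d, max_total, horizon, deriv = FALSE) {
  L <- max_total + horizon
  ret <- lambda / (1 - d)
  s <- seq_len(L - 1L)
  V <- pmax(lambda, s / L) / (1 - d)
  C <- matrix(NA_real_, max_total - 1L, max_total - 1L)
  if (deriv) {
    Vp <- (lambda >= s / L) / (1 - d)
    Cp <- matrix(NA_real_, max_total - 1L, max_total - 1L)
  }
  for (N in (L - 1L):2L) {
    s <- seq_len(N - 1L)
    mu <- s / N
    cv <- mu * (1 + d * V[s + 1L]) + (1 - mu) * (d * V[s])
    stopped <- cv < ret
    if (deriv) {
      cvp <- d * (mu * Vp[s + 1L] + (1 - mu) * Vp[s])
      if (N <= max_total) Cp[cbind(s, N - s)] <- cvp
      Vp <- cvp
      Vp[stopped] <- 1 / (1 - d)
    }
    if (N <= max_total) C[cbind(s, N - s)] <- cv
    V <- cv
    V[stopped] <- ret
  }
  if (deriv) list(cont = C, dcont = Cp) else list(cont = C)
}

# Certified enclosure of the root of the convex decreasing gap function from
# its values and slopes at the bracket ends: Newton tangents at either end
# under-shoot (lower bounds), the chord over-shoots (upper bound).
root_enclosure <- function(lo, glo, plo, hi, ghi, phi) {
  newton_lo <- lo - glo / plo
  newton_hi <- hi - ghi / phi
  lower <- pmax(newton_lo, newton_hi, lo)
  upper <- pmin(lo + (hi - lo) * glo / (glo - ghi), hi)
  # guard against floating-point inversions of the bounds
  bad <- !is.na(lower) & lower > upper
  if (any(bad)) {
    mid <- (lower[bad] + upper[bad]) / 2
    lower[bad] <- mid
    upper[bad] <- mid
  }
  list(lower = lower, upper = upper)
}

# Synchronized bisection with Newton-sandwich termination: states sharing a
# bracket share DP passes, the widest enclosures are attacked first, and a
# state finishes once its certified enclosure is narrow enough (the sandwich
# collapses as soon as its bracket is free of kinks, so few rounds are
# needed).
refine_states <- function(d, max_total, horizon, idx, lo, glo, plo,
                          hi, ghi, phi, width_target, max_pass,
                          verbose = FALSE) {
  npass <- 0L
  est <- function() {
    enc <- root_enclosure(lo, glo, plo, hi, ghi, phi)
    list(val = (enc$lower + enc$upper) / 2, w = enc$upper - enc$lower)
  }
  repeat {
    e <- est()
    active <- e$w > width_target
    if (!any(active) || npass >= max_pass) break
    mid <- (lo + hi) / 2
    mids <- unique(mid[active])
    worst <- vapply(mids, function(l) max(e$w[active & mid == l]), numeric(1L))
    for (lam in mids[order(-worst)]) {
      pass <- gittins_dp_pass(lam, d, max_total, horizon, deriv = TRUE)
      npass <- npass + 1L
      sel <- which(active & mid == lam)
      g <- pass$cont[idx[sel]] - lam / (1 - d)
      gp <- pass$dcont[idx[sel]] - 1 / (1 - d)
      up <- g >= 0
      lo[sel[up]] <- lam; glo[sel[up]] <- g[up]; plo[sel[up]] <- gp[up]
      hi[sel[!up]] <- lam; ghi[sel[!up]] <- g[!up]; phi[sel[!up]] <- gp[!up]
      if (npass >= max_pass) break
    }
    if (verbose) message(sprintf("refine passes so far: %d", npass))
  }
  est()
}
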