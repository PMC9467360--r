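# Independent numerical oracles used to validate the package's own
# closed-form and dynamic-programming implementations.

# P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2) by 1-D quadrature of
# f_X(x) * F_Y(x); independent of the finite-sum identity in the package.
oracle_prob_greater <- function(a1, b1, a2, b2) {
  stats::integrate(function(x) stats::dbeta(x, a1, b1) * stats::pbeta(x, a2, b2),
                   0, 1, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# Brute-force Gittins index oracle: recursive finite-horizon value function
# with memoization plus uniroot calibration on the retirement value.
# Deliberately written as a plain recursion (no diagonal sweep) so it shares
# no code path with the package implementation.
oracle_gittins <- function(s, f, d, horizon, tol = 1e-9) {
  memo <- new.env(parent = emptyenv())
  value <- function(si, fi, h, lam) {
    key <- paste(si, fi, h, sep = "_")
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    mu <- si / (si + fi)
    v <- if (h == 0L) {
      max(lam, mu) / (1 - d)
    } else {
      cont <- mu * (1 + d * value(si + 1L, fi, h - 1L, lam)) +
        (1 - mu) * d * value(si, fi + 1L, h - 1L, lam)
      max(lam / (1 - d), cont)
    }
    memo[[key]] <- v
    v
  }
  gap <- function(lam) {
    rm(list = ls(memo), envir = memo)
    mu <- s / (s + f)
    cont <- mu * (1 + d * value(s + 1L, f, horizon - 1L, lam)) +
      (1 - mu) * d * value(s, f + 1L, horizon - 1L, lam)
    cont - lam / (1 - d)
  }
  stats::uniroot(gap, c(s / (s + f) - 1e-12, 1), tol = tol)$root
}
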