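# Shared fixtures: reference configurations and a naive per-outcome brute
# force used as the independent oracle for the exact engine.

# Boundary configurations (components at +/- log 1.4 or the off-diagonal
# pairs) rebuilt exactly with the solvers; `rej100` is the reference exact
# rejection probability at n1 = n2 = 100.
boundary_config <- function(pi1, sf, sm) {
  pi2 <- solve_pi2_for_delta_f(pi1, sf * log(1.4))
  pX <- pi1 + pi2 / 2
  pY <- solve_pY_for_delta_m(pX, sm * log(1.4))
  list(pi1 = pi1, pi2 = pi2, pY = pY)
}

# Per-outcome brute force: loops the whole outcome space and calls the
# user-facing test on each nondegenerate outcome. Independent of the
# vectorized enumeration path.
brute_force_rejection_prob <- function(pi1, pi2, pY, n1, n2,
                                       alpha = 0.05, epsilon = hwx_margin()) {
  pi3 <- 1 - pi1 - pi2
  tot <- 0
  for (x1 in 0:n1) for (x2 in 0:(n1 - x1)) for (y in 0:n2) {
    x3 <- n1 - x1 - x2
    rej <- FALSE
    if (x1 > 0 && x2 > 0 && x3 > 0 && y > 0 && y < n2) {
      tst <- hwx_test(hwx_counts(x1, x2, x3, n2, y),
                      alpha = alpha, epsilon = epsilon)
      rej <- tst$reject_null
    }
    if (rej)
      tot <- tot + stats::dmultinom(c(x1, x2, x3),
                                    prob = c(pi1, pi2, pi3)) *
        stats::dbinom(y, n2, pY)
  }
  tot
}

# GENEVA worked-example counts (printed reference table)
geneva_counts <- function() {
  list(
    rs6646338  = hwx_counts(230, 314, 107, n2 = 604, y = 399, "rs6646338"),
    rs12010339 = hwx_counts(651, 0, 0,     n2 = 605, y = 603, "rs12010339"),
    rs5935567  = hwx_counts(231, 337, 83,  n2 = 605, y = 372, "rs5935567"),
    rs5968922  = hwx_counts(275, 296, 80,  n2 = 604, y = 392, "rs5968922"))
}

# Absolute-tolerance comparison against a printed reference value
# (testthat's own `tolerance` is relative, which is meaningless for
# reproducing small tabulated probabilities to a fixed decimal count)
expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Diagonal non-null alternative: both signed components at frac * log(1.4)
diag_alt <- function(pi1, lam, frac = 0.5) {
  pi2 <- solve_pi2_for_delta_f(pi1, frac * log(1.4))
  pY <- solve_pY_for_delta_m(pi1 + pi2 / 2, frac * log(1.4))
  pop_config(pi1, pi2, pY = pY, lam = lam)
}

random_config <- function() {
  pi1 <- stats::runif(1, 0.05, 0.6)
  pi2 <- stats::runif(1, 0.05, 0.9 - pi1)
  list(pi1 = pi1, pi2 = pi2, pi3 = 1 - pi1 - pi2,
       pY = stats::runif(1, 0.1, 0.9))
}
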