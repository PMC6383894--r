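# Exact finite-sample rejection probability of the equivalence test by
# full enumeration of the trinomial (females) x binomial (males) outcome
# space. Outcomes with a zero cell among {x1, x2, x3, y, n2 - y} leave the
# test statistic undefined and are counted as non-rejections.

# Female outcome grid with all three genotype counts >= 1.
.female_grid <- function(n1) {
  if (n1 < 3) return(list(x1 = integer(0), x2 = integer(0)))
  x1max <- n1 - 2L
  reps <- n1 - 1L - seq_len(x1max)
  list(x1 = rep.int(seq_len(x1max), reps), x2 = sequence(reps))
}

#' Exact rejection probability of the HWE equivalence test
#'
#' Sums the trinomial-by-binomial probability mass of all outcomes
#' `(x1, x2, x3, y)` for which the upper confidence bound falls below the
#' equivalence margin. Degenerate outcomes (any zero cell) never reject;
#' a documented alternative applies the sparse-count correction to them
#' inside the sum instead.
#'
#' Probability masses are computed via log-gamma, so sample sizes in the
#' thousands are safe. With `prune > 0`, female cells and male counts of
#' negligible mass are skipped; the total skipped mass is guaranteed below
#' `prune` and reported in the `mass_pruned` attribute, bounding the
#' absolute error of the returned probability.
#'
#' @param pi1,pi2,pi3 true female genotype frequencies (pi3 defaults to
#'   the simplex complement)
#' @param pY true male A-allele frequency
#' @param n1,n2 numbers of females and males
#' @param alpha one-sided nominal level
#' @param epsilon equivalence margin
#' @param prune total probability mass allowed to be skipped (0 = full
#'   enumeration)
#' @param degenerate policy for zero-cell outcomes: `"nonreject"`
#'   (default) or `"correct"` (apply [sparse_correct()] inside the sum)
#' @param chunk number of female cells per vectorized block
#' @return the rejection probability, with attributes `mass_enumerated`
#'   (nondegenerate mass summed), `mass_pruned` (exact skipped mass) and
#'   `outcomes` (number of enumerated nondegenerate outcomes)
#' @export
#' @examples
#' exact_rejection_prob(0.25, 0.5, pY = 0.5, n1 = 100, n2 = 100)  # 0.10239
exact_rejection_prob <- function(pi1, pi2, pi3 = NULL, pY, n1, n2,
                                 alpha = 0.05, epsilon = hwx_margin(),
                                 prune = 0,
                                 degenerate = c("nonreject", "correct"),
                                 chunk = 2000L) {
  degenerate <- match.arg(degenerate)
  if (is.null(pi3)) pi3 <- 1 - pi1 - pi2
  .check_freqs(pi1, pi2, pi3)
  .check_prob(pY, "pY")
  if (n1 < 1 || n2 < 1) .domain_error("n1 and n2 must be >= 1")
  z <- stats::qnorm(1 - alpha)
  N <- n1 + n2
  lam <- n1 / N

  g <- .female_grid(n1)
  x1 <- g$x1; x2 <- g$x2; x3 <- n1 - x1 - x2
  mF <- exp(lgamma(n1 + 1) - lgamma(x1 + 1) - lgamma(x2 + 1) -
              lgamma(x3 + 1) +
              x1 * log(pi1) + x2 * log(pi2) + x3 * log(pi3))
  yv <- seq_len(max(n2 - 1L, 0L))
  mY <- stats::dbinom(yv, n2, pY)

  pruned <- 0
  if (prune > 0 && length(mF)) {
    thF <- prune / 2 / length(mF)
    dropF <- mF < thF
    pruned <- pruned + sum(mF[dropF])
    x1 <- x1[!dropF]; x2 <- x2[!dropF]; x3 <- x3[!dropF]; mF <- mF[!dropF]
    thY <- prune / 2 / max(length(mY), 1L)
    dropY <- mY < thY
    pruned <- pruned + sum(mY[dropY])
    yv <- yv[!dropY]; mY <- mY[!dropY]
  }

  prob <- 0
  enumerated <- 0
  n_outcomes <- 0
  if (length(mF) && length(mY)) {
    # per-cell female quantities
    p1 <- x1 / n1; p2 <- x2 / n1; p3 <- x3 / n1
    df <- log(p2) - (log(p1) + log(p3)) / 2 - log(2)
    sf2 <- (1 / lam) * (0.25 * (1 - p2) / (p1 * p3) + 1 / p2)
    pX <- p1 + p2 / 2
    lgtX <- log(pX / (1 - pX))
    Am <- (p1 + p2 / 4 - pX^2) / (lam * pX^2 * (1 - pX)^2)
    # per-count male quantities
    pYe <- yv / n2
    lgtY <- log(pYe / (1 - pYe))
    B <- 1 / ((1 - lam) * pYe * (1 - pYe))
    sqN <- sqrt(N)

    n_outcomes <- length(mF) * length(mY)
    idx <- seq_along(mF)
    for (blk in unname(split(idx, ceiling(idx / chunk)))) {
      dfb <- df[blk]
      dm <- outer(lgtX[blk], lgtY, "-")
      d2 <- dfb^2 + dm^2
      sm2 <- outer(Am[blk], B, "+")
      t2 <- (dfb^2 * sf2[blk] + dm^2 * sm2) / d2
      zero <- which(d2 == 0)
      if (length(zero)) {
        ri <- row(d2)[zero]
        t2[zero] <- (sf2[blk][ri] + sm2[zero]) / 2
      }
      rej <- (sqrt(d2) + z * sqrt(t2) / sqN) < epsilon
      prob <- prob + sum(mF[blk] * (rej %*% mY))
    }
    enumerated <- sum(mF) * sum(mY)
  }

  if (degenerate == "correct")
    prob <- prob +
      .degenerate_rejection_mass(pi1, pi2, pi3, pY, n1, n2, z, epsilon)

  structure(prob, mass_enumerated = enumerated, mass_pruned = pruned,
            outcomes = n_outcomes)
}

# Rejection mass contributed by zero-cell outcomes when they are repaired
# with the sparse-count correction instead of being counted as
# non-rejections. Zero-cell outcomes live on the boundary of the outcome
# simplex, so only O(n1 * n2) of them exist; enumerate them directly.
.degenerate_rejection_mass <- function(pi1, pi2, pi3, pY, n1, n2, z, epsilon) {
  grid <- expand.grid(x1 = 0:n1, x2 = 0:n1)
  grid <- grid[grid$x1 + grid$x2 <= n1, , drop = FALSE]
  grid$x3 <- n1 - grid$x1 - grid$x2
  degF <- grid$x1 == 0 | grid$x2 == 0 | grid$x3 == 0
  mF <- exp(lgamma(n1 + 1) - lgamma(grid$x1 + 1) - lgamma(grid$x2 + 1) -
              lgamma(grid$x3 + 1) + grid$x1 * log(pi1) +
              grid$x2 * log(pi2) + grid$x3 * log(pi3))
  yv <- 0:n2
  degY <- yv == 0L | yv == n2
  mY <- stats::dbinom(yv, n2, pY)
  total <- 0
  for (i in seq_len(nrow(grid))) {
    for (j in seq_along(yv)) {
      if (!(degF[i] || degY[j])) next
      cts <- tryCatch(
        sparse_correct(hwx_counts(grid$x1[i], grid$x2[i], grid$x3[i],
                                  n2, yv[j])),
        hwx_degenerate_error = function(e) NULL)
      if (is.null(cts)) next
      ub <- .hwx_bound_vec(cts$x1, cts$x2, cts$x3, cts$y, n1, n2, z)
      if (ub < epsilon) total <- total + mF[i] * mY[j]
    }
  }
  total
}

#' Total enumerated outcome mass (sanity channel for the exact engine)
#'
#' Sums the probability mass over the full outcome space, including
#' degenerate outcomes; equals 1 up to floating point when nothing is
#' pruned.
#'
#' @inheritParams exact_rejection_prob
#' @return total mass, with attribute `mass_pruned`
#' @export
outcome_mass_total <- function(pi1, pi2, pi3 = NULL, pY, n1, n2, prune = 0) {
  if (is.null(pi3)) pi3 <- 1 - pi1 - pi2
  .check_freqs(pi1, pi2, pi3)
  .check_prob(pY, "pY")
  grid <- expand.grid(x1 = 0:n1, x2 = 0:n1)
  grid <- grid[grid$x1 + grid$x2 <= n1, , drop = FALSE]
  x3 <- n1 - grid$x1 - grid$x2
  mF <- exp(lgamma(n1 + 1) - lgamma(grid$x1 + 1) - lgamma(grid$x2 + 1) -
              lgamma(x3 + 1) + grid$x1 * log(pi1) + grid$x2 * log(pi2) +
              x3 * log(pi3))
  mY <- stats::dbinom(0:n2, n2, pY)
  pruned <- 0
  if (prune > 0) {
    thF <- prune / 2 / length(mF)
    pruned <- pruned + sum(mF[mF < thF])
    mF <- mF[mF >= thF]
    thY <- prune / 2 / length(mY)
    pruned <- pruned + sum(mY[mY < thY])
    mY <- mY[mY >= thY]
  }
  structure(sum(mF) * sum(mY), mass_pruned = pruned)
}
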