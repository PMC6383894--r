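# The "inverted chi-squared" lack-of-fit comparator and a Monte Carlo
# harness contrasting it with the equivalence test. Declaring HWE because
# a lack-of-fit p-value exceeds alpha controls no error rate; the harness
# makes that visible against the exact engine.

#' Draw synthetic per-SNP counts from a population configuration
#'
#' Female genotype counts are multinomial(n1; pi), the male A-allele count
#' binomial(n2; pY) -- the sampling model under which all operating
#' characteristics of the test are computed.
#'
#' @param config an [pop_config()] truth
#' @param n1,n2 numbers of females and males
#' @param seed optional integer seed for reproducibility
#' @return an [hwx_counts()] object
#' @export
sample_counts <- function(config, n1, n2, seed = NULL) {
  stopifnot(inherits(config, "hwx_config"))
  if (n1 < 1 || n2 < 1) .domain_error("n1 and n2 must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rmultinom(1, n1, c(config$pi1, config$pi2, config$pi3))
  y <- stats::rbinom(1, n2, config$pY)
  hwx_counts(x[1], x[2], x[3], n2, y)
}

#' Combined chi-squared lack-of-fit statistic for an X-linked SNP
#'
#' Pearson statistic for HWE among females (expected counts
#' `n1 * (pX^2, 2 pX qX, qX^2)` from the female allele frequency, 1 df)
#' plus the 2x2 Pearson statistic comparing female allele counts
#' `(2 x1 + x2, x2 + 2 x3)` with male counts `(y, n2 - y)` (1 df),
#' referred to a chi-squared distribution with 2 df. On the X chromosome
#' HWE requires both within-female equilibrium and equal allele
#' frequencies across the sexes, hence the combination.
#'
#' @param counts an [hwx_counts()] object
#' @return the upper-tail p-value
#' @export
#' @examples
#' combined_chisq_pvalue(hwx_counts(25, 50, 25, n2 = 100, y = 50))  # 1
combined_chisq_pvalue <- function(counts) {
  stopifnot(inherits(counts, "hwx_counts"))
  n1 <- counts$n1; n2 <- counts$n2
  a <- 2 * counts$x1 + counts$x2      # female A alleles
  b <- counts$x2 + 2 * counts$x3      # female B alleles
  pXf <- a / (2 * n1)
  if (pXf == 0 || pXf == 1)
    .degenerate_error("degenerate counts: a female allele is unobserved")
  e <- n1 * c(pXf^2, 2 * pXf * (1 - pXf), (1 - pXf)^2)
  o <- c(counts$x1, counts$x2, counts$x3)
  stat_f <- sum((o - e)^2 / e)
  # 2x2 allele table females vs males
  cc <- counts$y; d <- n2 - counts$y
  tot <- 2 * n1 + n2
  stat_m <- (a * d - b * cc)^2 * tot /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  if (!is.finite(stat_m))
    .degenerate_error("degenerate counts: zero marginal in the allele table")
  stats::pchisq(stat_f + stat_m, df = 2, lower.tail = FALSE)
}

#' Decision rule of the inverted lack-of-fit test
#'
#' Declares HWE when the lack-of-fit p-value exceeds `alpha` (strict
#' inequality). This practice controls no type-I error rate; it is
#' provided purely as a comparator.
#'
#' @param p p-value of a lack-of-fit test
#' @param alpha significance level
#' @return `TRUE` iff `p > alpha`
#' @export
inverted_decision <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .domain_error("p must lie in [0, 1]")
  p > alpha
}

# Vectorized sparse correction over replicate matrices (females) and
# vectors (males); mirrors sparse_correct() per column.
.sparse_correct_mat <- function(X, n1) {
  nz <- colSums(X == 0L)
  fix <- which(nz > 0)
  for (j in fix) {
    x <- X[, j]
    k <- sum(x == 0L)
    x[x == 0L] <- 1L
    im <- which.max(x)
    x[im] <- x[im] - k
    X[, j] <- x
  }
  X
}

#' Monte Carlo comparison of the equivalence test and the inverted test
#'
#' Draws `reps` replicate count tables under `config`, applies both the
#' equivalence test (degenerate replicates never reject) and the inverted
#' combined chi-squared rule (degenerate replicates sparse-corrected), and
#' reports the rejection/declaration rates and their concordance.
#'
#' @param config an [pop_config()] truth
#' @param n1,n2 per-sex sample sizes
#' @param reps number of Monte Carlo replicates
#' @param alpha nominal level used by both procedures
#' @param epsilon equivalence margin
#' @param seed integer seed (bit-reproducible runs)
#' @return an object of class `hwx_mc`: `reps`, `gof_rate`,
#'   `inverted_rate`, `concordance`, `seed`
#' @export
#' @examples
#' monte_carlo_compare(pop_config(0.09, 0.42, pY = 0.3), 100, 100,
#'                     reps = 1000, seed = 1)
monte_carlo_compare <- function(config, n1, n2, reps = 1e5, alpha = 0.05,
                                epsilon = hwx_margin(), seed = 1L) {
  stopifnot(inherits(config, "hwx_config"))
  if (reps < 1) .domain_error("reps must be >= 1")
  set.seed(seed)
  X <- stats::rmultinom(reps, n1, c(config$pi1, config$pi2, config$pi3))
  y <- stats::rbinom(reps, n2, config$pY)
  z <- stats::qnorm(1 - alpha)

  # equivalence test: zero cells never reject
  ok <- X[1, ] > 0 & X[2, ] > 0 & X[3, ] > 0 & y > 0 & y < n2
  gof <- logical(reps)
  if (any(ok))
    gof[ok] <- .hwx_bound_vec(X[1, ok], X[2, ok], X[3, ok], y[ok],
                              n1, n2, z) < epsilon

  # inverted chi-squared comparator on sparse-corrected tables
  Xc <- .sparse_correct_mat(X, n1)
  yc <- pmin(pmax(y, 1L), n2 - 1L)
  a <- 2 * Xc[1, ] + Xc[2, ]
  b <- Xc[2, ] + 2 * Xc[3, ]
  pXf <- a / (2 * n1)
  e1 <- n1 * pXf^2; e2 <- n1 * 2 * pXf * (1 - pXf); e3 <- n1 * (1 - pXf)^2
  stat_f <- (Xc[1, ] - e1)^2 / e1 + (Xc[2, ] - e2)^2 / e2 +
    (Xc[3, ] - e3)^2 / e3
  d <- n2 - yc
  tot <- 2 * n1 + n2
  stat_m <- (a * d - b * yc)^2 * tot /
    ((a + b) * (yc + d) * (a + yc) * (b + d))
  pvals <- stats::pchisq(stat_f + stat_m, df = 2, lower.tail = FALSE)
  inv <- pvals > alpha

  structure(
    list(reps = as.integer(reps),
         gof_rate = mean(gof),
         inverted_rate = mean(inv),
         concordance = mean(gof == inv),
         seed = as.integer(seed),
         n1 = as.integer(n1), n2 = as.integer(n2),
         alpha = alpha, epsilon = epsilon),
    class = "hwx_mc")
}

#' @export
print.hwx_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo comparison (%d replicates, seed %d)\n",
              x$reps, x$seed))
  cat(sprintf("  equivalence test rejection rate: %.5f\n", x$gof_rate))
  cat(sprintf("  inverted chi-squared declare-HWE rate: %.5f\n",
              x$inverted_rate))
  cat(sprintf("  concordant decisions: %.5f\n", x$concordance))
  invisible(x)
}
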