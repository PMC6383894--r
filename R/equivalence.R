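# Per-SNP decision procedure: an upper confidence bound for the combined
# disequilibrium distance is compared with the equivalence margin.
# Rejecting the null hypothesis of relevant disequilibrium (bound < margin)
# establishes approximate compatibility with the Hardy-Weinberg model.

# Vectorized test kernel shared by the exact engine and the Monte Carlo
# harness. All inputs nondegenerate; returns the upper confidence bound.
.hwx_bound_vec <- function(x1, x2, x3, y, n1, n2, z) {
  N <- n1 + n2
  lam <- n1 / N
  p1 <- x1 / n1
  p2 <- x2 / n1
  p3 <- x3 / n1
  pYh <- y / n2
  df <- log(p2) - (log(p1) + log(p3)) / 2 - log(2)
  pX <- p1 + p2 / 2
  dm <- log(pX / (1 - pX)) - log(pYh / (1 - pYh))
  d2 <- df^2 + dm^2
  sf2 <- (1 / lam) * (0.25 * (1 - p2) / (p1 * p3) + 1 / p2)
  sm2 <- 1 / ((1 - lam) * pYh * (1 - pYh)) +
    (p1 + p2 / 4 - pX^2) / (lam * pX^2 * (1 - pX)^2)
  t2 <- ifelse(d2 == 0, (sf2 + sm2) / 2, (df^2 * sf2 + dm^2 * sm2) / d2)
  sqrt(d2) + z * sqrt(t2) / sqrt(N)
}

#' Repair sparse count tables before testing
#'
#' Zero cells make the plug-in estimator undefined. Following common
#' practice for sparse contingency tables, every zero cell is replaced by 1
#' and the total added is taken from the largest cell of the same sex
#' stratum, so that n1 and n2 are preserved. A table of female counts
#' (651, 0, 0) becomes (649, 1, 1); a male count y = 0 becomes y = 1.
#' Zero-free inputs are returned unchanged.
#'
#' @param counts an [hwx_counts()] object
#' @return an [hwx_counts()] object with no zero cells, with attribute
#'   `corrected` set to `TRUE` if any cell was changed
#' @export
#' @examples
#' sparse_correct(hwx_counts(651, 0, 0, n2 = 605, y = 603))
sparse_correct <- function(counts) {
  stopifnot(inherits(counts, "hwx_counts"))
  x <- c(counts$x1, counts$x2, counts$x3)
  corrected <- FALSE
  if (any(x == 0L)) {
    nz <- sum(x == 0L)
    if (counts$n1 < nz + nz + 1L)
      .degenerate_error("unrecoverably sparse female counts: too few females to fill zero cells")
    x[x == 0L] <- 1L
    imax <- which.max(x)
    x[imax] <- x[imax] - nz
    if (any(x <= 0L))
      .degenerate_error("unrecoverably sparse female counts: largest cell cannot compensate")
    corrected <- TRUE
  }
  y <- counts$y
  if (y == 0L || y == counts$n2) {
    if (counts$n2 < 2L)
      .degenerate_error("unrecoverably sparse male counts: n2 < 2")
    y <- if (y == 0L) 1L else counts$n2 - 1L
    corrected <- TRUE
  }
  out <- hwx_counts(x[1], x[2], x[3], counts$n2, y, counts$snp_id)
  attr(out, "corrected") <- corrected
  out
}

#' Upper confidence bound for the combined disequilibrium distance
#'
#' One-sided asymptotic bound `delta_hat + z_(1-alpha) * tau_hat /
#' sqrt(n1 + n2)`.
#'
#' @param counts an [hwx_counts()] object without zero cells
#' @param alpha one-sided level, default 0.05
#' @return the upper (1 - alpha) confidence limit (log units)
#' @export
#' @examples
#' upper_confidence_bound(hwx_counts(230, 314, 107, n2 = 604, y = 399)) # 0.4526
upper_confidence_bound <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "hwx_counts"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5)
    .domain_error("alpha must lie in (0, 0.5)")
  pt <- estimate_point(counts)
  pt$delta + stats::qnorm(1 - alpha) *
    sqrt(tau_hat_sq(counts)) / sqrt(counts$n1 + counts$n2)
}

#' Equivalence test for Hardy-Weinberg compatibility of one X-linked SNP
#'
#' Tests H0: delta >= epsilon against H1: delta < epsilon. The null
#' hypothesis of relevant disequilibrium is rejected -- i.e. approximate
#' compatibility with the model is established -- when the upper
#' confidence bound falls below the margin.
#'
#' @param counts an [hwx_counts()] object
#' @param alpha one-sided nominal level, default 0.05
#' @param epsilon equivalence margin, default [hwx_margin()]
#' @param sparse policy for zero cells: `"reject"` raises a degenerate
#'   counts error, `"correct"` applies [sparse_correct()] first
#' @return an object of class `hwx_test` with the point estimate, variance
#'   estimate, upper bound and decision
#' @export
#' @examples
#' hwx_test(hwx_counts(230, 314, 107, n2 = 604, y = 399, snp_id = "rs6646338"))
hwx_test <- function(counts, alpha = 0.05, epsilon = hwx_margin(),
                     sparse = c("reject", "correct")) {
  stopifnot(inherits(counts, "hwx_counts"))
  sparse <- match.arg(sparse)
  if (!is.finite(epsilon) || epsilon <= 0)
    .domain_error("epsilon must be positive")
  corrected <- FALSE
  if (.has_zero_cell(counts)) {
    if (sparse == "reject")
      .degenerate_error("degenerate counts: zero cell (use sparse = \"correct\" to repair)")
    counts <- sparse_correct(counts)
    corrected <- TRUE
  }
  pt <- estimate_point(counts)
  t2 <- tau_hat_sq(counts)
  ub <- pt$delta + stats::qnorm(1 - alpha) * sqrt(t2) / sqrt(counts$n1 + counts$n2)
  structure(
    list(snp_id = counts$snp_id, counts = counts,
         delta_hat = pt$delta, delta_f_hat = pt$delta_f,
         delta_m_hat = pt$delta_m, tau_hat_sq = t2,
         upper_bound = ub, alpha = alpha, epsilon = epsilon,
         reject_null = ub < epsilon, corrected = corrected),
    class = "hwx_test")
}

#' @export
print.hwx_test <- function(x, ...) {
  cat("Equivalence test for HWE at an X-chromosomal SNP\n")
  if (!is.na(x$snp_id)) cat(sprintf("  SNP:            %s\n", x$snp_id))
  cat(sprintf("  delta_hat:      %.4f  (delta_f = %.4f, delta_m = %.4f)\n",
              x$delta_hat, x$delta_f_hat, x$delta_m_hat))
  cat(sprintf("  tau_hat_sq:     %.4f\n", x$tau_hat_sq))
  cat(sprintf("  upper %2.0f%% bound: %.4f   margin: %.4f\n",
              100 * (1 - x$alpha), x$upper_bound, x$epsilon))
  cat(sprintf("  decision:       %s\n",
              if (x$reject_null)
                "+ (approximate HWE compatibility established)"
              else "- (compatibility not established)"))
  if (x$corrected) cat("  note: sparse-count correction applied\n")
  invisible(x)
}

#' Run the equivalence test on every row of a counts table
#'
#' @param data a data frame with columns `snp_id, x1, x2, x3, n2, y`
#'   (e.g. from [read_counts()])
#' @inheritParams hwx_test
#' @return a data frame with one row per SNP: counts, `delta_hat`,
#'   `tau_hat_sq`, `upper_bound`, `decision` (`"+"`/`"-"`), `corrected`
#' @export
hwx_test_table <- function(data, alpha = 0.05, epsilon = hwx_margin(),
                           sparse = c("reject", "correct")) {
  sparse <- match.arg(sparse)
  need <- c("snp_id", "x1", "x2", "x3", "n2", "y")
  if (!all(need %in% names(data)))
    .domain_error(paste("missing columns:",
                        paste(setdiff(need, names(data)), collapse = ", ")))
  rows <- lapply(seq_len(nrow(data)), function(i) {
    cts <- hwx_counts(data$x1[i], data$x2[i], data$x3[i],
                      data$n2[i], data$y[i], data$snp_id[i])
    tst <- hwx_test(cts, alpha = alpha, epsilon = epsilon, sparse = sparse)
    # report the counts as observed; `corrected` flags a repaired table
    data.frame(snp_id = cts$snp_id, n1 = cts$n1,
               x1 = cts$x1, x2 = cts$x2, x3 = cts$x3,
               n2 = cts$n2, y = cts$y,
               delta_hat = tst$delta_hat, tau_hat_sq = tst$tau_hat_sq,
               upper_bound = tst$upper_bound,
               decision = if (tst$reject_null) "+" else "-",
               corrected = tst$corrected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
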