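# Disequilibrium parameterization for X-chromosomal diallelic markers.
#
# Females contribute a trinomial genotype distribution (pi1, pi2, pi3) for
# AA/AB/BB; hemizygous males contribute a binomial A-allele frequency pY.
# Disequilibrium is measured by two signed components on the log scale:
#   delta_f = log REH        (REH = pi2 / (2*sqrt(pi1*pi3)), 1 under HWE)
#   delta_m = logit(pX) - logit(pY),  pX = pi1 + pi2/2
# and their Euclidean combination delta = sqrt(delta_f^2 + delta_m^2).

.domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("hwx_domain_error", "error")))
}

.degenerate_error <- function(msg) {
  stop(errorCondition(msg, class = c("hwx_degenerate_error", "error")))
}

.check_freqs <- function(pi1, pi2, pi3, tol = 1e-12) {
  if (any(!is.finite(c(pi1, pi2, pi3))))
    .domain_error("genotype frequencies must be finite")
  if (pi1 <= 0 || pi2 <= 0 || pi3 <= 0 || pi1 >= 1 || pi2 >= 1 || pi3 >= 1)
    .domain_error("genotype frequencies must lie strictly inside (0, 1)")
  if (abs(pi1 + pi2 + pi3 - 1) > 1e-8)
    .domain_error("genotype frequencies must sum to 1")
  invisible(TRUE)
}

.check_prob <- function(p, what = "probability") {
  if (!is.finite(p) || p <= 0 || p >= 1)
    .domain_error(sprintf("%s must lie strictly inside (0, 1)", what))
  invisible(TRUE)
}

#' Default equivalence margin for the combined disequilibrium distance
#'
#' The margin is the radius of the smallest circle in the
#' (delta_f, delta_m) plane containing the square with half-edge
#' `log(fold)`, i.e. `sqrt(2) * log(fold)`. The default fold change of 1.4
#' corresponds to the conventional margin `log(1.4)` for the log relative
#' excess heterozygosity, giving a combined margin of about 0.4758.
#'
#' @param fold per-component fold-change margin on the natural scale
#' @return the combined equivalence margin (log units)
#' @export
#' @examples
#' hwx_margin()          # sqrt(2) * log(1.4)
hwx_margin <- function(fold = 1.4) {
  if (!is.finite(fold) || fold <= 1)
    .domain_error("fold must exceed 1")
  sqrt(2) * log(fold)
}

#' Signed female disequilibrium component (log relative excess heterozygosity)
#'
#' @param pi1,pi2,pi3 genotype frequencies of AA, AB, BB among females;
#'   strictly positive and summing to one
#' @return `log(pi2) - (log(pi1) + log(pi3))/2 - log(2)`; zero if and only
#'   if the female genotype distribution satisfies `pi2^2 = 4 * pi1 * pi3`
#' @export
#' @examples
#' delta_f_signed(0.25, 0.5, 0.25)        # 0: perfect HWE
#' delta_f_signed(0.25, 0.57897, 0.17103) # log(1.4), excess heterozygosity
delta_f_signed <- function(pi1, pi2, pi3) {
  .check_freqs(pi1, pi2, pi3)
  log(pi2) - (log(pi1) + log(pi3)) / 2 - log(2)
}

#' Signed male disequilibrium component (log odds ratio between the sexes)
#'
#' @param pX A-allele frequency among females (`pi1 + pi2/2`)
#' @param pY A-allele frequency among males
#' @return `logit(pX) - logit(pY)`
#' @export
delta_m_signed <- function(pX, pY) {
  .check_prob(pX, "pX")
  .check_prob(pY, "pY")
  stats::qlogis(pX) - stats::qlogis(pY)
}

#' Combine signed components into the Euclidean disequilibrium distance
#'
#' @param delta_f,delta_m signed components (log units)
#' @return a list with elements `delta_f`, `delta_m` and their Euclidean
#'   norm `delta`
#' @export
combined_delta <- function(delta_f, delta_m) {
  if (!is.finite(delta_f) || !is.finite(delta_m))
    .domain_error("components must be finite")
  list(delta_f = delta_f, delta_m = delta_m,
       delta = sqrt(delta_f^2 + delta_m^2))
}

#' Per-SNP observed counts for one X-chromosomal marker
#'
#' @param x1,x2,x3 female genotype counts for AA, AB, BB
#' @param n2 number of genotyped males
#' @param y number of males carrying allele A
#' @param snp_id optional marker label
#' @return an object of class `hwx_counts`
#' @export
#' @examples
#' hwx_counts(230, 314, 107, n2 = 604, y = 399, snp_id = "rs6646338")
hwx_counts <- function(x1, x2, x3, n2, y, snp_id = NA_character_) {
  for (v in list(x1, x2, x3, n2, y)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      .domain_error("counts must be single nonnegative integers")
  }
  n1 <- x1 + x2 + x3
  if (n1 < 1) .domain_error("at least one genotyped female is required (n1 >= 1)")
  if (n2 < 1) .domain_error("at least one genotyped male is required (n2 >= 1)")
  if (y > n2) .domain_error("y cannot exceed n2")
  structure(
    list(snp_id = as.character(snp_id),
         x1 = as.integer(x1), x2 = as.integer(x2), x3 = as.integer(x3),
         n1 = as.integer(n1), n2 = as.integer(n2), y = as.integer(y)),
    class = "hwx_counts")
}

#' @export
print.hwx_counts <- function(x, ...) {
  cat(sprintf("X-chromosomal SNP counts%s\n",
              if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]")))
  cat(sprintf("  females (AA/AB/BB): %d/%d/%d  (n1 = %d)\n",
              x$x1, x$x2, x$x3, x$n1))
  cat(sprintf("  males (A of n2):    %d of %d\n", x$y, x$n2))
  invisible(x)
}

.has_zero_cell <- function(counts) {
  counts$x1 == 0L || counts$x2 == 0L || counts$x3 == 0L ||
    counts$y == 0L || counts$y == counts$n2
}

#' Plug-in estimate of the disequilibrium components from observed counts
#'
#' Replaces the population frequencies in the two signed components by the
#' observed relative genotype and allele frequencies. All five cells
#' (x1, x2, x3, y, n2 - y) must be nonzero; sparse tables can be repaired
#' first with [sparse_correct()].
#'
#' @param counts an [hwx_counts()] object
#' @return a list with `delta_f`, `delta_m`, `delta` (as [combined_delta()])
#' @export
#' @examples
#' estimate_point(hwx_counts(230, 314, 107, n2 = 604, y = 399)) # delta ~ 0.2835
estimate_point <- function(counts) {
  stopifnot(inherits(counts, "hwx_counts"))
  if (.has_zero_cell(counts))
    .degenerate_error(
      "degenerate counts: a zero cell makes the plug-in estimate undefined (consider sparse_correct())")
  p1 <- counts$x1 / counts$n1
  p2 <- counts$x2 / counts$n1
  p3 <- counts$x3 / counts$n1
  pY <- counts$y / counts$n2
  combined_delta(delta_f_signed(p1, p2, p3),
                 delta_m_signed(p1 + p2 / 2, pY))
}

#' Solve for the heterozygote frequency giving a target female component
#'
#' At fixed `pi1` (with `pi3 = 1 - pi1 - pi2`) the signed female component
#' is strictly increasing in `pi2`, so a unique root exists for any finite
#' target. Used to construct boundary and conjugate parameter
#' configurations.
#'
#' @param pi1 fixed AA frequency in (0, 1)
#' @param target desired value of the signed female component
#' @param tol absolute tolerance of the bracketing root search
#' @return the unique `pi2` in (0, 1 - pi1)
#' @export
#' @examples
#' solve_pi2_for_delta_f(0.25, log(1.4)) # 0.57897
solve_pi2_for_delta_f <- function(pi1, target, tol = 1e-12) {
  .check_prob(pi1, "pi1")
  if (!is.finite(target)) .domain_error("target must be finite")
  lo <- tol
  hi <- 1 - pi1 - tol
  f <- function(pi2) delta_f_signed(pi1, pi2, 1 - pi1 - pi2) - target
  # component spans (-Inf, Inf) over (0, 1 - pi1), so the bracket holds
  stats::uniroot(f, lower = lo, upper = hi, tol = tol)$root
}

#' Solve for the male allele frequency giving a target male component
#'
#' Closed form: `logit(pY) = logit(pX) - target`.
#'
#' @param pX female A-allele frequency in (0, 1)
#' @param target desired value of the signed male component
#' @return `pY` in (0, 1)
#' @export
solve_pY_for_delta_m <- function(pX, target) {
  .check_prob(pX, "pX")
  if (!is.finite(target)) .domain_error("target must be finite")
  stats::plogis(stats::qlogis(pX) - target)
}

#' Population parameter configuration for design and exact computations
#'
#' @param pi1,pi2 female genotype frequencies of AA and AB (`pi3` is
#'   derived as the complement unless given)
#' @param pi3 optional BB frequency; must complete the simplex
#' @param pY male A-allele frequency
#' @param lam limiting fraction of females among all subjects, n1/(n1+n2)
#' @return an object of class `hwx_config` with the derived female allele
#'   frequency `pX` and the disequilibrium components attached
#' @export
#' @examples
#' pop_config(0.25, 0.5, pY = 0.5, lam = 1/2)  # perfect HWE
pop_config <- function(pi1, pi2, pi3 = NULL, pY, lam = 0.5) {
  if (is.null(pi3)) pi3 <- 1 - pi1 - pi2
  .check_freqs(pi1, pi2, pi3)
  .check_prob(pY, "pY")
  .check_prob(lam, "lam")
  pX <- pi1 + pi2 / 2
  df <- delta_f_signed(pi1, pi2, pi3)
  dm <- delta_m_signed(pX, pY)
  structure(
    list(pi1 = pi1, pi2 = pi2, pi3 = pi3, pY = pY, lam = lam, pX = pX,
         delta_f = df, delta_m = dm, delta = sqrt(df^2 + dm^2)),
    class = "hwx_config")
}

#' @export
print.hwx_config <- function(x, ...) {
  cat("X-chromosomal HWE parameter configuration\n")
  cat(sprintf("  pi = (%.5f, %.5f, %.5f), pX = %.5f, pY = %.5f, lambda = %.4f\n",
              x$pi1, x$pi2, x$pi3, x$pX, x$pY, x$lam))
  cat(sprintf("  delta_f = %.5f, delta_m = %.5f, delta = %.5f\n",
              x$delta_f, x$delta_m, x$delta))
  invisible(x)
}
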