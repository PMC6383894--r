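# Asymptotic variances of the component estimators and their combination.
#
# sqrt(N) * (delta_f_hat - delta_f) and sqrt(N) * (delta_m_hat - delta_m)
# are asymptotically independent normals with variances sigma_f_sq and
# sigma_m_sq; sqrt(N) * (delta_hat - delta) is asymptotically normal with
# variance tau_sq, a weighted mean of the two with weights proportional to
# the squared components.

#' Asymptotic variance of the female component estimator
#'
#' Variance of `sqrt(N) * delta_f_hat` under female genotype frequencies
#' (pi1, pi2, pi3) when a fraction `lam` of the N subjects are female:
#' `(1/lam) * ((1/4) * (1 - pi2)/(pi1*pi3) + 1/pi2)`.
#'
#' @inheritParams delta_f_signed
#' @param lam limiting female fraction n1/(n1+n2), in (0, 1)
#' @return the asymptotic variance (dimensionless)
#' @export
#' @examples
#' sigma_f_sq(0.25, 0.5, 0.25, lam = 1/2)  # 8
sigma_f_sq <- function(pi1, pi2, pi3, lam) {
  .check_freqs(pi1, pi2, pi3)
  .check_prob(lam, "lam")
  (1 / lam) * (0.25 * (1 - pi2) / (pi1 * pi3) + 1 / pi2)
}

#' Asymptotic variance of the male component estimator
#'
#' Variance of `sqrt(N) * delta_m_hat`, the empirical logit difference
#' between the female and male allele frequencies. By the delta method,
#' with `pX = pi1 + pi2/2`:
#' `1/((1-lam) pY (1-pY)) + (pi1 + pi2/4 - pX^2) / (lam pX^2 (1-pX)^2)`,
#' where `pi1 + pi2/4 - pX^2` is n1 times the sampling variance of the
#' empirical female allele frequency `pi1_hat + pi2_hat/2`.
#'
#' @inheritParams sigma_f_sq
#' @param pY male A-allele frequency
#' @return the asymptotic variance (dimensionless), strictly positive
#' @export
#' @examples
#' sigma_m_sq(0.25, 0.5, 0.25, pY = 0.5, lam = 1/2)  # 12
sigma_m_sq <- function(pi1, pi2, pi3, pY, lam) {
  .check_freqs(pi1, pi2, pi3)
  .check_prob(pY, "pY")
  .check_prob(lam, "lam")
  pX <- pi1 + pi2 / 2
  vX <- pi1 + pi2 / 4 - pX^2          # n1 * Var(pX_hat)
  1 / ((1 - lam) * pY * (1 - pY)) + vX / (lam * pX^2 * (1 - pX)^2)
}

#' Ratio of asymptotic standard deviations sigma_m / sigma_f
#'
#' This ratio is the scale parameter `c` of the extended chi distribution
#' governing the limiting law of `sqrt(N) * delta_hat` under alternatives
#' in perfect equilibrium.
#'
#' @inheritParams sigma_m_sq
#' @return `sqrt(sigma_m_sq / sigma_f_sq)`
#' @export
#' @examples
#' sigma_ratio(0.25, 0.5, 0.25, pY = 0.5, lam = 1/2)  # 1.22475
sigma_ratio <- function(pi1, pi2, pi3, pY, lam) {
  sqrt(sigma_m_sq(pi1, pi2, pi3, pY, lam) / sigma_f_sq(pi1, pi2, pi3, lam))
}

#' Combined asymptotic variance of the distance estimator
#'
#' Weighted mean of the component variances with weights
#' `delta_f^2 / delta^2` and `delta_m^2 / delta^2`. At `delta = 0` the
#' weights are undefined; the symmetric limit convention (equal weights)
#' is used there.
#'
#' @param delta_f,delta_m signed components of the configuration
#' @param sf2,sm2 component variances ([sigma_f_sq()], [sigma_m_sq()])
#' @return the asymptotic variance of `sqrt(N) * delta_hat`
#' @export
tau_sq <- function(delta_f, delta_m, sf2, sm2) {
  d2 <- delta_f^2 + delta_m^2
  if (d2 == 0) (sf2 + sm2) / 2
  else (delta_f^2 * sf2 + delta_m^2 * sm2) / d2
}

#' Plug-in estimate of the combined variance from observed counts
#'
#' Replaces all population quantities by observed relative frequencies and
#' the limiting female fraction by `n1 / (n1 + n2)`.
#'
#' @param counts an [hwx_counts()] object with no zero cells
#' @return the estimated variance of `sqrt(n1 + n2) * delta_hat`
#' @export
#' @examples
#' tau_hat_sq(hwx_counts(230, 314, 107, n2 = 604, y = 399))  # 13.2641
tau_hat_sq <- function(counts) {
  stopifnot(inherits(counts, "hwx_counts"))
  pt <- estimate_point(counts)
  p1 <- counts$x1 / counts$n1
  p2 <- counts$x2 / counts$n1
  p3 <- counts$x3 / counts$n1
  pY <- counts$y / counts$n2
  lam <- counts$n1 / (counts$n1 + counts$n2)
  tau_sq(pt$delta_f, pt$delta_m,
         sigma_f_sq(p1, p2, p3, lam),
         sigma_m_sq(p1, p2, p3, pY, lam))
}
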