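# Study planning: approximate power and closed sample-size formulas for
# the equivalence test, against non-null alternatives (0 < delta < margin,
# Gaussian limit) and null alternatives (perfect equilibrium, extended chi
# limit). The "boundary" variance entering both formulas is evaluated at a
# conjugate point on the equivalence circle.

#' Conjugate boundary point for study planning
#'
#' For an alternative with AA frequency `pi1_star`, the conjugate point
#' keeps `pi1` fixed and places both signed components at
#' `epsilon / sqrt(2)` (positive sign), so the point lies on the circle of
#' radius `epsilon` in the (delta_f, delta_m) plane. The boundary
#' variances entering the planning formulas are evaluated here.
#'
#' @param pi1_star AA genotype frequency of the alternative of interest
#' @param lam limiting female fraction
#' @param epsilon equivalence margin
#' @return a list with the conjugate frequencies (`pi1`, `pi2`, `pi3`,
#'   `pY`, `pX`) and the variances `sigma_f_sq`, `sigma_m_sq`, `tau_sq`
#'   (equal-weight combination) at the point
#' @export
#' @examples
#' conjugate_point(0.25, lam = 1/2)  # pi2 = 0.57897, pY = 0.45557
conjugate_point <- function(pi1_star, lam = 0.5, epsilon = hwx_margin()) {
  .check_prob(pi1_star, "pi1_star")
  .check_prob(lam, "lam")
  target <- epsilon / sqrt(2)
  pi2 <- solve_pi2_for_delta_f(pi1_star, target)
  pi3 <- 1 - pi1_star - pi2
  pX <- pi1_star + pi2 / 2
  pY <- solve_pY_for_delta_m(pX, target)
  sf2 <- sigma_f_sq(pi1_star, pi2, pi3, lam)
  sm2 <- sigma_m_sq(pi1_star, pi2, pi3, pY, lam)
  list(pi1 = pi1_star, pi2 = pi2, pi3 = pi3, pY = pY, pX = pX,
       delta_f = target, delta_m = target,
       sigma_f_sq = sf2, sigma_m_sq = sm2,
       tau_sq = tau_sq(target, target, sf2, sm2))
}

.tau_tilde <- function(conj, convention) {
  switch(convention,
         sigma_f = sqrt(conj$sigma_f_sq),
         eq_mean = sqrt(conj$tau_sq),
         .domain_error("unknown tau-tilde convention"))
}

.round_design <- function(N, lam) {
  n1 <- ceiling(lam * N)
  n2 <- round(n1 * (1 - lam) / lam)
  list(n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Approximate power against a non-null alternative
#'
#' Gaussian approximation
#' `Phi((tau_tilde * z_alpha - sqrt(N) * (delta - epsilon)) / tau)` for an
#' alternative with `0 < delta`, where `tau` is the combined standard
#' deviation at the alternative and `tau_tilde` the boundary value at its
#' conjugate point.
#'
#' @param config an [pop_config()] alternative with `delta > 0`
#' @param N total sample size (`n1 + n2`)
#' @param alpha one-sided nominal level
#' @param epsilon equivalence margin
#' @param convention boundary-variance rule: `"sigma_f"` (female
#'   component standard deviation at the conjugate point; reproduces the
#'   reference sample-size tables) or `"eq_mean"` (the weighted-mean
#'   combined variance at the conjugate point)
#' @return the approximate rejection probability
#' @export
approx_power_nonnull <- function(config, N, alpha = 0.05,
                                 epsilon = hwx_margin(),
                                 convention = c("sigma_f", "eq_mean")) {
  stopifnot(inherits(config, "hwx_config"))
  convention <- match.arg(convention)
  if (config$delta == 0)
    .domain_error("delta = 0: use approx_power_null() for null alternatives")
  conj <- conjugate_point(config$pi1, config$lam, epsilon)
  tt <- .tau_tilde(conj, convention)
  tau <- sqrt(tau_sq(config$delta_f, config$delta_m,
                     sigma_f_sq(config$pi1, config$pi2, config$pi3, config$lam),
                     sigma_m_sq(config$pi1, config$pi2, config$pi3,
                                config$pY, config$lam)))
  stats::pnorm((tt * stats::qnorm(alpha) - sqrt(N) * (config$delta - epsilon)) / tau)
}

#' Sample size for a target power against a non-null alternative
#'
#' Closed formula
#' `N = (tau_tilde * z_(1-alpha) + tau * z_(1-beta))^2 / (delta - epsilon)^2`,
#' rounded to `n1 = ceiling(lam * N)` females and
#' `n2 = round(n1 * (1 - lam) / lam)` males.
#'
#' @inheritParams approx_power_nonnull
#' @param power target power `1 - beta`
#' @return an object of class `hwx_design`: `N_total` (formula value),
#'   `n1`, `n2`, `approx_power_at_n`, and the `convention` used
#' @export
#' @examples
#' alt <- pop_config(0.25, 0.54097, pY = 0.47846, lam = 1/2)
#' sample_size_nonnull(alt, power = 0.8)  # n1 = n2 = 485
sample_size_nonnull <- function(config, alpha = 0.05, power = 0.8,
                                epsilon = hwx_margin(),
                                convention = c("sigma_f", "eq_mean")) {
  stopifnot(inherits(config, "hwx_config"))
  convention <- match.arg(convention)
  if (config$delta == 0)
    .domain_error("delta = 0: use sample_size_null() for null alternatives")
  if (config$delta >= epsilon)
    .domain_error("infeasible design: the alternative lies outside the equivalence region (delta >= epsilon)")
  conj <- conjugate_point(config$pi1, config$lam, epsilon)
  tt <- .tau_tilde(conj, convention)
  tau <- sqrt(tau_sq(config$delta_f, config$delta_m,
                     sigma_f_sq(config$pi1, config$pi2, config$pi3, config$lam),
                     sigma_m_sq(config$pi1, config$pi2, config$pi3,
                                config$pY, config$lam)))
  N <- (tt * stats::qnorm(1 - alpha) + tau * stats::qnorm(power))^2 /
    (config$delta - epsilon)^2
  n <- .round_design(N, config$lam)
  structure(
    list(N_total = N, n1 = n$n1, n2 = n$n2,
         approx_power_at_n = approx_power_nonnull(config, n$n1 + n$n2,
                                                  alpha, epsilon, convention),
         alpha = alpha, power_target = power, epsilon = epsilon,
         convention = convention, kind = "nonnull"),
    class = "hwx_design")
}

#' Approximate power against a null alternative (perfect equilibrium)
#'
#' Under perfect equilibrium `sqrt(N) * delta_hat` converges to an
#' extended chi law rather than a Gaussian. The approximation is
#' `Q_c((sqrt(N) * epsilon - z_(1-alpha) * max(sigma_f~, sigma_m~)) / sigma_f)`
#' with `c = sigma_m / sigma_f` at the null alternative and the tilde
#' variances at its conjugate point (the max rule improves on the
#' weighted-mean boundary variance).
#'
#' @param config an [pop_config()] in perfect equilibrium (`delta = 0`)
#' @inheritParams approx_power_nonnull
#' @return the approximate rejection probability (0 when the argument of
#'   the CDF is negative)
#' @export
approx_power_null <- function(config, N, alpha = 0.05,
                              epsilon = hwx_margin()) {
  stopifnot(inherits(config, "hwx_config"))
  if (config$delta > 1e-10)
    .domain_error("config is not a null alternative (delta > 0)")
  sf <- sqrt(sigma_f_sq(config$pi1, config$pi2, config$pi3, config$lam))
  sm <- sqrt(sigma_m_sq(config$pi1, config$pi2, config$pi3,
                        config$pY, config$lam))
  conj <- conjugate_point(config$pi1, config$lam, epsilon)
  smax <- sqrt(max(conj$sigma_f_sq, conj$sigma_m_sq))
  arg <- (sqrt(N) * epsilon - stats::qnorm(1 - alpha) * smax) / sf
  if (arg <= 0) return(0)
  pextchi(arg, sm / sf)
}

#' Sample size for a target power against a null alternative
#'
#' Closed formula
#' `N = (z_(1-alpha) * max(sigma_f~, sigma_m~) + sigma_f * Qc^{-1}(power))^2
#' / epsilon^2` with `c = sigma_m / sigma_f`, rounded as in
#' [sample_size_nonnull()].
#'
#' @inheritParams approx_power_null
#' @param power target power `1 - beta`
#' @return an object of class `hwx_design`
#' @export
#' @examples
#' null_alt <- pop_config(0.25, 0.5, pY = 0.5, lam = 1/2)
#' sample_size_null(null_alt, power = 0.8)  # n1 = n2 = 279
sample_size_null <- function(config, alpha = 0.05, power = 0.8,
                             epsilon = hwx_margin()) {
  stopifnot(inherits(config, "hwx_config"))
  if (config$delta > 1e-10)
    .domain_error("config is not a null alternative (delta > 0)")
  sf <- sqrt(sigma_f_sq(config$pi1, config$pi2, config$pi3, config$lam))
  sm <- sqrt(sigma_m_sq(config$pi1, config$pi2, config$pi3,
                        config$pY, config$lam))
  conj <- conjugate_point(config$pi1, config$lam, epsilon)
  smax <- sqrt(max(conj$sigma_f_sq, conj$sigma_m_sq))
  N <- (stats::qnorm(1 - alpha) * smax + sf * qextchi(power, sm / sf))^2 /
    epsilon^2
  n <- .round_design(N, config$lam)
  structure(
    list(N_total = N, n1 = n$n1, n2 = n$n2,
         approx_power_at_n = approx_power_null(config, n$n1 + n$n2,
                                               alpha, epsilon),
         alpha = alpha, power_target = power, epsilon = epsilon,
         convention = "max_sigma_tilde", kind = "null",
         sigma_ratio = sm / sf),
    class = "hwx_design")
}

#' @export
print.hwx_design <- function(x, ...) {
  cat(sprintf("Sample size for the HWE equivalence test (%s alternative)\n",
              if (x$kind == "null") "null" else "non-null"))
  cat(sprintf("  formula N:  %.2f\n", x$N_total))
  cat(sprintf("  n1 (females): %d   n2 (males): %d\n", x$n1, x$n2))
  cat(sprintf("  approximate power at (n1, n2): %.4f (target %.2f)\n",
              x$approx_power_at_n, x$power_target))
  cat(sprintf("  alpha = %.3f, epsilon = %.4f, boundary-variance rule: %s\n",
              x$alpha, x$epsilon, x$convention))
  invisible(x)
}
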