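# Asymptotic variance formulas: closed-form female part, delta-method
# male part checked against a numerically differentiated oracle, and the
# weighted combination with its plug-in estimator.

test_that("female variance matches its closed form and 1/lambda scaling", {
  expect_close(sigma_f_sq(0.25, 0.5, 0.25, lam = 1/2), 8, 1e-12)
  expect_close(sigma_f_sq(0.25, 0.5, 0.25, lam = 1/3), 12, 1e-12)
  set.seed(5)
  for (k in 1:10) {
    cfg <- random_config()
    lam <- runif(1, 0.2, 0.8)
    expect_close(sigma_f_sq(cfg$pi1, cfg$pi2, cfg$pi3, lam),
                 sigma_f_sq(cfg$pi1, cfg$pi2, cfg$pi3, 0.999999) *
                   0.999999 / lam, 1e-6)
  }
})

test_that("male variance agrees with a numerical delta-method oracle", {
  # oracle: numerically differentiate g(pi1, pi2, pY) = logit(pi1 + pi2/2)
  # - logit(pY) and contract with the multinomial/binomial covariance of
  # the empirical frequencies (scaled by N)
  oracle <- function(pi1, pi2, pY, lam) {
    g <- function(v) stats::qlogis(v[1] + v[2] / 2) - stats::qlogis(v[3])
    v0 <- c(pi1, pi2, pY)
    h <- 1e-6
    grad <- vapply(1:3, function(i) {
      e <- rep(0, 3); e[i] <- h
      (g(v0 + e) - g(v0 - e)) / (2 * h)
    }, numeric(1))
    # Cov of sqrt(N) * (pi1_hat, pi2_hat, pY_hat)
    S <- matrix(0, 3, 3)
    S[1, 1] <- pi1 * (1 - pi1) / lam
    S[2, 2] <- pi2 * (1 - pi2) / lam
    S[1, 2] <- S[2, 1] <- -pi1 * pi2 / lam
    S[3, 3] <- pY * (1 - pY) / (1 - lam)
    drop(t(grad) %*% S %*% grad)
  }
  expect_close(sigma_m_sq(0.25, 0.5, 0.25, 0.5, 1/2), 12, 1e-12)
  expect_close(sigma_m_sq(0.09, 0.42, 0.49, 0.3, 1/2), 14.28571, 1e-5)
  set.seed(6)
  for (k in 1:10) {
    cfg <- random_config()
    lam <- runif(1, 0.2, 0.8)
    expect_close(sigma_m_sq(cfg$pi1, cfg$pi2, cfg$pi3, cfg$pY, lam),
                 oracle(cfg$pi1, cfg$pi2, cfg$pY, lam), 1e-7)
  }
})

test_that("standard-deviation ratios reproduce the reference table", {
  # at the uniform configuration the ratio is exactly sqrt(12/8) =
  # 1.2247449, which rounds to 1.22474; the reference prints 1.22475
  # (one final-digit ulp up), so that entry is asserted at one ulp
  expect_close(sigma_ratio(0.25, 0.50, 0.25, 0.5, 1/2), sqrt(1.5), 1e-12)
  expect_close(sigma_ratio(0.25, 0.50, 0.25, 0.5, 1/2), 1.22475, 1.05e-5)
  expect_close(sigma_ratio(0.09, 0.42, 0.49, 0.3, 1/2), 1.12250, 5e-6)
  expect_close(sigma_ratio(0.25, 0.50, 0.25, 0.5, 1/3), 1.00000, 5e-6)
  expect_close(sigma_ratio(0.01, 0.18, 0.81, 0.1, 1/2), 0.73485, 5e-6)
})

test_that("combined variance is a weighted mean between the components", {
  expect_equal(tau_sq(0.2, 0.2, 8, 12), 10)   # equal weights
  expect_equal(tau_sq(0, 0.3, 8, 12), 12)     # degenerate weighting
  expect_equal(tau_sq(0, 0, 8, 12), 10)       # zero-delta convention
  set.seed(7)
  for (k in 1:25) {
    df <- rnorm(1); dm <- rnorm(1)
    sf2 <- runif(1, 1, 20); sm2 <- runif(1, 1, 20)
    t2 <- tau_sq(df, dm, sf2, sm2)
    expect_gte(t2, min(sf2, sm2) - 1e-12)
    expect_lte(t2, max(sf2, sm2) + 1e-12)
  }
})

test_that("plug-in combined variance reproduces the worked examples", {
  g <- geneva_counts()
  expect_close(tau_hat_sq(g$rs6646338), 13.2641, 5.5e-5)
  expect_close(tau_hat_sq(g$rs5935567), 8.8719, 5.5e-5)
  expect_close(tau_hat_sq(g$rs5968922), 12.1492, 5.5e-5)
})
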