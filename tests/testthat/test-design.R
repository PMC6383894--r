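# Study planning: conjugate points, approximate power, and the two
# sample-size formulas with their table-reproducing conventions.

test_that("conjugate point places both components on the circle", {
  for (pi1 in c(0.25, 0.09, 0.04)) {
    cp <- conjugate_point(pi1, lam = 1/2)
    tgt <- hwx_margin() / sqrt(2)
    expect_close(delta_f_signed(cp$pi1, cp$pi2, cp$pi3), tgt, 1e-10)
    expect_close(delta_m_signed(cp$pX, cp$pY), tgt, 1e-10)
    expect_close(sqrt(2) * tgt, hwx_margin(), 1e-12)
  }
  cp <- conjugate_point(0.25, lam = 1/2)
  expect_close(cp$pi2, 0.57897, 1e-5)
  expect_close(cp$pY, 0.45557, 1e-5)
  expect_close(conjugate_point(0.09, 1/2)$pi2, 0.52274, 1e-5)
})

test_that("non-null sample sizes reproduce the reference table", {
  expected <- list(list(lam = 1/2, n1 = 485, n2 = 485),
                   list(lam = 1/3, n1 = 449, n2 = 898),
                   list(lam = 2/3, n1 = 552, n2 = 276),
                   list(lam = 1/4, n1 = 436, n2 = 1308),
                   list(lam = 3/4, n1 = 612, n2 = 204))
  for (e in expected) {
    d <- sample_size_nonnull(diag_alt(0.25, e$lam), power = 0.8)
    expect_equal(d$n1, e$n1)
    expect_equal(d$n2, e$n2)
  }
  # second reference block: components at 0.4 * log(1.4)
  d2 <- sample_size_nonnull(diag_alt(0.04, 1/2, frac = 0.4), power = 0.8)
  expect_equal(c(d2$n1, d2$n2), c(697, 697))
})

test_that("formula N attains the target power under its own approximation", {
  alt <- diag_alt(0.25, 1/2)
  d <- sample_size_nonnull(alt, power = 0.8)
  expect_close(approx_power_nonnull(alt, d$N_total), 0.8, 1e-3)
  # boundary behavior: at delta = margin the approximate power is ~alpha
  b <- boundary_config(0.25, 1, 1)
  cfg <- pop_config(b$pi1, b$pi2, pY = b$pY, lam = 1/2)
  expect_close(approx_power_nonnull(cfg, 800), 0.05, 0.03)
  expect_error(sample_size_nonnull(cfg), class = "hwx_domain_error")
  expect_gt(approx_power_nonnull(diag_alt(0.25, 1/2), 1e7), 0.9999)
})

test_that("null-alternative sample sizes reproduce the reference table", {
  n0 <- pop_config(0.25, 0.5, pY = 0.5, lam = 1/2)
  expect_equal(sample_size_null(n0, power = 0.6)$n1, 213)
  expect_equal(sample_size_null(n0, power = 0.8)$n1, 279)
  expect_equal(sample_size_null(n0, power = 0.9)$n1, 338)
  rare <- pop_config(0.01, 0.18, pY = 0.1, lam = 1/2)
  expect_equal(sample_size_null(rare, power = 0.8)$n1, 1375)
  n13 <- pop_config(0.25, 0.5, pY = 0.5, lam = 1/3)
  d <- sample_size_null(n13, power = 0.8)
  expect_equal(c(d$n1, d$n2), c(214, 428))
})

test_that("null sample size is monotone in power and margin", {
  n0 <- pop_config(0.09, 0.42, pY = 0.3, lam = 1/2)
  sizes <- vapply(c(0.6, 0.8, 0.9),
                  function(pw) sample_size_null(n0, power = pw)$n1, integer(1))
  expect_true(all(diff(sizes) > 0))
  wide <- sample_size_null(n0, power = 0.8, epsilon = 2 * hwx_margin())
  expect_lt(wide$n1, sample_size_null(n0, power = 0.8)$n1)
})

test_that("null power approximation inverts the size formula", {
  n0 <- pop_config(0.25, 0.5, pY = 0.5, lam = 1/2)
  expect_close(approx_power_null(n0, 558), 0.80, 0.01)
  expect_equal(approx_power_null(n0, 10), 0)
  expect_gt(approx_power_null(n0, 1e6), 0.99999)
  # null/non-null guards
  expect_error(approx_power_null(diag_alt(0.25, 1/2), 500),
               class = "hwx_domain_error")
  expect_error(approx_power_nonnull(n0, 500), class = "hwx_domain_error")
})
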