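# Disequilibrium components, plug-in estimation, and the root-solvers
# used to construct boundary configurations.

test_that("signed components reproduce reference boundary values", {
  # perfect HWE and equal allele frequencies give zero components
  expect_equal(delta_f_signed(0.25, 0.5, 0.25), 0)
  expect_equal(delta_m_signed(0.3, 0.3), 0)

  # reference table rows: components at +/- log(1.4) = +/- 0.33647
  expect_close(delta_f_signed(0.25, 0.57897, 0.17103), 0.33647, 1e-4)
  expect_close(delta_f_signed(0.25, 0.41402, 0.33598), -0.33647, 1e-4)
  expect_close(delta_m_signed(0.53949, 0.45557), 0.33647, 1e-4)
  expect_close(delta_m_signed(0.52048, 0.47846), 0.16824, 1e-4)
})

test_that("combined distance is the Euclidean norm of the components", {
  expect_equal(combined_delta(0, 0)$delta, 0)
  expect_close(combined_delta(0.16824, 0.16824)$delta, 0.23792, 1e-4)
  expect_close(combined_delta(0.13459, 0.13459)$delta, 0.19034, 1e-4)
  pt <- combined_delta(-0.3, 0.4)
  expect_close(pt$delta, sqrt(0.3^2 + 0.4^2), 1e-12)
})

test_that("default margin is the circle radius through (log 1.4, log 1.4)", {
  expect_close(hwx_margin(), sqrt(2) * log(1.4), 1e-12)
  # any configuration with both components at +/- log(1.4) sits on the circle
  for (sf in c(-1, 1)) for (sm in c(-1, 1)) {
    cfg <- boundary_config(0.25, sf, sm)
    pX <- cfg$pi1 + cfg$pi2 / 2
    d <- combined_delta(delta_f_signed(cfg$pi1, cfg$pi2, 1 - cfg$pi1 - cfg$pi2),
                        delta_m_signed(pX, cfg$pY))$delta
    expect_close(d, hwx_margin(), 1e-10)
  }
})

test_that("plug-in estimate reproduces the worked examples", {
  expect_close(estimate_point(geneva_counts()$rs6646338)$delta, 0.2835, 5.5e-5)
  expect_close(estimate_point(geneva_counts()$rs5968922)$delta, 0.0040, 5.5e-5)
  # empirically exact HWE with equal allele frequencies
  expect_equal(estimate_point(hwx_counts(25, 50, 25, 100, 50))$delta, 0)
})

test_that("degenerate and domain errors are distinct", {
  expect_error(estimate_point(hwx_counts(651, 0, 0, 605, 603)),
               class = "hwx_degenerate_error")
  expect_error(delta_f_signed(0, 0.5, 0.5), class = "hwx_domain_error")
  expect_error(delta_m_signed(1, 0.5), class = "hwx_domain_error")
  expect_error(hwx_counts(1, 2, 3, n2 = 5, y = 6), class = "hwx_domain_error")
})

test_that("solvers invert the components to tight tolerance", {
  expect_close(solve_pi2_for_delta_f(0.25, 0), 0.5, 1e-9)
  expect_close(solve_pi2_for_delta_f(0.25, log(1.4)), 0.57897, 1e-5)
  expect_close(solve_pi2_for_delta_f(0.09, log(1.4)), 0.52274, 1e-5)
  expect_close(solve_pY_for_delta_m(0.53949, log(1.4)), 0.45557, 1e-5)
  expect_close(solve_pY_for_delta_m(0.3, 0), 0.3, 1e-12)
  expect_close(solve_pY_for_delta_m(0.35137, -log(1.4)), 0.43130, 1e-5)
  # solver residuals
  set.seed(11)
  for (k in 1:20) {
    pi1 <- runif(1, 0.02, 0.7)
    target <- runif(1, -2, 2)
    pi2 <- solve_pi2_for_delta_f(pi1, target)
    expect_lt(abs(delta_f_signed(pi1, pi2, 1 - pi1 - pi2) - target), 1e-9)
  }
})

test_that("allele relabeling preserves the combined distance", {
  # swapping the allele coding maps (pi1, pi2, pi3) -> (pi3, pi2, pi1)
  # and pY -> 1 - pY: the female component is symmetric in the two
  # homozygote frequencies (hence invariant), the male component flips
  # sign, and the combined distance is unchanged
  set.seed(3)
  for (k in 1:25) {
    cfg <- random_config()
    df1 <- delta_f_signed(cfg$pi1, cfg$pi2, cfg$pi3)
    df2 <- delta_f_signed(cfg$pi3, cfg$pi2, cfg$pi1)
    pX <- cfg$pi1 + cfg$pi2 / 2
    dm1 <- delta_m_signed(pX, cfg$pY)
    dm2 <- delta_m_signed(1 - pX, 1 - cfg$pY)
    expect_close(df2, df1, 1e-12)
    expect_close(dm2, -dm1, 1e-12)
    expect_close(combined_delta(df1, dm1)$delta,
                 combined_delta(df2, dm2)$delta, 1e-12)
  }
})

test_that("female component is strictly increasing in pi2 at fixed pi1", {
  pi1 <- 0.2
  pi2 <- seq(0.05, 0.7, by = 0.05)
  vals <- vapply(pi2, function(p2) delta_f_signed(pi1, p2, 1 - pi1 - p2),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})
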