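test_that("single-unit and CFU survival match frozen closed-form values", {
  p <- ctrl_params()
  # frozen from independent high-precision evaluation of the closed forms
  expect_equal(single_unit_survival(8, p), 0.1265832768, tolerance = 1e-9)
  expect_equal(cfu_survival(8, p), 0.4180495449, tolerance = 1e-9)
  # dose 0 is exactly 1, no tolerance
  expect_identical(single_unit_survival(0, p), 1)
  expect_identical(cfu_survival(0, p), 1)
  # beta = 0 collapses to the pure exponential
  p0 <- survival_params(0.3, 0, 0.7)
  expect_equal(single_unit_survival(5, p0), exp(-1.5), tolerance = 1e-12)
  # n_units = 1 makes both curves identical
  p1 <- survival_params(0.29, 1.9, 0.35, n_units = 1L)
  d <- seq(0, 10, 0.25)
  expect_equal(cfu_survival(d, p1), single_unit_survival(d, p1))
})

test_that("parameter and dose validation rejects out-of-domain input", {
  expect_error(survival_params(-0.1, 1, 1), "alpha")
  expect_error(survival_params(0.3, -1, 1), "beta")
  expect_error(survival_params(0.3, 1, -1), "delta")
  expect_error(survival_params(0.3, 1, 1, n_units = 0), "n_units")
  expect_error(single_unit_survival(-1, ctrl_params()), "dose")
  expect_error(approximate_survival(3, ctrl_params(), "quadratic"))
})

test_that("approximations agree with their closed forms and limits", {
  p <- ctrl_params()
  expect_equal(approximate_survival(8, p, "asymptotic"), exp(-0.29 * 8),
               tolerance = 1e-12)
  # beta = 0: first order and asymptotic coincide everywhere
  p0 <- survival_params(0.4, 0, 0.5)
  d <- seq(0, 12, 0.5)
  expect_equal(approximate_survival(d, p0, "first_order"),
               approximate_survival(d, p0, "asymptotic"))
  # at delta*D = 10 the first-order error is far below 1e-3 (frozen: ~3e-8)
  D <- 10 / p$delta
  rel <- abs(approximate_survival(D, p, "first_order") -
               single_unit_survival(D, p)) / single_unit_survival(D, p)
  expect_lt(rel, 1e-3)
})

test_that("first-order approximation error decays as delta*D grows", {
  prm <- random_params(10, seed = 11)
  for (k in seq_len(nrow(prm))) {
    p <- survival_params(prm$alpha[k], prm$beta[k], prm$delta[k])
    dd <- seq(3, 12, 1) / p$delta   # delta*D from 3 to 12
    err <- abs(approximate_survival(dd, p, "first_order") -
                 single_unit_survival(dd, p))
    expect_true(all(diff(err) <= 1e-12))
  }
})

test_that("CFU survival is a strictly decreasing probability in dose", {
  prm <- random_params(20, seed = 7)
  d <- seq(0, 30, 0.1)
  for (k in seq_len(nrow(prm))) {
    p <- survival_params(prm$alpha[k], prm$beta[k], prm$delta[k])
    s <- cfu_survival(d, p)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) < 0))
  }
})

test_that("beta -> 0 and delta -> Inf limits reduce to exp(-alpha D)", {
  d <- seq(0.5, 10, 0.5)
  expect_equal(single_unit_survival(d, survival_params(0.29, 0, 0.35)),
               exp(-0.29 * d), tolerance = 1e-15)
  expect_equal(single_unit_survival(d, survival_params(0.29, 1.9, 1e8)),
               exp(-0.29 * d), tolerance = 1e-12)
})

test_that("dose_at_survival inverts the CFU curve", {
  # analytic inversion for the degenerate exponential case
  p <- survival_params(0.5, 0, 0.3, n_units = 1L)
  expect_equal(dose_at_survival(p, exp(-1)), 2, tolerance = 1e-5)
  # frozen bisection oracle values for the packaged parameter rows
  expect_equal(dose_at_survival(ctrl_params(), 0.5, tol = 1e-9), 7.33404827,
               tolerance = 1e-6)
  expect_equal(dose_at_survival(ptnp_params(), 0.5, tol = 1e-9), 5.97570905,
               tolerance = 1e-6)
  expect_error(dose_at_survival(ctrl_params(), 1.2), "target")
  expect_error(dose_at_survival(survival_params(1e-6, 0, 0), 0.5,
                                dose_cap = 10), "dose cap")
})

test_that("dose_at_survival composed with cfu_survival is the identity", {
  prm <- random_params(15, seed = 23)
  doses <- withr::with_seed(24, stats::runif(15, 0.5, 15))
  for (k in seq_len(nrow(prm))) {
    p <- survival_params(prm$alpha[k], prm$beta[k], prm$delta[k])
    target <- cfu_survival(doses[k], p)
    expect_equal(dose_at_survival(p, target), doses[k], tolerance = 1e-4)
  }
})

test_that("SER equals the ratio of iso-effect doses", {
  expect_equal(sensitization_enhancement_ratio(ctrl_params(), ctrl_params()),
               1, tolerance = 1e-9)
  # frozen oracle: 7.33404827 / 5.97570905
  expect_equal(
    sensitization_enhancement_ratio(ctrl_params(), ptnp_params()),
    1.22731013, tolerance = 1e-6)
  # doubling alpha in the pure exponential doubles the iso-effect dose ratio
  a <- survival_params(0.2, 0, 0, n_units = 1L)
  b <- survival_params(0.4, 0, 0, n_units = 1L)
  expect_equal(sensitization_enhancement_ratio(a, b), 2, tolerance = 1e-6)
})

test_that("amplification is the relative survival reduction", {
  expect_equal(amplification_at_dose(0.37, 0.22), 0.15 / 0.37,
               tolerance = 1e-12)
  expect_identical(amplification_at_dose(0.8, 0.8), 0)
  expect_equal(amplification_at_dose(1.0, 0.5), 0.5)
  expect_error(amplification_at_dose(0, 0.5))
  expect_warning(out <- amplification_at_dose(0.5, 0.8), "protection")
  expect_lt(out, 0)
})
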