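test_that("CFU inversion is the algebraic inverse of the multi-target form", {
  expect_identical(invert_cfu_to_unit_survival(1, 4L), 1)
  s <- seq(0.05, 1, 0.05)
  expect_equal(invert_cfu_to_unit_survival(s, 1L), s)
  # frozen inverse of the worked CFU example
  expect_equal(invert_cfu_to_unit_survival(0.4180495449, 4L), 0.1265832768,
               tolerance = 1e-9)
  # round trip through the forward relation for several unit counts
  for (n in c(1L, 2L, 4L, 7L)) {
    su <- invert_cfu_to_unit_survival(s, n)
    expect_equal(1 - (1 - su)^n, s, tolerance = 1e-12)
  }
  expect_error(invert_cfu_to_unit_survival(0, 4L))
  expect_error(invert_cfu_to_unit_survival(1.1, 4L))
})

test_that("asymptotic alpha estimator matches the through-origin formula", {
  # exact exponential data: estimator is exact at any threshold
  d <- seq(0, 8, 1)
  dat <- survival_dataset(
    tibble::tibble(dose_kGy = d, survival = exp(-0.3 * d)))
  expect_equal(as.numeric(estimate_alpha_asymptotic(dat, n_units = 1L)), 0.3,
               tolerance = 1e-12)
  # frozen hand evaluation on the control-row single-unit curve at D = 6,7,8
  du <- c(0, 6, 7, 8)
  dat2 <- survival_dataset(
    tibble::tibble(dose_kGy = du,
                   survival = single_unit_survival(du, ctrl_params())))
  expect_equal(as.numeric(estimate_alpha_asymptotic(dat2, threshold = 6,
                                                    n_units = 1L)),
               0.24744166, tolerance = 1e-7)
  # a single qualifying point is not enough
  expect_error(estimate_alpha_asymptotic(dat2, threshold = 8, n_units = 1L),
               "fewer than 2")
})

test_that("adjusted R-squared matches brute-force evaluation", {
  obs <- c(1, 0.8, 0.55, 0.4, 0.3)
  pred <- c(0.95, 0.78, 0.6, 0.38, 0.28)
  # hand computation: RSS = 0.0062, TSS = 0.332, R2 = 0.98132530,
  # adj = 1 - (1 - R2) * 4 / 2
  expect_equal(adjusted_r_squared(obs, pred, 2), 0.9626506, tolerance = 1e-6)
  expect_equal(adjusted_r_squared(obs, obs, 2), 1)
  expect_lte(adjusted_r_squared(obs, rep(mean(obs), 5), 2), 0)
  expect_error(adjusted_r_squared(rep(0.5, 5), pred, 2), "constant")
  expect_error(adjusted_r_squared(obs, pred[1:4], 2), "equal length")
})

test_that("noiseless self-consistency recovers both packaged parameter rows", {
  for (p in list(ctrl_params(), ptnp_params())) {
    fit <- fit_survival_model(noiseless_dataset(p))
    expect_equal(fit$params$alpha, p$alpha, tolerance = 1e-4)
    expect_equal(fit$params$beta, p$beta, tolerance = 1e-3)
    expect_equal(fit$params$delta, p$delta, tolerance = 1e-3)
    expect_true(fit$converged)
    expect_equal(fit$adjusted_r_squared, 1, tolerance = 1e-8)
  }
})

test_that("degenerate exponential data give beta near zero", {
  d <- seq(0, 8, 0.5)
  dat <- tibble::tibble(
    dose_kGy = d,
    survival = cfu_survival(d, survival_params(0.3, 0, 0.5)))
  fit <- suppressWarnings(fit_survival_model(dat))
  expect_equal(fit$params$alpha, 0.3, tolerance = 1e-3)
  expect_lt(fit$params$beta, 1e-3)
})

test_that("fit is invariant to row order and to duplication with halved weight", {
  p <- ctrl_params()
  d <- seq(0, 8, 0.5)
  s <- cfu_survival(d, p) * exp(withr::with_seed(5, stats::rnorm(17, 0, 0.05)))
  base <- tibble::tibble(dose_kGy = d, survival = pmin(s, 1))
  f1 <- fit_survival_model(base)
  shuffled <- base[withr::with_seed(6, sample(nrow(base))), ]
  f2 <- fit_survival_model(shuffled)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-8)
  # duplicating the 6 kGy record with half weight leaves the loss unchanged
  dup <- base
  dup$weight <- 1
  i <- which(dup$dose_kGy == 6)
  extra <- dup[i, ]
  dup$weight[i] <- 0.5
  extra$weight <- 0.5
  f3 <- fit_survival_model(dplyr::bind_rows(dup, extra) |>
                             dplyr::arrange(dose_kGy))
  expect_equal(tidy(f1)$estimate, tidy(f3)$estimate, tolerance = 1e-6)
})

test_that("joint refinement never fits worse than the frozen-alpha mode", {
  sc <- reference_scenarios()
  for (seed in c(2, 9, 31)) {
    a <- suppressWarnings(simulate_clonogenic_assay(sc$table1_control,
                                                    seed = seed))
    dat <- suppressWarnings(assay_to_dataset(a))
    f_ref <- suppressWarnings(fit_survival_model(dat, mode = "staged_refine"))
    f_pap <- suppressWarnings(fit_survival_model(dat, mode = "paper_staged"))
    expect_lte(f_ref$deviance, f_pap$deviance + 1e-12)
    expect_equal(f_pap$params$alpha, f_pap$alpha_asymptotic)
  }
})

test_that("dataset validation enforces the fitting preconditions", {
  expect_error(fit_survival_model(
    tibble::tibble(dose_kGy = c(0, 1, 2), survival = c(1, 0.9, 0.7))),
    "4 distinct doses")
  expect_error(survival_dataset(
    tibble::tibble(dose_kGy = c(1, 2), survival = c(0.9, 0.7))),
    "dose-0")
  expect_silent(survival_dataset(
    tibble::tibble(dose_kGy = c(1, 2), survival = c(0.9, 0.7)),
    pre_normalized = TRUE))
  expect_error(survival_dataset(
    tibble::tibble(dose_kGy = c(0, 1), survival = c(1, -0.2))),
    "survival")
  # replicate rows aggregate to per-dose means with SD and n
  rep_data <- tibble::tibble(dose_kGy = c(0, 0, 2, 2),
                             survival = c(1, 1, 0.6, 0.8))
  ds <- survival_dataset(rep_data)
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$survival[2], 0.7)
  expect_equal(ds$n[2], 2L)
})

test_that("tidy and glance expose the fit in broom layout", {
  fit <- fit_survival_model(noiseless_dataset(ctrl_params()))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("alpha", "beta", "delta"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("adj.r.squared", "converged", "mode", "nobs") %in%
                    names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
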