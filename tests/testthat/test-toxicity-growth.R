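toy_toxicity <- function() {
  # balanced 2 x 2 design, 2 replicates per cell, chosen for a clean
  # hand-computed decomposition
  tibble::tibble(
    concentration = rep(c(0, 0, 10, 10), each = 2),
    time_h = rep(c(3, 12, 3, 12), each = 2),
    replicate = rep(1:2, 4),
    cfu_count = c(100, 110, 90, 100, 60, 70, 40, 50)
  )
}

test_that("normalized_cfu divides by the matching-time control mean", {
  tab <- toy_toxicity()
  nc <- normalized_cfu(tab)
  expect_equal(nc$ratio[nc$time_h == 3], 65 / 105)
  expect_equal(nc$ratio[nc$time_h == 12], 45 / 95)
  # treated == control gives ratio 1
  same <- tab
  same$cfu_count[same$concentration == 10] <-
    same$cfu_count[same$concentration == 0]
  expect_equal(normalized_cfu(same)$ratio, c(1, 1))
  # all-zero treated counts give ratio 0
  zero <- tab
  zero$cfu_count[zero$concentration == 10] <- 0L
  expect_equal(normalized_cfu(zero)$ratio, c(0, 0))
  # first-order error propagation of the ratio SD
  r <- nc[nc$time_h == 3, ]
  sd_t <- stats::sd(c(60, 70)); sd_c <- stats::sd(c(100, 110))
  expect_equal(r$sd, (65 / 105) * sqrt((sd_t / 65)^2 + (sd_c / 105)^2),
               tolerance = 1e-12)
  expect_error(normalized_cfu(tab[tab$concentration > 0, ]), "control")
})

test_that("MIC is the lowest concentration crossing the reduction threshold", {
  r <- tibble::tibble(concentration = c(2.9, 4.8, 9.6, 19.2), time_h = 12,
                      ratio = c(0.95, 0.75, 0.42, 0.20), sd = 0.05, n = 3)
  expect_equal(minimal_inhibitory_concentration(r), 4.8)
  expect_equal(minimal_inhibitory_concentration(r, reduction_threshold = 0.5),
               9.6)
  high <- dplyr::mutate(r, ratio = pmax(ratio, 0.9))
  expect_message(mic <- minimal_inhibitory_concentration(high), "no tested")
  expect_true(is.na(mic))
  expect_error(minimal_inhibitory_concentration(r[0, ]), "non-empty")
})

test_that("MIC with a significance table also requires a Tukey hit", {
  sc <- reference_scenarios()
  tox <- simulate_toxicity_table(sc$toxicity_means, seed = 5)
  an <- two_factor_anova(tox)
  nc <- normalized_cfu(tox)
  mic_plain <- minimal_inhibitory_concentration(nc)
  mic_sig <- minimal_inhibitory_concentration(nc, significance = an)
  expect_equal(mic_plain, 4.8)
  expect_equal(mic_sig, 4.8)
})

test_that("two-factor ANOVA matches the hand-computed decomposition", {
  an <- two_factor_anova(toy_toxicity())
  tbl <- an$anova
  # hand decomposition: SS_conc 4050, SS_time 450, SS_int 50, SS_err 200
  expect_equal(tbl$sumsq[tbl$term == "concentration"], 4050)
  expect_equal(tbl$sumsq[tbl$term == "time"], 450)
  expect_equal(tbl$sumsq[tbl$term == "concentration:time"], 50)
  expect_equal(tbl$sumsq[tbl$term == "residuals"], 200)
  expect_equal(tbl$df, c(1, 1, 1, 4))
  expect_equal(tbl$statistic[1:3], c(81, 9, 1))
  # balanced design: components add up to the total, df to n - 1
  expect_equal(sum(tbl$sumsq),
               sum((toy_toxicity()$cfu_count - 77.5)^2), tolerance = 1e-9)
  expect_equal(sum(tbl$df), nrow(toy_toxicity()) - 1L)
})

test_that("ANOVA SS decomposition holds on random balanced designs", {
  for (seed in c(13, 29)) {
    tab <- withr::with_seed(seed, tibble::tibble(
      concentration = rep(rep(c(0, 5, 10), each = 3), 2),
      time_h = rep(c(3, 12), each = 9),
      replicate = rep(1:3, 6),
      cfu_count = stats::rpois(18, 150)
    ))
    tbl <- two_factor_anova(tab)$anova
    total <- sum((tab$cfu_count - mean(tab$cfu_count))^2)
    expect_equal(sum(tbl$sumsq), total, tolerance = 1e-9)
    expect_equal(sum(tbl$df), 17L)
  }
})

test_that("Tukey contrasts: identical groups give p ~ 1, adjustment only raises p", {
  tab <- toy_toxicity()
  # make both concentration groups identical within each time
  tab$cfu_count <- rep(c(100, 110, 90, 100), 2)
  an <- two_factor_anova(tab)
  expect_true(all(an$tukey$adj.p.value > 0.95))
  # adjusted p-values dominate the unadjusted ones from the same model
  an2 <- two_factor_anova(toy_toxicity())
  unadj <- summary(emmeans::contrast(
    emmeans::emmeans(an2$model, ~ concentration_f | time_f),
    method = "pairwise", adjust = "none"))$p.value
  expect_true(all(an2$tukey$adj.p.value >= unadj - 1e-12))
  expect_error(two_factor_anova(tab[tab$time_h == 3, ]), "2 levels")
})

test_that("null data flag no more concentration effects than the nominal rate", {
  hits <- sapply(1:40, function(seed) {
    tab <- withr::with_seed(seed, tibble::tibble(
      concentration = rep(rep(c(0, 5), each = 2), 2),
      time_h = rep(c(3, 12), each = 4),
      replicate = rep(1:2, 4),
      cfu_count = stats::rpois(8, 200)
    ))
    two_factor_anova(tab)$anova$p.value[1] < 0.05
  })
  expect_lt(mean(hits), 0.2)   # nominal 5%; generous bound for 40 draws
})

test_that("doubling time is exact on exponential data and scale-invariant", {
  tt <- seq(0, 600, 30)
  curve <- tibble::tibble(time_min = tt, od600 = 0.1 * 2^(tt / 144))
  expect_equal(as.numeric(doubling_time(curve)), 144, tolerance = 1e-9)
  scaled <- dplyr::mutate(curve, od600 = od600 * 10)
  expect_equal(as.numeric(doubling_time(scaled)),
               as.numeric(doubling_time(curve)), tolerance = 1e-12)
  # explicit window restricts the regression
  expect_equal(as.numeric(doubling_time(curve, window = c(120, 420))), 144,
               tolerance = 1e-9)
  flat <- tibble::tibble(time_min = tt, od600 = 0.3)
  expect_error(doubling_time(flat), "no growth")
  expect_error(doubling_time(curve[1:3, ]), "at least 4")
})

test_that("slowed-growth preset is recovered from a noisy curve", {
  g <- simulate_growth_curve(455, lag = 0, carrying_od = 10, od0 = 0.05,
                             times = seq(0, 1200, 120), noise_cv = 0.02,
                             seed = 1)
  expect_equal(as.numeric(doubling_time(g)), 455, tolerance = 15 / 455)
})
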