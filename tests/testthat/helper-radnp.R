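# shared fixtures: the two packaged parameter rows and noiseless datasets
ctrl_params <- function() survival_params(0.290, 1.9, 0.35, 4L)
ptnp_params <- function() survival_params(0.350, 1.9, 0.45, 4L)

noiseless_dataset <- function(params, doses = seq(0, 8, 0.5), label = "exact") {
  survival_dataset(
    tibble::tibble(dose_kGy = doses, survival = cfu_survival(doses, params)),
    label = label
  )
}

# randomised-but-reproducible parameter draws for property tests
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      alpha = stats::runif(n, 0.05, 1),
      beta = stats::runif(n, 0, 5),
      delta = stats::runif(n, 0.05, 2)
    )
  })
}
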