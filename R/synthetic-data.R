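#' Simulate a clonogenic survival assay
#'
#' Generates replicate colony counts for a dose series under the multi-target
#' survival model. Per dose and replicate the expected colony number is
#' `cells_plated * plating_efficiency * cfu_survival(dose)`; a lognormal
#' plate factor (mean 1, coefficient of variation `plating_lognormal_cv`)
#' models day-to-day plating variability, and the observed count is a Poisson
#' draw around that expectation. Survival fractions are computed by
#' normalising each count to the mean dose-0 count, either within the same
#' replicate series (default, mirroring assay practice of plating each
#' biological replicate with its own control) or pooled across replicates.
#'
#' The default design mirrors a gamma-irradiation study of a radioresistant
#' bacterium: doses 0-8 kGy in 0.5 kGy steps (dense enough to resolve the
#' survival shoulder near 3 kGy), triplicate plating, ~200 expected control
#' colonies per plate.
#'
#' @param params A [survival_params()] object for the generating curve.
#' @param doses Dose grid, kGy.
#' @param cells_plated Cells plated per dish (after dilution).
#' @param plating_efficiency Fraction of unirradiated cells that form
#'   colonies.
#' @param n_replicates Independent replicate series.
#' @param plating_lognormal_cv CV of the lognormal plate factor (0 disables).
#' @param normalize `"replicate"` (each series to its own dose-0 mean) or
#'   `"pooled"`.
#' @param seed Mandatory integer seed; the generator is fully reproducible.
#' @return Tibble with columns `dose_kGy`, `replicate`, `colonies`,
#'   `expected`, `survival`, plus attribute `"params"`.
#' @examples
#' simulate_clonogenic_assay(survival_params(0.29, 1.9, 0.35), seed = 1)
#' @export
simulate_clonogenic_assay <- function(params,
                                      doses = seq(0, 8, by = 0.5),
                                      cells_plated = 1000,
                                      plating_efficiency = 0.2,
                                      n_replicates = 3L,
                                      plating_lognormal_cv = 0.1,
                                      normalize = c("replicate", "pooled"),
                                      seed) {
  params <- as_survival_params(params)
  normalize <- match.arg(normalize)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for reproducibility", call. = FALSE)
  check_dose(doses)
  if (!any(doses == 0))
    stop("the dose grid must include 0 (normalisation plates)",
         call. = FALSE)
  stopifnot(cells_plated > 0, plating_efficiency > 0,
            plating_efficiency <= 1, n_replicates >= 1,
            plating_lognormal_cv >= 0)

  grid <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                             dose_kGy = sort(doses))
  mu <- cells_plated * plating_efficiency *
    cfu_survival(grid$dose_kGy, params)
  if (any(mu < 5))
    warning("expected colony count < 5 at some dose: counting noise ",
            "dominates the simulated survival there", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    if (plating_lognormal_cv > 0) {
      sdlog <- sqrt(log(1 + plating_lognormal_cv^2))
      plate_factor <- stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
    } else {
      plate_factor <- rep(1, nrow(grid))
    }
    grid$expected <- mu * plate_factor
    grid$colonies <- stats::rpois(nrow(grid), grid$expected)
  })

  ref <- if (normalize == "replicate") {
    grid |>
      dplyr::group_by(.data$replicate) |>
      dplyr::mutate(ref = mean(.data$colonies[.data$dose_kGy == 0])) |>
      dplyr::ungroup() |>
      dplyr::pull(.data$ref)
  } else {
    rep(mean(grid$colonies[grid$dose_kGy == 0]), nrow(grid))
  }
  if (any(ref == 0))
    stop("a replicate series drew zero colonies on its dose-0 plates; ",
         "increase `cells_plated`", call. = FALSE)
  grid$survival <- grid$colonies / ref
  out <- grid[c("dose_kGy", "replicate", "colonies", "expected", "survival")]
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Collapse a simulated assay to a fit-ready dose-response dataset
#'
#' Averages replicate survival fractions per dose into the
#' [survival_dataset()] layout used by [fit_survival_model()].
#'
#' @param assay Output of [simulate_clonogenic_assay()].
#' @param label Condition label.
#' @return A `survival_dataset` tibble.
#' @export
assay_to_dataset <- function(assay, label = "simulated") {
  stopifnot(is.data.frame(assay),
            all(c("dose_kGy", "survival") %in% names(assay)))
  survival_dataset(assay[c("dose_kGy", "survival")], label = label)
}

#' Simulate an OD600 growth curve
#'
#' Logistic growth after a lag phase, observed with multiplicative lognormal
#' noise: for `t > lag`,
#' `OD(t) = K * od0 * e^(r (t - lag)) / (K + od0 * (e^(r (t - lag)) - 1))`
#' with `r = ln 2 / doubling_time`, so the early exponential-phase log2 slope
#' is exactly `1 / doubling_time` when noise is zero.
#'
#' @param doubling_time Exponential-phase doubling time, minutes.
#' @param lag Lag duration, minutes (default 0).
#' @param carrying_od Carrying-capacity OD (plateau).
#' @param od0 Inoculum OD.
#' @param times Strictly increasing sampling times, minutes.
#' @param noise_cv CV of multiplicative lognormal measurement noise.
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @return Tibble with `time_min`, `od600`.
#' @examples
#' simulate_growth_curve(144, times = seq(0, 600, 30), noise_cv = 0)
#' @export
simulate_growth_curve <- function(doubling_time, lag = 0, carrying_od = 2,
                                  od0 = 0.1,
                                  times = seq(0, 1440, by = 30),
                                  noise_cv = 0.02, seed = NULL) {
  stopifnot(doubling_time > 0, lag >= 0, carrying_od > od0, od0 > 0,
            noise_cv >= 0)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (noise_cv > 0 && is.null(seed))
    stop("a `seed` is required when `noise_cv` > 0", call. = FALSE)
  r <- log(2) / doubling_time
  te <- pmax(times - lag, 0)
  g <- exp(r * te)
  od <- carrying_od * od0 * g / (carrying_od + od0 * (g - 1))
  if (noise_cv > 0) {
    od <- withr::with_seed(as.integer(seed), {
      sdlog <- sqrt(log(1 + noise_cv^2))
      od * stats::rlnorm(length(od), -sdlog^2 / 2, sdlog)
    })
  }
  tibble::tibble(time_min = times, od600 = od)
}

#' Simulate a concentration-by-time CFU toxicity table
#'
#' Control plates draw Poisson counts around `control_count_mean`; treated
#' plates draw Poisson counts around `ratio * control_count_mean`, where the
#' per-replicate ratio carries an additional normal between-replicate
#' component with the supplied SD (truncated at 0). This mirrors a toxicity
#' assay in which biological replicates vary around a condition mean that is
#' itself an unknown survival ratio.
#'
#' @param condition_means Data frame with columns `concentration`, `time_h`,
#'   `mean_ratio` (in `[0, 1.2]`) and optionally `sd` (between-replicate SD of
#'   the ratio, default 0).
#' @param control_count_mean Expected control colony count per plate.
#' @param n_replicates Replicates per condition (>= 2 for SDs to be defined;
#'   1 is allowed but flagged).
#' @param seed Integer seed.
#' @return Replicate-level tibble `concentration`, `time_h`, `replicate`,
#'   `cfu_count` including the concentration-0 control rows per time.
#' @export
simulate_toxicity_table <- function(condition_means,
                                    control_count_mean = 300,
                                    n_replicates = 3L,
                                    seed) {
  stopifnot(is.data.frame(condition_means),
            all(c("concentration", "time_h", "mean_ratio") %in%
                  names(condition_means)))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for reproducibility", call. = FALSE)
  if (any(condition_means$mean_ratio < 0 |
            condition_means$mean_ratio > 1.2))
    stop("`mean_ratio` must lie in [0, 1.2]", call. = FALSE)
  if (control_count_mean <= 0)
    stop("`control_count_mean` must be > 0", call. = FALSE)
  if (n_replicates < 2L)
    warning("with a single replicate per condition the SDs of the ",
            "normalised ratios are undefined", call. = FALSE)
  cm <- tibble::as_tibble(condition_means)
  if (!"sd" %in% names(cm)) cm$sd <- 0

  times <- unique(cm$time_h)
  ctrl <- tidyr::expand_grid(time_h = times,
                             replicate = seq_len(n_replicates))
  ctrl$concentration <- 0
  trt <- tidyr::expand_grid(
    cm[c("concentration", "time_h", "mean_ratio", "sd")],
    replicate = seq_len(n_replicates))
  withr::with_seed(as.integer(seed), {
    ctrl$cfu_count <- stats::rpois(nrow(ctrl), control_count_mean)
    rep_ratio <- pmax(stats::rnorm(nrow(trt), trt$mean_ratio, trt$sd), 0)
    trt$cfu_count <- stats::rpois(nrow(trt), rep_ratio * control_count_mean)
  })

  out <- dplyr::bind_rows(
    ctrl[c("concentration", "time_h", "replicate", "cfu_count")],
    trt[c("concentration", "time_h", "replicate", "cfu_count")]
  ) |>
    dplyr::arrange(.data$time_h, .data$concentration, .data$replicate)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Reference scenario bundle
#'
#' Packaged parameter sets and constants describing the study conditions the
#' generators emulate: the two fitted survival-parameter rows ("control" and
#' nanoparticle-loaded cells), the nanoparticle exposure series, the particle
#' and cell geometry used in the uptake arithmetic, and the toxicity/growth
#' presets.
#'
#' @return A named list with elements `table1_control`, `table1_ptnp`
#'   ([survival_params()]), `exposure` (tibble of particles-per-cell levels
#'   with their nominal mg/L concentrations), `particle` ([particle_spec()]),
#'   `cell` (volume nm^3, density cells/mL), `icpms` (measured mass,
#'   administered mass, cell count), `toxicity_means` (tibble for
#'   [simulate_toxicity_table()]) and `doubling_times_min`.
#' @examples
#' reference_scenarios()$table1_control
#' @export
reference_scenarios <- function() {
  list(
    table1_control = survival_params(0.290, 1.9, 0.35, 4L),
    table1_ptnp = survival_params(0.350, 1.9, 0.45, 4L),
    exposure = tibble::tibble(
      particles_per_cell = c(0, 9e5, 1.5e6, 3e6, 6e6),
      nominal_mg_per_L = c(0, 2.9, 4.8, 9.6, 19.2)
    ),
    particle = particle_spec(atoms_per_particle = 1000,
                             atomic_mass = PT_ATOMIC_MASS,
                             diameter = 2, particle_volume = 4.2),
    cell = list(volume_nm3 = 4.2e9, density_per_mL = 1e7),
    icpms = list(total_metal_mass_ug = 1.079, administered_mass_ug = 20,
                 n_cells = 7e8),
    toxicity_means = tibble::tibble(
      concentration = rep(c(2.9, 4.8, 9.6, 19.2), 2),
      time_h = rep(c(3, 12), each = 4),
      mean_ratio = c(0.97, 0.78, 0.42, 0.25, 0.95, 0.70, 0.18, 0.10),
      sd = c(0.05, 0.07, 0.08, 0.05, 0.05, 0.06, 0.03, 0.03)
    ),
    doubling_times_min = c(control = 144, high_np = 455)
  )
}
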