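check_toxicity_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("toxicity table must be a non-empty data frame", call. = FALSE)
  need <- c("concentration", "time_h", "cfu_count")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("toxicity table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(table$cfu_count < 0) || any(table$cfu_count != round(table$cfu_count)))
    stop("`cfu_count` must be non-negative integers", call. = FALSE)
  times <- unique(table$time_h)
  has_ctrl <- vapply(times, function(t)
    any(table$concentration == 0 & table$time_h == t), logical(1))
  if (!all(has_ctrl))
    stop("no concentration-0 control rows at time(s): ",
         paste(times[!has_ctrl], collapse = ", "), call. = FALSE)
  tibble::as_tibble(table)
}

#' Normalise CFU counts to the untreated control
#'
#' For every (concentration, incubation time) condition, divides the mean
#' treated colony count by the mean control (concentration 0) count at the
#' same time. The SD of the ratio is propagated to first order from the
#' replicate SDs of the two means:
#' `sd_ratio = ratio * sqrt((sd_t/mean_t)^2 + (sd_c/mean_c)^2)`.
#'
#' @param table Data frame with columns `concentration`, `time_h`,
#'   `cfu_count` (one row per replicate plate; a `replicate` column is
#'   allowed and ignored here).
#' @return Tibble with one row per treated condition: `concentration`,
#'   `time_h`, `ratio`, `sd`, `n`.
#' @export
normalized_cfu <- function(table) {
  table <- check_toxicity_table(table)
  stats_tbl <- table |>
    dplyr::group_by(.data$concentration, .data$time_h) |>
    dplyr::summarise(mean = mean(.data$cfu_count),
                     sd = stats::sd(.data$cfu_count),
                     n = dplyr::n(), .groups = "drop")
  ctrl <- stats_tbl |>
    dplyr::filter(.data$concentration == 0) |>
    dplyr::select("time_h", ctrl_mean = "mean", ctrl_sd = "sd")
  if (any(ctrl$ctrl_mean == 0))
    stop("control mean CFU is zero at some time: cannot normalise",
         call. = FALSE)
  stats_tbl |>
    dplyr::filter(.data$concentration > 0) |>
    dplyr::left_join(ctrl, by = "time_h") |>
    dplyr::mutate(
      ratio = .data$mean / .data$ctrl_mean,
      sd = .data$ratio * sqrt(
        (dplyr::coalesce(.data$sd, 0) / .data$mean)^2 +
          (dplyr::coalesce(.data$ctrl_sd, 0) / .data$ctrl_mean)^2)
    ) |>
    dplyr::select("concentration", "time_h", "ratio", "sd", "n") |>
    dplyr::arrange(.data$concentration, .data$time_h)
}

#' Minimal inhibitory concentration from normalised CFU ratios
#'
#' Returns the lowest tested concentration whose mean survival ratio drops
#' below `1 - reduction_threshold` at any incubation time (default: a > 20%
#' CFU reduction). When a Tukey pairwise table is supplied (see
#' [two_factor_anova()]), the drop must additionally be significant against
#' the control at `alpha_level` for that concentration.
#'
#' @param ratios Output of [normalized_cfu()] (or any data frame with
#'   `concentration`, `time_h`, `ratio`).
#' @param reduction_threshold Fractional CFU reduction that counts as
#'   inhibition (default 0.20).
#' @param significance Optional `anova_result` from [two_factor_anova()];
#'   when given, Tukey-adjusted significance vs. control is also required.
#' @param alpha_level Significance level for the Tukey requirement.
#' @return The MIC as a single concentration, or `NA` (with a message) when
#'   no tested concentration qualifies.
#' @examples
#' r <- tibble::tibble(concentration = c(2.9, 4.8, 9.6, 19.2), time_h = 12,
#'                     ratio = c(0.95, 0.75, 0.42, 0.20))
#' minimal_inhibitory_concentration(r)   # 4.8
#' @export
minimal_inhibitory_concentration <- function(ratios,
                                             reduction_threshold = 0.20,
                                             significance = NULL,
                                             alpha_level = 0.05) {
  if (!is.data.frame(ratios) || nrow(ratios) == 0)
    stop("`ratios` must be a non-empty data frame", call. = FALSE)
  stopifnot(all(c("concentration", "time_h", "ratio") %in% names(ratios)))
  hits <- ratios |>
    dplyr::filter(.data$ratio < 1 - reduction_threshold)
  if (!is.null(significance)) {
    sig <- significant_vs_control(significance, alpha_level)
    hits <- dplyr::semi_join(hits, sig, by = c("concentration", "time_h"))
  }
  if (nrow(hits) == 0) {
    message("no tested concentration reaches a ",
            round(100 * reduction_threshold), "% CFU reduction")
    return(NA_real_)
  }
  min(hits$concentration)
}

significant_vs_control <- function(anova_result, alpha_level) {
  stopifnot(inherits(anova_result, "anova_result"))
  anova_result$tukey |>
    dplyr::filter(.data$vs_control, .data$adj.p.value < alpha_level) |>
    dplyr::select("concentration", "time_h")
}

#' Doubling time from an OD600 growth curve
#'
#' Fits a least-squares line to `log2(OD)` against time over the exponential
#' window and reports `1 / slope` in minutes. With `window = "auto"` the
#' exponential phase is located as the longest contiguous run of at least
#' three points whose point-to-point log2 slopes all lie within 20% of that
#' run's median slope; an explicit `c(t_min, t_max)` window (minutes) may be
#' given instead.
#'
#' @param curve Data frame with strictly increasing `time_min` and positive
#'   `od600` columns (>= 4 points).
#' @param window `"auto"` or a length-2 numeric time interval in minutes.
#' @return Doubling time in minutes, with attributes `window` (time range
#'   used) and `n_points`.
#' @examples
#' tt <- seq(0, 600, 30)
#' doubling_time(tibble::tibble(time_min = tt, od600 = 0.1 * 2^(tt / 144)))
#' @export
doubling_time <- function(curve, window = "auto") {
  if (!is.data.frame(curve) ||
      !all(c("time_min", "od600") %in% names(curve)))
    stop("`curve` needs columns `time_min` and `od600`", call. = FALSE)
  if (nrow(curve) < 4L)
    stop("need at least 4 growth-curve points", call. = FALSE)
  if (any(diff(curve$time_min) <= 0))
    stop("`time_min` must be strictly increasing", call. = FALSE)
  if (any(curve$od600 <= 0))
    stop("`od600` must be positive", call. = FALSE)

  if (identical(window, "auto")) {
    idx <- auto_exponential_window(curve$time_min, curve$od600)
  } else {
    if (!is.numeric(window) || length(window) != 2L)
      stop("`window` must be \"auto\" or a numeric interval c(t0, t1)",
           call. = FALSE)
    idx <- which(curve$time_min >= min(window) & curve$time_min <= max(window))
  }
  if (length(idx) < 3L)
    stop("exponential window contains fewer than 3 points", call. = FALSE)
  sub <- curve[idx, ]
  if (all(diff(sub$od600) <= 0))
    stop("no growth: OD600 is non-increasing over the window", call. = FALSE)
  fit <- stats::lm(log2(od600) ~ time_min, data = sub)
  slope <- stats::coef(fit)[["time_min"]]
  if (slope <= 0)
    stop("no growth: log-slope is non-positive over the window",
         call. = FALSE)
  structure(1 / slope,
            window = range(sub$time_min), n_points = nrow(sub))
}

# longest run of >= 3 points whose local log2 slopes stay within 20% of the
# run's median local slope; lag and plateau phases are excluded by requiring
# the run's median slope to be at least half the steepest local slope (their
# slopes are mutually consistent but near zero)
auto_exponential_window <- function(time, od) {
  # 3-point moving average of log2(OD) stabilises the local slopes used for
  # window selection; the doubling-time regression itself uses the raw points
  lod <- log2(od)
  if (length(lod) >= 3L) {
    sm <- stats::filter(lod, rep(1 / 3, 3), sides = 2)
    lod[!is.na(sm)] <- sm[!is.na(sm)]
  }
  slopes <- diff(lod) / diff(time)
  n <- length(slopes)
  smax <- max(slopes)
  best <- integer(0)
  best_med <- -Inf
  if (n >= 2L && smax > 0) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        run <- slopes[i:j]
        med <- stats::median(run)
        if (med <= 0 || med < 0.5 * smax) next
        better <- (j - i + 2L) > length(best) ||
          ((j - i + 2L) == length(best) && med > best_med)
        if (all(abs(run - med) <= 0.2 * abs(med)) && better) {
          best <- i:(j + 1L)
          best_med <- med
        }
      }
    }
  }
  if (!length(best)) {
    # fall back to the steepest consecutive-triple window
    trip <- vapply(seq_len(max(n - 1L, 1L)), function(i)
      mean(slopes[i:min(i + 1L, n)]), numeric(1))
    i <- which.max(trip)
    best <- i:min(i + 2L, n + 1L)
  }
  best
}

#' Two-factor ANOVA with Tukey comparisons for a toxicity design
#'
#' Fixed-effects two-way ANOVA of colony counts with factors concentration
#' and incubation time plus their interaction, using type-II sums of squares
#' (which coincide with the textbook decomposition on balanced designs), and
#' Tukey HSD pairwise comparisons among concentration levels within each
#' incubation time (Tukey-Kramer on unbalanced cells, via the studentized
#' range distribution).
#'
#' @param table Replicate-level toxicity table (see [normalized_cfu()]);
#'   needs >= 2 levels per factor and >= 2 replicates per cell.
#' @param response Name of the response column (default `"cfu_count"`).
#' @return An object of class `anova_result`: a list with `anova` (tibble:
#'   term, sumsq, df, statistic, p.value, signif), `tukey` (tibble of
#'   pairwise concentration contrasts within time, with Tukey-adjusted
#'   p-values and a `vs_control` flag) and the underlying `model`.
#' @export
two_factor_anova <- function(table, response = "cfu_count") {
  if (!is.data.frame(table) || !response %in% names(table))
    stop("`table` must contain a `", response, "` column", call. = FALSE)
  need <- c("concentration", "time_h")
  if (!all(need %in% names(table)))
    stop("`table` needs `concentration` and `time_h` columns", call. = FALSE)
  df <- tibble::as_tibble(table)
  df$concentration_f <- factor(df$concentration)
  df$time_f <- factor(df$time_h)
  if (nlevels(df$concentration_f) < 2L || nlevels(df$time_f) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  cell_n <- dplyr::count(df, .data$concentration_f, .data$time_f)
  if (any(cell_n$n < 2L))
    stop("every (concentration, time) cell needs >= 2 replicates",
         call. = FALSE)

  form <- stats::as.formula(
    paste(response, "~ concentration_f * time_f"))
  model <- stats::aov(form, data = df)
  a2 <- car::Anova(model, type = 2)
  terms_map <- c("concentration_f" = "concentration",
                 "time_f" = "time",
                 "concentration_f:time_f" = "concentration:time",
                 "Residuals" = "residuals")
  anova_tbl <- tibble::tibble(
    term = unname(terms_map[rownames(a2)]),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`
  )
  anova_tbl$signif <- dplyr::case_when(
    is.na(anova_tbl$p.value) ~ "",
    anova_tbl$p.value < 0.01 ~ "**",
    anova_tbl$p.value < 0.05 ~ "*",
    TRUE ~ ""
  )

  emm <- emmeans::emmeans(model, ~ concentration_f | time_f)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  prs <- tibble::as_tibble(prs)
  split_levels <- function(contrast) {
    # emmeans writes "concentration_fA - concentration_fB"
    parts <- strsplit(gsub("concentration_f", "", contrast), " - ")
    do.call(rbind, lapply(parts, function(p) as.numeric(p)))
  }
  lv <- split_levels(prs$contrast)
  tukey <- tibble::tibble(
    level_1 = lv[, 1], level_2 = lv[, 2],
    time_h = as.numeric(as.character(prs$time_f)),
    estimate = prs$estimate,
    adj.p.value = prs$p.value
  )
  tukey$vs_control <- tukey$level_1 == 0 | tukey$level_2 == 0
  tukey$concentration <- ifelse(tukey$level_1 == 0, tukey$level_2,
                                tukey$level_1)
  tukey$signif <- dplyr::case_when(
    tukey$adj.p.value < 0.01 ~ "**",
    tukey$adj.p.value < 0.05 ~ "*",
    TRUE ~ ""
  )

  structure(list(anova = anova_tbl, tukey = tukey, model = model),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> two-factor design (concentration x time)\n")
  print(x$anova)
  cat("Tukey pairwise contrasts within time (vs-control rows flagged):\n")
  print(dplyr::filter(x$tukey, .data$vs_control))
  invisible(x)
}

#' @rdname tidy.radnp_fit
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) x$anova
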