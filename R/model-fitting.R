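#' Assemble and validate a dose-response survival dataset
#'
#' Normalises a data frame of clonogenic dose-response measurements into the
#' layout the fitting routines expect: one row per dose, sorted ascending,
#' with columns `dose_kGy`, `survival` and optionally `sd`, `n` and `weight`.
#' Replicate-level rows (repeated doses) are aggregated to their mean survival
#' with the replicate standard deviation and count. Survival values slightly
#' above 1 (a replicate outgrowing its control) are clipped to 1 with a
#' warning; values <= 0 or above 1.5 are rejected.
#'
#' @param data Data frame with numeric columns `dose_kGy` and `survival`
#'   (optionally `sd`, `n`, `weight`).
#' @param label Free-text condition name attached to the dataset.
#' @param pre_normalized Set `TRUE` to silence the check that a dose-0
#'   (normalisation) point is present.
#' @return A tibble of class `survival_dataset`, one row per distinct dose.
#' @export
survival_dataset <- function(data, label = "unnamed", pre_normalized = FALSE) {
  if (!is.data.frame(data))
    stop("`data` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c("dose_kGy", "survival"), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- tibble::as_tibble(data)
  check_dose(data$dose_kGy)
  s <- data$survival
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0))
    stop("`survival` must be finite and > 0", call. = FALSE)
  if (!"weight" %in% names(data)) data$weight <- 1
  replicated <- anyDuplicated(data$dose_kGy) > 0
  if (replicated) {
    data <- data |>
      dplyr::group_by(.data$dose_kGy) |>
      dplyr::summarise(
        sd = stats::sd(.data$survival),
        n = dplyr::n(),
        weight = sum(.data$weight),
        survival = mean(.data$survival),
        .groups = "drop"
      ) |>
      dplyr::select("dose_kGy", "survival", "sd", "n", "weight")
  } else {
    if (!"sd" %in% names(data)) data$sd <- NA_real_
    if (!"n" %in% names(data)) data$n <- NA_integer_
    data <- data[c("dose_kGy", "survival", "sd", "n", "weight")]
  }
  data <- dplyr::arrange(data, .data$dose_kGy)
  # clip after aggregation: a replicate outgrowing its control is ordinary
  # noise and must average with its siblings before the domain is enforced
  if (any(data$survival > 1)) {
    warning(sum(data$survival > 1),
            " mean survival value(s) > 1 clipped to 1", call. = FALSE)
    data$survival <- pmin(data$survival, 1)
  }
  if (!pre_normalized && !any(data$dose_kGy == 0))
    stop("dataset has no dose-0 record; pass `pre_normalized = TRUE` if the ",
         "survival values are already normalised", call. = FALSE)
  structure(data, class = c("survival_dataset", class(tibble::tibble())),
            label = label)
}

as_survival_dataset <- function(data, ...) {
  if (inherits(data, "survival_dataset")) data else survival_dataset(data, ...)
}

#' Invert colony-level survival to single-unit survival
#'
#' Algebraic inverse of the multi-target relation `s_cfu = 1 - (1 - s)^n`:
#' returns `1 - (1 - s_cfu)^(1/n)`. Needed so that the asymptotic exponential
#' form (which holds for the single-unit curve) can be fitted to CFU-level
#' observations.
#'
#' @param s_cfu CFU survival fraction(s) in (0, 1].
#' @param n_units Positive integer genome-unit count.
#' @return Single-unit survival fraction(s).
#' @export
invert_cfu_to_unit_survival <- function(s_cfu, n_units = 4L) {
  if (!is.numeric(s_cfu) || any(!is.finite(s_cfu)) ||
      any(s_cfu <= 0) || any(s_cfu > 1))
    stop("`s_cfu` must lie in (0, 1]", call. = FALSE)
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L)
    stop("`n_units` must be a positive integer", call. = FALSE)
  1 - (1 - s_cfu)^(1 / n_units)
}

default_dose_threshold <- function(dataset) {
  rng <- range(dataset$dose_kGy)
  mid <- mean(rng)
  ok <- dataset$dose_kGy >= mid & dataset$survival < 0.9
  if (!any(ok)) mid else min(dataset$dose_kGy[ok])
}

#' Asymptotic (high-dose) estimate of the DSB induction rate
#'
#' At doses where repair is saturated the single-unit survival is close to
#' `exp(-alpha*D)`, so `-ln S` is proportional to dose. This estimator
#' converts the CFU-level observations to single-unit survival, keeps the
#' high-dose subset (doses at or above `threshold` with survival < 1), and
#' fits the through-origin regression
#' `alpha-hat = sum(D_i * (-ln S_i)) / sum(D_i^2)`.
#'
#' The default threshold keeps doses in the upper half of the observed range
#' whose survival is below 0.9. Note the estimator is downward-biased whenever
#' the repair term has not fully decayed at the largest doses available; the
#' joint refinement stage of [fit_survival_model()] removes that bias.
#'
#' @param data Dose-response data (see [survival_dataset()]).
#' @param threshold Minimum dose (kGy) of the asymptotic subset; `NULL` for
#'   the adaptive default.
#' @param n_units Genome-unit exponent used in the CFU inversion.
#' @return Estimated alpha (kGy^-1) as a single number with attribute
#'   `"n_points"`.
#' @export
estimate_alpha_asymptotic <- function(data, threshold = NULL, n_units = 4L) {
  dataset <- as_survival_dataset(data)
  if (is.null(threshold)) threshold <- default_dose_threshold(dataset)
  sub <- dataset[dataset$dose_kGy >= threshold & dataset$dose_kGy > 0, ]
  if (any(sub$survival == 1)) {
    warning("excluding ", sum(sub$survival == 1),
            " record(s) with survival = 1 from the asymptotic subset",
            call. = FALSE)
    sub <- sub[sub$survival < 1, ]
  }
  if (nrow(sub) < 2L)
    stop("fewer than 2 usable records at doses >= ", signif(threshold, 4),
         " kGy: cannot estimate alpha asymptotically", call. = FALSE)
  s_unit <- invert_cfu_to_unit_survival(sub$survival, n_units)
  alpha <- sum(sub$dose_kGy * (-log(s_unit))) / sum(sub$dose_kGy^2)
  structure(alpha, n_points = nrow(sub), threshold = threshold)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) * (n - 1) / (n - n_params - 1)` with `R^2` the ordinary
#' coefficient of determination of `predicted` against `observed`. Computed on
#' whatever scale the caller supplies (the fitting routines use it on the loss
#' scale of the fit).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param n_params Number of free model parameters.
#' @return Adjusted R-squared (<= 1; can be negative).
#' @export
adjusted_r_squared <- function(observed, predicted, n_params) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  n <- length(observed)
  if (length(predicted) != n)
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  if (n < n_params + 2L)
    stop("need at least n_params + 2 observations", call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss <= .Machine$double.eps * n)
    stop("observations are constant: R-squared undefined", call. = FALSE)
  r2 <- 1 - sum((observed - predicted)^2) / tss
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

model_bounds <- function() {
  list(lower = c(alpha = 1e-8, beta = 0, delta = 0),
       upper = c(alpha = 10, beta = 50, delta = 10))
}

# residual vector on the configured loss scale; dose-0 rows are dropped from
# the log-scale loss (log 1 = 0 carries no information and a noisy replicate
# above 1 would leave the domain)
fit_residual_fun <- function(dataset, loss_scale, weights_mode, n_units) {
  keep <- if (loss_scale == "log") dataset$dose_kGy > 0 else
    rep(TRUE, nrow(dataset))
  d <- dataset$dose_kGy[keep]
  obs <- dataset$survival[keep]
  w <- dataset$weight[keep]
  if (weights_mode == "inverse_variance") {
    se <- dataset$sd[keep] / sqrt(dataset$n[keep])
    if (any(!is.finite(se)) || any(se <= 0))
      stop("`weights = \"inverse_variance\"` needs positive `sd` and `n` ",
           "columns on every fitted record", call. = FALSE)
    if (loss_scale == "log") se <- se / obs   # delta method for log(survival)
    w <- w / se^2
  }
  sw <- sqrt(w)
  obs_t <- if (loss_scale == "log") log(obs) else obs
  list(
    fn = function(p) {
      pred <- cfu_survival(d, survival_params(p[["alpha"]], p[["beta"]],
                                              p[["delta"]], n_units))
      pred_t <- if (loss_scale == "log") log(pred) else pred
      sw * (pred_t - obs_t)
    },
    dose = d, observed_t = obs_t, sqrt_w = sw, loss_scale = loss_scale
  )
}

run_lm <- function(res_fn, start, free, max_iterations, tol) {
  b <- model_bounds()
  wrapped <- function(pfree) {
    p <- start
    p[free] <- pfree
    res_fn(p)
  }
  fit <- minpack.lm::nls.lm(
    par = start[free], fn = wrapped,
    lower = b$lower[free], upper = b$upper[free],
    control = minpack.lm::nls.lm.control(
      maxiter = max_iterations, ftol = tol, ptol = tol)
  )
  p <- start
  p[free] <- fit$par
  list(par = p, deviance = fit$deviance, info = fit$info,
       message = fit$message, niter = fit$niter)
}

#' Fit the radiation-survival model to dose-response data
#'
#' Staged nonlinear least-squares estimation of `(alpha, beta, delta)`.
#' Stage 1 anchors `alpha` with the asymptotic high-dose estimator
#' ([estimate_alpha_asymptotic()]). Stage 2 holds `alpha` fixed and estimates
#' `(beta, delta)` by Levenberg-Marquardt least squares of the CFU-level model
#' against the observed survival at all doses. In mode `"paper_staged"` the
#' procedure stops there; in the default mode `"staged_refine"` the stage-2
#' solution seeds a joint refinement of all three parameters, which removes
#' the downward bias of the asymptotic alpha when the repair term has not
#' fully decayed within the measured dose range.
#'
#' Fitting is performed on `log(survival)` by default (variance stabilisation
#' for exponential decay); dose-0 records are excluded from the log-scale loss.
#' Standard errors come from the Gauss-Newton approximation
#' `(J'J)^-1 * s^2` at the solution, and the adjusted R-squared is evaluated
#' on the loss scale of the fit.
#'
#' @param data Dose-response data (see [survival_dataset()]); at least 4
#'   distinct doses.
#' @param mode `"staged_refine"` (default) or `"paper_staged"` (alpha frozen
#'   at its asymptotic estimate).
#' @param threshold High-dose threshold for stage 1 (kGy); `NULL` for the
#'   adaptive default.
#' @param loss_scale `"log"` (default) or `"linear"`.
#' @param weights `"none"` (default) or `"inverse_variance"` (requires `sd`
#'   and `n` columns).
#' @param n_units Genome-unit exponent (default 4).
#' @param max_iterations,tol Levenberg-Marquardt control.
#' @return An object of class `radnp_fit`; see [tidy.radnp_fit()],
#'   [glance.radnp_fit()] and [autoplot.radnp_fit()].
#' @examples
#' d <- tibble::tibble(dose_kGy = seq(0, 8, 0.5),
#'                     survival = cfu_survival(seq(0, 8, 0.5),
#'                                             survival_params(0.29, 1.9, 0.35)))
#' fit <- fit_survival_model(d)
#' tidy(fit)
#' @export
fit_survival_model <- function(data,
                               mode = c("staged_refine", "paper_staged"),
                               threshold = NULL,
                               loss_scale = c("log", "linear"),
                               weights = c("none", "inverse_variance"),
                               n_units = 4L,
                               max_iterations = 200L,
                               tol = 1e-12) {
  mode <- match.arg(mode)
  loss_scale <- match.arg(loss_scale)
  weights <- match.arg(weights)
  dataset <- as_survival_dataset(data)
  if (length(unique(dataset$dose_kGy)) < 4L)
    stop("need at least 4 distinct doses to fit the 3-parameter model",
         call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)

  alpha0 <- estimate_alpha_asymptotic(dataset, threshold, n_units)
  threshold_used <- attr(alpha0, "threshold")
  alpha0 <- as.numeric(alpha0)

  res <- fit_residual_fun(dataset, loss_scale, weights, n_units)

  # stage 2: (beta, delta) with alpha frozen; start grid guards against the
  # local minima the saturating repair term can create
  cond_bd <- function(alpha) {
    starts <- expand.grid(beta = c(0.5, 2, 5), delta = c(0.1, 0.5, 1.5))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      cand <- run_lm(res$fn,
                     c(alpha = alpha, beta = starts$beta[i],
                       delta = starts$delta[i]),
                     free = c("beta", "delta"), max_iterations, tol)
      if (is.null(best) || cand$deviance < best$deviance) best <- cand
    }
    best
  }
  stage2 <- cond_bd(alpha0)

  final <- stage2
  free <- c("beta", "delta")
  if (mode == "staged_refine") {
    free <- c("alpha", "beta", "delta")
    # alternate the two staged steps to a fixed point: the asymptotic alpha is
    # biased low whenever the repair term has not decayed at the top dose, so
    # re-estimating alpha conditional on (beta, delta) and iterating removes
    # that bias while keeping the search anchored in the staged basin (the
    # joint problem has a long weakly-identified ridge; a global search would
    # drift along it on noisy data)
    cur <- stage2
    for (it in seq_len(25L)) {
      a_step <- run_lm(res$fn, cur$par, free = "alpha", max_iterations, tol)
      bd_step <- cond_bd(a_step$par[["alpha"]])
      delta_a <- abs(a_step$par[["alpha"]] - cur$par[["alpha"]])
      cur <- bd_step
      if (delta_a < 1e-9) break
    }
    # local joint polish from the fixed point (single start, stays in-basin)
    final <- run_lm(res$fn, cur$par, free, max_iterations, tol)
    if (final$deviance > cur$deviance) final <- cur  # LM safeguard
  }

  converged <- final$info %in% 1:4
  if (!converged)
    warning("fit did not converge: ", final$message, call. = FALSE)
  b <- model_bounds()
  at_bounds <- names(which(
    abs(final$par[free] - b$lower[free]) < 1e-10 |
      abs(final$par[free] - b$upper[free]) < 1e-10))
  if (length(at_bounds))
    warning("parameter(s) pinned at bounds: ",
            paste(at_bounds, collapse = ", "), call. = FALSE)

  params <- survival_params(final$par[["alpha"]], final$par[["beta"]],
                            final$par[["delta"]], n_units)
  se <- gauss_newton_se(res$fn, final$par, free)

  pred_t <- res$fn(final$par) / res$sqrt_w + res$observed_t
  n_free <- length(free)
  adj_r2 <- adjusted_r_squared(res$observed_t, pred_t, n_free)
  residuals <- tibble::tibble(
    dose_kGy = res$dose,
    observed = res$observed_t,
    predicted = pred_t,
    residual = res$observed_t - pred_t
  )

  structure(
    list(params = params, std_errors = se, adjusted_r_squared = adj_r2,
         mode = mode, threshold = threshold_used, loss_scale = loss_scale,
         weights = weights, alpha_asymptotic = alpha0,
         converged = converged, info = final$info, niter = final$niter,
         deviance = final$deviance, at_bounds = at_bounds,
         residuals = residuals, data = dataset,
         label = attr(dataset, "label")),
    class = "radnp_fit"
  )
}

# numerical Jacobian of the residual vector; SEs via (J'J)^-1 * sigma^2
gauss_newton_se <- function(res_fn, par, free) {
  r0 <- res_fn(par)
  n <- length(r0); p <- length(free)
  J <- matrix(0, n, p, dimnames = list(NULL, free))
  for (j in free) {
    h <- max(1e-7, 1e-7 * abs(par[[j]]))
    pp <- par; pp[[j]] <- pp[[j]] + h
    pm <- par; pm[[j]] <- max(pm[[j]] - h, 0)
    J[, j] <- (res_fn(pp) - res_fn(pm)) / (pp[[j]] - pm[[j]])
  }
  sigma2 <- sum(r0^2) / max(n - p, 1)
  se <- c(alpha = NA_real_, beta = NA_real_, delta = NA_real_)
  cov <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (!is.null(cov)) se[free] <- sqrt(pmax(diag(cov), 0))
  se
}

#' @export
print.radnp_fit <- function(x, ...) {
  cat("<radnp_fit>", if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n",
      sep = "")
  cat(sprintf("  mode: %s | loss: %s | high-dose threshold: %g kGy\n",
              x$mode, x$loss_scale, x$threshold))
  est <- c(x$params$alpha, x$params$beta, x$params$delta)
  lab <- c("alpha [kGy^-1]", "beta", "delta [kGy^-1]")
  for (i in 1:3)
    cat(sprintf("  %-15s %8.4f  (se %.4g)\n", lab[i], est[i], x$std_errors[i]))
  cat(sprintf("  adj. R^2: %.4f | converged: %s | n doses: %d\n",
              x$adjusted_r_squared, x$converged, nrow(x$data)))
  invisible(x)
}

#' Tidy a fitted radiation-survival model
#'
#' @param x A `radnp_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy radnp_fit
#' @export
tidy.radnp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "delta"),
    estimate = c(x$params$alpha, x$params$beta, x$params$delta),
    std.error = unname(x$std_errors[c("alpha", "beta", "delta")])
  )
}

#' One-row fit summary
#'
#' @param x A `radnp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with fit diagnostics.
#' @method glance radnp_fit
#' @export
glance.radnp_fit <- function(x, ...) {
  tibble::tibble(
    adj.r.squared = x$adjusted_r_squared,
    deviance = x$deviance,
    converged = x$converged,
    mode = x$mode,
    loss_scale = x$loss_scale,
    threshold_kGy = x$threshold,
    alpha.asymptotic = x$alpha_asymptotic,
    nobs = nrow(x$data)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a fitted survival curve over the data
#'
#' Log-scale survival against dose with the fitted CFU-level curve.
#'
#' @param object A `radnp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radnp_fit
#' @export
autoplot.radnp_fit <- function(object, ...) {
  grid <- tibble::tibble(
    dose_kGy = seq(min(object$data$dose_kGy), max(object$data$dose_kGy),
                   length.out = 200)
  )
  grid$survival <- cfu_survival(grid$dose_kGy, object$params)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dose_kGy, y = .data$survival)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (kGy)", y = "CFU survival fraction",
                  title = object$label,
                  subtitle = sprintf(
                    "alpha = %.3f, beta = %.2f, delta = %.3f (adj R2 = %.3f)",
                    object$params$alpha, object$params$beta,
                    object$params$delta, object$adjusted_r_squared))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
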