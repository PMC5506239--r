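#' Survival-model parameter set
#'
#' Bundles the three rate parameters of the multi-target radiation-survival
#' model together with the genome-unit exponent. The model describes clonogenic
#' survival of cells carrying `n_units` genome copies: a cell survives if at
#' least one copy remains functional, so the colony-level survival is
#' \deqn{S_{cfu}(D) = 1 - (1 - S(D))^{n}}
#' with per-unit survival
#' \deqn{S(D) = \exp(-\alpha D \exp[-\beta \exp\{-\delta D\}]).}
#'
#' `alpha` (kGy^-1) is the induction rate of lethal double-strand breaks,
#' `beta` (dimensionless) the repair capacity that shields the genome at low
#' dose (producing the survival "shoulder"), and `delta` (kGy^-1) the rate at
#' which radiation inactivates the repair proteins themselves, so that at high
#' dose the curve collapses onto the pure exponential `exp(-alpha*D)`.
#'
#' @param alpha Double-strand-break induction rate, kGy^-1; must be > 0.
#' @param beta Repair capacity, dimensionless; must be >= 0.
#' @param delta Protein-inactivation rate, kGy^-1; must be >= 0.
#' @param n_units Positive integer; number of genome units (default 4, the
#'   value appropriate for a tetraploid-genome bacterium).
#' @return An object of class `survival_params` (a named list).
#' @examples
#' survival_params(0.290, 1.9, 0.35)
#' @export
survival_params <- function(alpha, beta, delta, n_units = 4L) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(delta),
            length(alpha) == 1L, length(beta) == 1L, length(delta) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a finite positive rate (kGy^-1), got ", alpha,
         call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be finite and >= 0, got ", beta, call. = FALSE)
  if (!is.finite(delta) || delta < 0)
    stop("`delta` must be finite and >= 0, got ", delta, call. = FALSE)
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L)
    stop("`n_units` must be a positive integer", call. = FALSE)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         delta = as.numeric(delta), n_units = n_units),
    class = "survival_params"
  )
}

#' @export
print.survival_params <- function(x, ...) {
  cat("<survival_params>\n")
  cat(sprintf("  alpha = %g kGy^-1 (DSB induction)\n", x$alpha))
  cat(sprintf("  beta  = %g (repair capacity)\n", x$beta))
  cat(sprintf("  delta = %g kGy^-1 (protein inactivation)\n", x$delta))
  cat(sprintf("  n_units = %d genome units\n", x$n_units))
  invisible(x)
}

#' @export
format.survival_params <- function(x, ...) {
  sprintf("(alpha=%g, beta=%g, delta=%g, n=%d)",
          x$alpha, x$beta, x$delta, x$n_units)
}

as_survival_params <- function(x) {
  if (inherits(x, "survival_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (all(c("alpha", "beta", "delta") %in% names(x)))
      return(survival_params(x$alpha, x$beta, x$delta,
                             x$n_units %||% 4L))
  }
  stop("cannot interpret object as survival_params", call. = FALSE)
}

check_dose <- function(dose) {
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("`dose` must be finite and >= 0 (kGy)", call. = FALSE)
  dose
}

#' Single genome-unit survival
#'
#' Survival probability of one genome unit at dose `D`:
#' `exp(-alpha * D * exp(-beta * exp(-delta * D)))`. At `D = 0` this is exactly
#' 1; for large `delta * D` the repair term dies away and the curve approaches
#' `exp(-alpha * D)`.
#'
#' @param dose Radiation dose in kGy; vectorised, each element >= 0.
#' @param params A [survival_params()] object.
#' @return Survival fraction(s) in (0, 1].
#' @examples
#' single_unit_survival(8, survival_params(0.290, 1.9, 0.35))
#' @export
single_unit_survival <- function(dose, params) {
  params <- as_survival_params(params)
  check_dose(dose)
  exp(-params$alpha * dose * exp(-params$beta * exp(-params$delta * dose)))
}

#' Colony-level (CFU) survival
#'
#' Survival measured by a clonogenic assay for a cell with `n_units` genome
#' copies: `1 - (1 - S)^n_units`, with `S` the single-unit survival. The cell
#' dies only when every copy is lost, which is what gives multi-genome
#' bacteria their pronounced survival shoulder.
#'
#' @inheritParams single_unit_survival
#' @return CFU survival fraction(s) in (0, 1]; strictly decreasing in dose.
#' @examples
#' cfu_survival(8, survival_params(0.290, 1.9, 0.35))   # ~0.418
#' @export
cfu_survival <- function(dose, params) {
  params <- as_survival_params(params)
  s <- single_unit_survival(dose, params)
  1 - (1 - s)^params$n_units
}

#' Closed-form approximations to the survival curve
#'
#' Two limiting forms valid when `delta * D` is large: the `first_order`
#' expansion `exp(-alpha*D*(1 - beta*exp(-delta*D)))` (the inner double
#' exponential linearised), and the `asymptotic` form `exp(-alpha*D)` in which
#' repair is fully inactivated. The asymptotic form is the basis of the staged
#' alpha estimator in [estimate_alpha_asymptotic()].
#'
#' @inheritParams single_unit_survival
#' @param order One of `"first_order"` or `"asymptotic"`.
#' @return Approximate single-unit survival fraction(s).
#' @examples
#' approximate_survival(8, survival_params(0.290, 1.9, 0.35), "asymptotic")
#' @export
approximate_survival <- function(dose, params,
                                 order = c("first_order", "asymptotic")) {
  params <- as_survival_params(params)
  check_dose(dose)
  order <- match.arg(order)
  switch(order,
    first_order = exp(-params$alpha * dose *
                        (1 - params$beta * exp(-params$delta * dose))),
    asymptotic  = exp(-params$alpha * dose)
  )
}

#' Invert the CFU survival curve for a target survival level
#'
#' Finds the unique dose at which the colony-level survival equals `target`.
#' Because the exponent `alpha*D*exp(-beta*exp(-delta*D))` is strictly
#' increasing in `D` for `alpha > 0`, the CFU curve is strictly decreasing and
#' the root is unique; it is located by bracketed root search on
#' `[0, dose_cap]`.
#'
#' @param params A [survival_params()] object.
#' @param target Survival fraction in (0, 1).
#' @param dose_cap Upper bracket for the search, kGy (default 100).
#' @param tol Absolute dose tolerance, kGy (default 1e-6).
#' @return Dose in kGy with `cfu_survival(dose, params) == target` within
#'   tolerance.
#' @examples
#' dose_at_survival(survival_params(0.290, 1.9, 0.35), 0.5)   # ~7.33 kGy
#' @export
dose_at_survival <- function(params, target, dose_cap = 100, tol = 1e-6) {
  params <- as_survival_params(params)
  if (!is.numeric(target) || length(target) != 1L ||
      !is.finite(target) || target <= 0 || target >= 1)
    stop("`target` must be a survival fraction strictly inside (0, 1)",
         call. = FALSE)
  f <- function(D) cfu_survival(D, params) - target
  if (f(dose_cap) > 0)
    stop("survival does not drop to ", target, " below the dose cap of ",
         dose_cap, " kGy; raise `dose_cap`", call. = FALSE)
  stats::uniroot(f, interval = c(0, dose_cap), tol = tol)$root
}

#' Sensitization enhancement ratio (SER)
#'
#' Ratio of the doses producing the same biological effect without and with a
#' sensitizer: `D_ref(level) / D_test(level)`, where each dose solves the CFU
#' survival curve for the given survival level (default 0.5, i.e. 50% CFU
#' reduction). Values above 1 indicate radio-enhancement by the test
#' condition.
#'
#' @param params_ref [survival_params()] for the reference (sensitizer-free)
#'   condition.
#' @param params_test [survival_params()] for the sensitized condition.
#' @param level Iso-effect survival fraction in (0, 1); default 0.5.
#' @param dose_cap,tol Passed to [dose_at_survival()].
#' @return Dimensionless dose ratio; 1 when the two parameter sets coincide.
#' @examples
#' sensitization_enhancement_ratio(
#'   survival_params(0.290, 1.9, 0.35),
#'   survival_params(0.350, 1.9, 0.45)
#' )
#' @export
sensitization_enhancement_ratio <- function(params_ref, params_test,
                                            level = 0.5,
                                            dose_cap = 100, tol = 1e-9) {
  dose_at_survival(params_ref, level, dose_cap, tol) /
    dose_at_survival(params_test, level, dose_cap, tol)
}

#' Fixed-dose amplification of radiation effect
#'
#' Relative survival reduction at a fixed dose caused by a sensitizer:
#' `(S_ref - S_test) / S_ref`. For the survivals printed for the 8 kGy gamma
#' exposure (0.37 without and 0.22 with nanoparticles) this gives ~0.405, the
#' ">40%" amplification headline figure.
#'
#' @param survival_ref Survival fraction of the reference condition, in (0, 1].
#' @param survival_test Survival fraction of the test condition, >= 0. Values
#'   above `survival_ref` are allowed (protection); the result is then
#'   negative and a warning is raised.
#' @return Fraction of the reference survival lost in the test condition.
#' @examples
#' amplification_at_dose(0.37, 0.22)   # ~0.405
#' @export
amplification_at_dose <- function(survival_ref, survival_test) {
  if (!is.numeric(survival_ref) || any(!is.finite(survival_ref)) ||
      any(survival_ref <= 0) || any(survival_ref > 1))
    stop("`survival_ref` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(survival_test) || any(!is.finite(survival_test)) ||
      any(survival_test < 0))
    stop("`survival_test` must be >= 0", call. = FALSE)
  out <- (survival_ref - survival_test) / survival_ref
  if (any(out < 0))
    warning("test survival exceeds reference survival: ",
            "negative amplification (protection)", call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
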