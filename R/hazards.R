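#' Monthly hazard curves
#'
#' A monthly hazard is a function of age in completed years returning a
#' per-month transition probability in \[0, 1\]. Two parameterizations are
#' provided: a constant probability and a Gompertz-type curve
#' `min(1, b * exp(theta * age))`, the standard shape for adult-onset
#' chronic-disease incidence and all-cause mortality.
#'
#' @param p Constant monthly probability in \[0, 1\].
#' @param b Gompertz baseline, `b >= 0` (monthly probability at age 0 before
#'   capping).
#' @param theta Gompertz log-slope per year of age.
#' @return An object of class `monthly_hazard`: a callable wrapper that is
#'   vectorized over age.
#' @examples
#' h <- hazard_gompertz(2.5e-6, 0.09)
#' hazard_at(h, c(40, 60, 80))
#' @name monthly_hazard
NULL

new_monthly_hazard <- function(fun, label) {
  stopifnot(is.function(fun), is.character(label))
  structure(list(fun = fun, label = label), class = "monthly_hazard")
}

#' @rdname monthly_hazard
#' @export
hazard_constant <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("constant hazard must be a single probability in [0, 1], got ",
         format(p), call. = FALSE)
  }
  force(p)
  new_monthly_hazard(function(age) rep(p, length(age)),
                     sprintf("constant(%g)", p))
}

#' @rdname monthly_hazard
#' @export
hazard_gompertz <- function(b, theta) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
    stop("Gompertz baseline b must be a single non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta)) {
    stop("Gompertz slope theta must be a single number", call. = FALSE)
  }
  force(b); force(theta)
  new_monthly_hazard(function(age) pmin(1, b * exp(theta * age)),
                     sprintf("gompertz(b=%g, theta=%g)", b, theta))
}

#' @rdname monthly_hazard
#' @param hazard A `monthly_hazard` object.
#' @param age Vector of ages in years.
#' @export
hazard_at <- function(hazard, age) {
  stopifnot(inherits(hazard, "monthly_hazard"))
  p <- hazard$fun(age)
  if (length(p) != length(age)) {
    stop("hazard function must be vectorized over age", call. = FALSE)
  }
  p
}

#' Scale a monthly hazard by a multiplier
#'
#' Used to express excess mortality in the ill state as a proportional
#' multiplier on healthy-state mortality; results are capped at 1.
#'
#' @param hazard A `monthly_hazard`.
#' @param multiplier Non-negative scale factor.
#' @return A new `monthly_hazard`.
#' @export
hazard_scaled <- function(hazard, multiplier) {
  stopifnot(inherits(hazard, "monthly_hazard"),
            is.numeric(multiplier), length(multiplier) == 1L, multiplier >= 0)
  f <- hazard$fun
  new_monthly_hazard(function(age) pmin(1, multiplier * f(age)),
                     sprintf("%g * %s", multiplier, hazard$label))
}

#' Hazard specification for the three-state illness-death process
#'
#' Bundles the three monthly hazards the generator and the analytic oracle
#' need: illness onset (healthy to ill), mortality while healthy, and
#' mortality while ill. Validation evaluates every hazard on the full age
#' grid 0--100 and rejects values outside \[0, 1\].
#'
#' @param illness `monthly_hazard` for healthy -> ill.
#' @param mortality_healthy `monthly_hazard` for healthy -> dead.
#' @param mortality_ill `monthly_hazard` for ill -> dead.
#' @return An object of class `hazard_spec`.
#' @examples
#' hz <- hazard_spec(
#'   illness           = hazard_gompertz(5e-5, 0.05),
#'   mortality_healthy = hazard_gompertz(2.5e-6, 0.09),
#'   mortality_ill     = hazard_scaled(hazard_gompertz(2.5e-6, 0.09), 2.5)
#' )
#' @export
hazard_spec <- function(illness, mortality_healthy, mortality_ill) {
  spec <- structure(
    list(illness = illness,
         mortality_healthy = mortality_healthy,
         mortality_ill = mortality_ill),
    class = "hazard_spec")
  validate_hazard_spec(spec)
  spec
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("Illness-death hazard specification (monthly probabilities)\n")
  cat("  illness onset:     ", x$illness$label, "\n")
  cat("  mortality healthy: ", x$mortality_healthy$label, "\n")
  cat("  mortality ill:     ", x$mortality_ill$label, "\n")
  invisible(x)
}

validate_hazard_spec <- function(spec, ages = 0:100) {
  stopifnot(inherits(spec, "hazard_spec"))
  for (nm in c("illness", "mortality_healthy", "mortality_ill")) {
    h <- spec[[nm]]
    if (!inherits(h, "monthly_hazard")) {
      stop("hazard_spec field '", nm, "' must be a monthly_hazard",
           call. = FALSE)
    }
    p <- hazard_at(h, ages)
    bad <- which(!is.finite(p) | p < 0 | p > 1)
    if (length(bad)) {
      stop("invalid hazard '", nm, "': value ", format(p[bad[1L]]),
           " outside [0, 1] at age ", ages[bad[1L]], call. = FALSE)
    }
  }
  invisible(spec)
}

#' Evaluate a hazard specification on the integer age grid
#'
#' @param spec A `hazard_spec`.
#' @param ages Integer ages; default 0--100.
#' @return A `data.frame` with columns `age`, `illness`,
#'   `mortality_healthy`, `mortality_ill` (monthly probabilities).
#' @export
hazard_table <- function(spec, ages = 0:100) {
  validate_hazard_spec(spec, ages)
  data.frame(
    age = as.integer(ages),
    illness = hazard_at(spec$illness, ages),
    mortality_healthy = hazard_at(spec$mortality_healthy, ages),
    mortality_ill = hazard_at(spec$mortality_ill, ages)
  )
}

#' Default hazards of the bundled synthetic study
#'
#' The package's worked examples, analysis scripts and validation suite all
#' simulate one fixed scenario: a common, high-incidence condition pair in an
#' adult population. Illness onset is Gompertz with monthly baseline 5e-5 and
#' slope 0.05 per year (about 1.2%/year incidence at age 60); healthy
#' mortality is Gompertz with monthly baseline 2.5e-6 and slope 0.09 (about
#' 0.7%/year at age 60, a life-table-like shape); ill-state mortality is 2.5
#' times healthy mortality, capped at 1.
#'
#' @return A `hazard_spec`.
#' @export
default_study_hazards <- function() {
  mh <- hazard_gompertz(2.5e-6, 0.09)
  hazard_spec(
    illness = hazard_gompertz(5e-5, 0.05),
    mortality_healthy = mh,
    mortality_ill = hazard_scaled(mh, 2.5)
  )
}
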