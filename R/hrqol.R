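#' Health-related quality-of-life trajectories
#'
#' An `hrqol_trajectory` is a piecewise-linear utility profile over the model
#' horizon, anchored at month 0 (baseline) and sampled at a set of knot times
#' in months (by default 6, 12, 18 and 24). Utilities live on the 0 (death)
#' to 1 (perfect health) scale. The time integral of the profile, in years,
#' is the pathway's QALY contribution.
#'
#' @param times knot times in months, strictly increasing, starting at 0.
#' @param utilities utility at each knot, each in \[0, 1\].
#' @param spec optional list recording the generating constructor and its
#'   parameters; kept so sensitivity analyses can perturb a parameter and
#'   rebuild the trajectory.
#'
#' @return An object of class `hrqol_trajectory`: a list with elements
#'   `times` (months) and `utilities`, with the generating `spec` (if any)
#'   stored as an attribute.
#' @export
#' @examples
#' tr <- hrqol_trajectory(c(0, 6, 12, 18, 24), c(0.62, 0.68, 0.74, 0.8, 0.8))
#' trapezoid_qaly(tr)
hrqol_trajectory <- function(times, utilities, spec = NULL) {
  stopifnot(length(times) == length(utilities), length(times) >= 2)
  if (times[1] != 0) {
    stop("trajectory must start at month 0 (baseline)", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("knot times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(utilities)) || any(utilities < 0) || any(utilities > 1)) {
    stop("utilities must be finite and in [0, 1]", call. = FALSE)
  }
  out <- structure(
    list(times = as.numeric(times), utilities = as.numeric(utilities)),
    class = "hrqol_trajectory"
  )
  attr(out, "spec") <- spec
  out
}

#' @export
print.hrqol_trajectory <- function(x, ...) {
  cat("<hrqol_trajectory> knots (months):",
      paste(x$times, collapse = ", "), "\n")
  cat("  utilities:", paste(format(x$utilities), collapse = ", "), "\n")
  cat("  QALY over horizon:", format(trapezoid_qaly(x)), "\n")
  invisible(x)
}

standard_knots <- function(horizon_months = 24) {
  seq(6, horizon_months, by = 6)
}

#' Integrate a utility trajectory into QALYs
#'
#' Applies the trapezoid rule between consecutive knots (baseline at month 0
#' included): each interval contributes its mean utility times its length in
#' years. For a piecewise-linear profile sampled at its own knots this
#' integral is exact.
#'
#' @param traj an [hrqol_trajectory()].
#' @return QALYs (years of perfect health) accumulated over the horizon.
#' @export
#' @examples
#' # immediate-surgery profile: linear rise to a 0.8 plateau at 18 months
#' trapezoid_qaly(make_linear_plateau(0.62, 0.8, 18)) # 1.465
trapezoid_qaly <- function(traj) {
  stopifnot(inherits(traj, "hrqol_trajectory"))
  u <- traj$utilities
  if (any(u < 0 | u > 1)) stop("utilities outside [0, 1]", call. = FALSE)
  dt_years <- diff(traj$times) / 12
  sum(dt_years * (u[-length(u)] + u[-1]) / 2)
}

#' Linear-rise-to-plateau trajectory (recovery after immediate surgery)
#'
#' Utility rises linearly from the baseline at month 0 to a plateau reached
#' at `plateau_month` and stays constant afterwards. With the default
#' parameters (baseline 0.62, plateau 0.8 at 18 months over a 24-month
#' horizon) this is the profile of a patient operated on promptly after
#' diagnosis.
#'
#' @param baseline utility at month 0.
#' @param plateau utility at and after `plateau_month`.
#' @param plateau_month month the plateau is reached; must be positive and
#'   at most `horizon`.
#' @param horizon horizon in months.
#' @return an [hrqol_trajectory()] sampled at the standard 6-month knots.
#' @export
make_linear_plateau <- function(baseline, plateau, plateau_month, horizon = 24) {
  stopifnot(baseline >= 0, baseline <= 1, plateau >= 0, plateau <= 1)
  if (plateau_month <= 0 || plateau_month > horizon) {
    stop("plateau_month must be in (0, horizon]", call. = FALSE)
  }
  knots <- standard_knots(horizon)
  u <- baseline + (plateau - baseline) * pmin(knots, plateau_month) / plateau_month
  hrqol_trajectory(
    c(0, knots), c(baseline, u),
    spec = list(type = "plateau", baseline = baseline, plateau = plateau,
                plateau_month = plateau_month, horizon = horizon)
  )
}

#' Linearly declining trajectory (needed surgery, not received)
#'
#' Utility declines by a fixed decrement per 6 months from the baseline,
#' floored at 0. Models patients with a loose implant who receive no surgery
#' (painkillers / watchful waiting only), whose quality of life erodes over
#' time.
#'
#' @param baseline utility at month 0.
#' @param step_per_6mo utility lost per 6-month interval (non-negative).
#' @param horizon horizon in months.
#' @return an [hrqol_trajectory()].
#' @export
make_linear_decline <- function(baseline, step_per_6mo, horizon = 24) {
  stopifnot(baseline >= 0, baseline <= 1)
  if (step_per_6mo < 0) stop("step_per_6mo must be >= 0", call. = FALSE)
  knots <- standard_knots(horizon)
  u <- pmax(0, baseline - step_per_6mo * knots / 6)
  hrqol_trajectory(
    c(0, knots), c(baseline, u),
    spec = list(type = "decline", baseline = baseline,
                step_per_6mo = step_per_6mo, horizon = horizon)
  )
}

#' Decline-then-recovery trajectory (surgery delayed)
#'
#' Utility declines as in [make_linear_decline()] until surgery at
#' `surgery_month`, then rises linearly to an adjusted maximum reached at the
#' horizon. The adjusted maximum defaults to `plateau - step_per_6mo`: the
#' recovery ceiling is lowered by one decline step to reflect the toll of the
#' delay. With the defaults this reproduces the profile of a patient whose
#' necessary surgery happens one year late.
#'
#' @param baseline utility at month 0.
#' @param step_per_6mo pre-surgery utility decrement per 6 months.
#' @param surgery_month month of surgery; must lie on the 6-month knot grid.
#' @param plateau the undelayed recovery plateau.
#' @param horizon horizon in months.
#' @param adjusted_max recovery ceiling actually reached at the horizon;
#'   defaults to `plateau - step_per_6mo`.
#' @return an [hrqol_trajectory()]. If `surgery_month == horizon` there is no
#'   post-surgery segment and the result equals the pure decline (a warning
#'   flags this degenerate case).
#' @export
make_delayed_surgery <- function(baseline, step_per_6mo, surgery_month,
                                 plateau, horizon = 24,
                                 adjusted_max = plateau - step_per_6mo) {
  stopifnot(baseline >= 0, baseline <= 1, plateau >= 0, plateau <= 1)
  if (step_per_6mo < 0) stop("step_per_6mo must be >= 0", call. = FALSE)
  knots <- standard_knots(horizon)
  if (!surgery_month %in% c(0, knots)) {
    stop("surgery_month must lie on the 6-month knot grid", call. = FALSE)
  }
  u_surgery <- max(0, baseline - step_per_6mo * surgery_month / 6)
  if (adjusted_max < u_surgery) {
    stop("recovery ceiling below utility at surgery", call. = FALSE)
  }
  spec <- list(type = "delayed", baseline = baseline,
               step_per_6mo = step_per_6mo, surgery_month = surgery_month,
               plateau = plateau, horizon = horizon,
               adjusted_max = adjusted_max)
  if (surgery_month >= horizon) {
    warning("surgery at or beyond the horizon: pure decline, no recovery",
            call. = FALSE)
    out <- make_linear_decline(baseline, step_per_6mo, horizon)
    attr(out, "spec") <- spec
    return(out)
  }
  u <- vapply(knots, function(t) {
    if (t <= surgery_month) {
      max(0, baseline - step_per_6mo * t / 6)
    } else {
      u_surgery + (adjusted_max - u_surgery) *
        (t - surgery_month) / (horizon - surgery_month)
    }
  }, numeric(1))
  hrqol_trajectory(c(0, knots), c(baseline, pmin(1, u)), spec = spec)
}

#' Constant-level trajectory (other treatment)
#'
#' Utility jumps from the baseline to a constant level held from the first
#' knot onward; models patients managed with non-surgical treatment whose
#' quality of life is stable.
#'
#' @param baseline utility at month 0.
#' @param level constant utility from the first knot to the horizon.
#' @param horizon horizon in months.
#' @return an [hrqol_trajectory()].
#' @export
make_constant_level <- function(baseline, level, horizon = 24) {
  knots <- standard_knots(horizon)
  hrqol_trajectory(
    c(0, knots), c(baseline, rep(level, length(knots))),
    spec = list(type = "constant", baseline = baseline, level = level,
                horizon = horizon)
  )
}

#' Rebuild a trajectory from its generating specification
#'
#' @param spec a list with a `type` field (`"plateau"`, `"decline"`,
#'   `"delayed"`, `"constant"`, or `"knots"`) and the matching constructor
#'   parameters. `"knots"` takes explicit `times`/`utilities`.
#' @return an [hrqol_trajectory()].
#' @export
build_profile <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$type))
  horizon <- spec$horizon %||% 24
  switch(
    spec$type,
    plateau = make_linear_plateau(spec$baseline, spec$plateau,
                                  spec$plateau_month, horizon),
    decline = make_linear_decline(spec$baseline, spec$step_per_6mo, horizon),
    delayed = make_delayed_surgery(
      spec$baseline, spec$step_per_6mo, spec$surgery_month, spec$plateau,
      horizon,
      adjusted_max = spec$adjusted_max %||% (spec$plateau - spec$step_per_6mo)
    ),
    constant = make_constant_level(spec$baseline, spec$level, horizon),
    knots = hrqol_trajectory(spec$times, spec$utilities, spec = spec),
    stop("unknown profile type: ", spec$type, call. = FALSE)
  )
}

#' Base-case HRQoL profile registry
#'
#' The four utility profiles attached to the decision-tree terminals:
#' * `immediate_surgery` — linear rise from 0.62 to a 0.8 plateau at
#'   18 months (QALY 1.465);
#' * `untreated_loosening` — needed surgery not received, utility declining
#'   0.0528 per 6 months (QALY 1.0288);
#' * `delayed_surgery` — decline until surgery at 12 months, then recovery to
#'   a delay-adjusted ceiling of 0.7472 (QALY 1.198);
#' * `other_treatment` — no loosening, constant 0.65 under conservative
#'   management (QALY 1.2925).
#'
#' All share a baseline utility of 0.62 at month 0.
#'
#' @param horizon horizon in months.
#' @return named list of [hrqol_trajectory()] objects.
#' @export
hrqol_profiles <- function(horizon = 24) {
  list(
    immediate_surgery   = make_linear_plateau(0.62, 0.8, 18, horizon),
    untreated_loosening = make_linear_decline(0.62, 0.0528, horizon),
    delayed_surgery     = make_delayed_surgery(0.62, 0.0528, 12, 0.8, horizon),
    other_treatment     = make_constant_level(0.62, 0.65, horizon)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
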