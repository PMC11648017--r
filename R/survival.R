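DAYS_PER_MONTH <- 30.44   # 365.25 / 12
DAYS_PER_YEAR <- 365.25

#' Model cycle grid
#'
#' The cohort is evaluated on an irregular cycle grid: a first cycle of 28
#' days (the 4-week ctDNA evaluation window) followed by 21-day cycles,
#' truncated at the horizon. The trailing partial cycle is dropped so every
#' cycle is full length; under the 5-year default this yields 86 cycles
#' covering 1813 of 1826.25 days.
#'
#' @param horizon_years Time horizon in years.
#' @param cycle1_days Length of the first cycle in days.
#' @param cycle_days Length of all subsequent cycles in days.
#' @return An object of class `cycle_grid` with elements `boundaries` (days,
#'   length `n_cycles + 1`), `intervals` (days) and `n_cycles`.
#' @examples
#' cycle_grid(5)$n_cycles # 86
#' @export
cycle_grid <- function(horizon_years = 5, cycle1_days = 28, cycle_days = 21) {
  stopifnot(horizon_years > 0, cycle1_days > 0, cycle_days > 0)
  horizon_days <- horizon_years * DAYS_PER_YEAR
  if (horizon_days <= cycle1_days)
    stop("horizon must exceed the first cycle")
  n <- 1L + floor((horizon_days - cycle1_days) / cycle_days)
  boundaries <- c(0, cycle1_days + cycle_days * (0:(n - 1L)))
  structure(list(boundaries = boundaries, intervals = diff(boundaries),
                 n_cycles = as.integer(n)),
            class = "cycle_grid")
}

#' Convert a survival median to a daily exponential hazard
#'
#' Assuming exponentially distributed event times, the hazard that puts the
#' median at `median` months is `log(2) / (median * 30.44)` per day.
#'
#' @param median Median in months, positive.
#' @return Hazard per day.
#' @export
median_to_rate <- function(median) {
  if (any(!is.finite(median)) || any(median <= 0))
    stop("median_to_rate requires median > 0")
  log(2) / (median * DAYS_PER_MONTH)
}

#' Split a cycle interval into cause-specific transition probabilities
#'
#' The PFS event hazard bundles progression and death; the death hazard
#' comes from overall survival. Within a cycle both hazards are treated as
#' constant competing risks: the total event probability
#' `1 - exp(-lambda_pfs * t)` is apportioned between progression and death
#' in proportion to their cause-specific hazards. This never produces
#' negative probabilities, unlike subtracting probabilities directly.
#'
#' @param lambda_pfs_event Daily hazard of any PFS event (progression or
#'   death); must be >= `lambda_death`.
#' @param lambda_death Daily hazard of death.
#' @param interval Cycle length in days.
#' @return Named list `p_prog`, `p_death`, `p_stay` summing to 1.
#' @export
cause_specific_cycle_probs <- function(lambda_pfs_event, lambda_death, interval) {
  if (any(lambda_death < 0) || any(lambda_pfs_event < 0))
    stop("hazards must be >= 0")
  if (any(lambda_death > lambda_pfs_event + 1e-12))
    stop("inconsistent survival inputs: death hazard exceeds PFS event hazard")
  sp <- split_competing(list(prog = pmax(lambda_pfs_event - lambda_death, 0),
                             death = lambda_death), interval)
  list(p_prog = sp$prog, p_death = sp$death, p_stay = sp$stay)
}

# general competing-risk split: constant cause-specific hazards over one
# interval; returns per-cause probabilities plus `stay`
split_competing <- function(lambdas, interval) {
  ltot <- Reduce(`+`, lambdas)
  p_event <- 1 - exp(-ltot * interval)
  frac <- ifelse(ltot > 0, p_event / ltot, 0)
  out <- lapply(lambdas, function(l) l * frac)
  out$stay <- 1 - p_event
  out
}

# daily hazard of `spec` averaged over [t0, t1) days since state entry
piecewise_mean_hazard <- function(spec, t0, t1) {
  if (spec$form == "exponential_median")
    return(rep(median_to_rate(spec$median), length(t0)))
  bp_days <- spec$breakpoints * DAYS_PER_MONTH
  haz_day <- spec$hazards / DAYS_PER_MONTH
  ends <- c(bp_days[-1], Inf)
  mapply(function(a, b) {
    overlap <- pmax(0, pmin(b, ends) - pmax(a, bp_days))
    uncovered <- b - a - sum(overlap)
    # beyond the last breakpoint the final hazard is extended
    sum(overlap * haz_day, uncovered * haz_day[length(haz_day)]) / (b - a)
  }, t0, t1)
}

#' Per-cycle hazards from a survival spec on a cycle grid
#'
#' For `exponential_median` the hazard is constant; for `piecewise_hazard`
#' each cycle receives the duration-weighted mean of the piecewise hazard
#' over that cycle's interval. A spec that does not cover the horizon has
#' its last hazard extended, with a warning.
#'
#' @param spec A [surv_spec()].
#' @param grid A [cycle_grid()]; cycle times are measured from state entry.
#' @return Numeric vector of daily hazards, one per cycle.
#' @export
piecewise_cycle_hazards <- function(spec, grid) {
  stopifnot(is_surv_spec(spec), inherits(grid, "cycle_grid"))
  n <- grid$n_cycles
  t0 <- grid$boundaries[seq_len(n)]
  t1 <- grid$boundaries[seq_len(n) + 1L]
  if (spec$form == "piecewise_hazard" && length(spec$breakpoints) > 1L) {
    last_start <- spec$breakpoints[length(spec$breakpoints)] * DAYS_PER_MONTH
    last_len <- diff(spec$breakpoints)[length(spec$breakpoints) - 1L] * DAYS_PER_MONTH
    if (max(t1) > last_start + last_len)
      warning("piecewise hazard spec does not cover the horizon; ",
              "extending the last hazard", call. = FALSE)
  }
  piecewise_mean_hazard(spec, t0, t1)
}

# per-cycle (lambda_pfs_event, lambda_death) daily hazards for a treatment
# line, measured from state entry on the given grid
line_cycle_hazards <- function(line, grid) {
  lam_death <- piecewise_cycle_hazards(line$os, grid)
  if (is.null(line$pfs)) {
    lam_pfs <- lam_death # no progression beyond death (BSC)
  } else {
    lam_pfs <- piecewise_cycle_hazards(line$pfs, grid)
  }
  if (any(lam_death > lam_pfs + 1e-12))
    stop("inconsistent survival inputs: OS hazard exceeds PFS event hazard")
  list(pfs = lam_pfs, death = lam_death)
}
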