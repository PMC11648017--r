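HALF_YEAR_DAYS <- 182.625  # 6 months, the earliest standard-of-care switch

#' State space of the expanded Markov model
#'
#' Seven health states expanded to 25: first-line ARPI; docetaxel as ten
#' 3-week tunnel sub-states plus a no-progression-after-docetaxel state;
#' cabazitaxel likewise; best supportive care; death. Tunnel sub-states
#' encode time on chemotherapy so that the usual 10-cycle course and
#' time-dependent hazards can be represented in a memoryless chain.
#'
#' @return Character vector of 25 state names in canonical order.
#' @export
state_space <- function() {
  c("ARPI", paste0("DOC_", 1:10), "DOC_NP",
    paste0("CAB_", 1:10), "CAB_NP", "BSC", "DEATH")
}

S_ARPI <- 1L
S_DOC <- 2:11
S_DOC_NP <- 12L
S_CAB <- 13:22
S_CAB_NP <- 23L
S_BSC <- 24L
S_DEATH <- 25L
N_STATES <- 25L

model_grid <- function(ps) {
  cycle_grid(ps$horizon_years, ps$cycle1_days, ps$cycle_days)
}

#' Annual discounting evaluated in days
#'
#' @param days_elapsed Days since model entry, >= 0.
#' @param annual_rate Annual discount rate, >= 0.
#' @return `(1 + annual_rate)^(-days_elapsed / 365.25)`.
#' @examples
#' discount_factor(365.25, 0.04) # 1/1.04
#' @export
discount_factor <- function(days_elapsed, annual_rate) {
  if (any(days_elapsed < 0) || any(annual_rate < 0))
    stop("discount_factor requires non-negative days and rate")
  (1 + annual_rate)^(-days_elapsed / DAYS_PER_YEAR)
}

# in-state grid used for chemotherapy tunnels: 10 treatment cycles plus one
# slot whose hazards persist in the no-progression state
tunnel_grid <- function(cycle_days) {
  structure(list(boundaries = cycle_days * (0:11),
                 intervals = rep(cycle_days, 11L), n_cycles = 11L),
            class = "cycle_grid")
}

subcohort_hazards <- function(sc, ps, grid) {
  tg <- tunnel_grid(ps$cycle_days)
  list(
    arpi = line_cycle_hazards(ps$lines[[sc$arpi_surv_line]], grid),
    doc = line_cycle_hazards(ps$lines[[sc$doc_line]], tg),
    cab = line_cycle_hazards(ps$lines[[sc$cab_line]], tg),
    bsc_death = line_cycle_hazards(ps$lines$bsc, tg)$death[1L],
    mu_bsc = ps$bsc_entry_rate_per_day
  )
}

build_P <- function(hz, interval, arpi_pfs, arpi_death, forced, hold_active) {
  P <- matrix(0, N_STATES, N_STATES, dimnames = list(state_space(), state_space()))
  lam_prog_arpi <- arpi_pfs - arpi_death
  if (lam_prog_arpi < -1e-12)
    stop("negative ARPI progression hazard after competing-risk conversion")
  lam_prog_arpi <- max(lam_prog_arpi, 0)

  sp <- split_competing(list(prog = lam_prog_arpi, death = arpi_death,
                             bsc = hz$mu_bsc), interval)
  P[S_ARPI, S_DEATH] <- sp$death
  P[S_ARPI, S_BSC] <- sp$bsc
  if (forced) {
    P[S_ARPI, S_DOC[1]] <- sp$prog + sp$stay
  } else if (hold_active) {
    P[S_ARPI, S_ARPI] <- sp$stay + sp$prog
  } else {
    P[S_ARPI, S_DOC[1]] <- sp$prog
    P[S_ARPI, S_ARPI] <- sp$stay
  }

  for (i in 1:11) {
    from <- if (i <= 10) S_DOC[i] else S_DOC_NP
    to_stay <- if (i < 10) S_DOC[i + 1] else S_DOC_NP
    lam_p <- max(hz$doc$pfs[i] - hz$doc$death[i], 0)
    sp <- split_competing(list(prog = lam_p, death = hz$doc$death[i],
                               bsc = hz$mu_bsc), interval)
    P[from, S_CAB[1]] <- sp$prog
    P[from, S_DEATH] <- sp$death
    P[from, S_BSC] <- sp$bsc
    P[from, to_stay] <- P[from, to_stay] + sp$stay
  }
  for (i in 1:11) {
    from <- if (i <= 10) S_CAB[i] else S_CAB_NP
    to_stay <- if (i < 10) S_CAB[i + 1] else S_CAB_NP
    lam_p <- max(hz$cab$pfs[i] - hz$cab$death[i], 0)
    sp <- split_competing(list(prog = lam_p, death = hz$cab$death[i],
                               bsc = hz$mu_bsc), interval)
    P[from, S_BSC] <- sp$prog + sp$bsc  # no active line after cabazitaxel
    P[from, S_DEATH] <- sp$death
    P[from, to_stay] <- P[from, to_stay] + sp$stay
  }
  p_death_bsc <- 1 - exp(-hz$bsc_death * interval)
  P[S_BSC, S_DEATH] <- p_death_bsc
  P[S_BSC, S_BSC] <- 1 - p_death_bsc
  P[S_DEATH, S_DEATH] <- 1

  if (any(P < 0)) stop("negative transition probability after conversion")
  P
}

hold_boundary_day <- function(grid) {
  idx <- which(grid$boundaries >= HALF_YEAR_DAYS)
  if (length(idx)) grid$boundaries[idx[1]] else Inf
}

#' Build the transition matrix for one cycle
#'
#' Assembles the row-stochastic 25 x 25 matrix governing one model cycle for
#' a given sub-cohort: cause-specific competing-risk conversion of the ARPI,
#' docetaxel, cabazitaxel and best-supportive-care hazards, tunnel
#' advancement, the standard-of-care 6-month progression hold, and the
#' forced week-4 switch of ctDNA-flagged patients.
#'
#' @param cycle_index Cycle number (1-based) on the model grid.
#' @param params A `cea_params` object.
#' @param subcohort A sub-cohort definition from [build_soc_arm()] or
#'   [build_ctdna_arm()].
#' @return A 25 x 25 row-stochastic matrix with named dimensions.
#' @export
build_transition_matrix <- function(cycle_index, params, subcohort) {
  grid <- model_grid(params)
  stopifnot(cycle_index >= 1, cycle_index <= grid$n_cycles)
  hz <- subcohort_hazards(subcohort, params, grid)
  t1 <- grid$boundaries[cycle_index + 1L]
  hold_active <- isTRUE(subcohort$hold) && t1 < hold_boundary_day(grid)
  forced <- !is.na(subcohort$forced_switch_cycle) &&
    cycle_index == subcohort$forced_switch_cycle
  build_P(hz, grid$intervals[cycle_index], hz$arpi$pfs[cycle_index],
          hz$arpi$death[cycle_index], forced, hold_active)
}

# one matrix per distinct regime (interval length, ARPI hazards, hold phase,
# forced-switch cycle); exponential inputs collapse 86 cycles to <= 4 regimes
build_matrix_set <- function(sc, ps, grid) {
  hz <- subcohort_hazards(sc, ps, grid)
  n <- grid$n_cycles
  t1 <- grid$boundaries[-1]
  hold_active <- isTRUE(sc$hold) & t1 < hold_boundary_day(grid)
  forced <- !is.na(sc$forced_switch_cycle) &
    seq_len(n) == sc$forced_switch_cycle
  key <- paste(grid$intervals, signif(hz$arpi$pfs, 12), signif(hz$arpi$death, 12),
               hold_active, forced)
  uk <- unique(key)
  mats <- lapply(uk, function(k) {
    c1 <- match(k, key)
    build_P(hz, grid$intervals[c1], hz$arpi$pfs[c1], hz$arpi$death[c1],
            forced[c1], hold_active[c1])
  })
  list(index = match(key, uk), matrices = mats)
}

## ---- rewards ---------------------------------------------------------------

ae_expected_cost <- function(line) {
  if (!length(line$ae_events)) return(0)
  sum(vapply(line$ae_events,
             function(ev) d_mean(ev$prob) * d_mean(ev$cost), numeric(1)))
}

state_utilities <- function(sc, ps) {
  u <- numeric(N_STATES)
  u[S_ARPI] <- d_mean(ps$lines[[sc$arpi_cost_line]]$utility)
  u_doc <- sc$doc_utility %||% d_mean(ps$lines[[sc$doc_line]]$utility)
  u[c(S_DOC, S_DOC_NP)] <- u_doc
  u[c(S_CAB, S_CAB_NP)] <- d_mean(ps$lines[[sc$cab_line]]$utility)
  u[S_BSC] <- d_mean(ps$lines$bsc$utility)
  u
}

# EUR per cycle by state and cost category, charged at cycle start
state_cycle_costs <- function(sc, ps) {
  z <- numeric(N_STATES)
  drug <- z; admin <- z; visits <- z; bsc <- z
  n_doc <- min(10, ps$lines[[sc$doc_line]]$max_cycles)
  n_cab <- min(10, ps$lines[[sc$cab_line]]$max_cycles)
  drug[S_ARPI] <- d_mean(ps$lines[[sc$arpi_cost_line]]$drug_cost_per_cycle)
  admin[S_ARPI] <- d_mean(ps$lines[[sc$arpi_cost_line]]$admin_cost_per_cycle)
  drug[S_DOC[seq_len(n_doc)]] <- d_mean(ps$lines[[sc$doc_line]]$drug_cost_per_cycle)
  admin[S_DOC[seq_len(n_doc)]] <- d_mean(ps$lines[[sc$doc_line]]$admin_cost_per_cycle)
  drug[S_CAB[seq_len(n_cab)]] <- d_mean(ps$lines[[sc$cab_line]]$drug_cost_per_cycle)
  admin[S_CAB[seq_len(n_cab)]] <- d_mean(ps$lines[[sc$cab_line]]$admin_cost_per_cycle)
  visits[-S_DEATH] <- d_mean(ps$visit_cost_per_cycle)
  bsc[S_BSC] <- d_mean(ps$bsc_cost_per_cycle)
  list(drug = drug, administration = admin, visits_diagnostics = visits,
       bsc = bsc)
}

# one-off charges on entering a treatment line: expected adverse-event
# management cost plus work-up diagnostics
entry_costs <- function(sc, ps) {
  diag <- d_mean(ps$diagnostic_cost)
  list(arpi = ae_expected_cost(ps$lines[[sc$arpi_cost_line]]) + diag,
       doc = ae_expected_cost(ps$lines[[sc$doc_line]]) + diag,
       cab = ae_expected_cost(ps$lines[[sc$cab_line]]) + diag)
}

cost_categories <- function() {
  c("drug", "administration", "visits_diagnostics", "adverse_events",
    "ctdna_assay", "bsc")
}

## ---- cohort evolution ------------------------------------------------------

run_subcohort <- function(sc, ps, grid = model_grid(ps)) {
  n <- grid$n_cycles
  ms <- build_matrix_set(sc, ps, grid)
  trace <- matrix(0, n + 1L, N_STATES, dimnames = list(NULL, state_space()))
  trace[1L, S_ARPI] <- 1
  inflow_doc <- numeric(n)
  inflow_cab <- numeric(n)
  occ <- trace[1L, ]
  for (cyc in seq_len(n)) {
    P <- ms$matrices[[ms$index[cyc]]]
    inflow_doc[cyc] <- sum(occ * P[, S_DOC[1]])
    inflow_cab[cyc] <- sum(occ * P[, S_CAB[1]])
    occ <- as.numeric(occ %*% P)
    trace[cyc + 1L, ] <- occ
  }

  t0 <- grid$boundaries[seq_len(n)]
  t1 <- grid$boundaries[-1L]
  d <- grid$intervals
  df_e <- discount_factor(t0, ps$discount_rate_effects)
  df_c <- discount_factor(t0, ps$discount_rate_costs)
  occ0 <- trace[seq_len(n), , drop = FALSE]  # state-start occupancy valuation

  u <- state_utilities(sc, ps)
  alive <- 1 - occ0[, S_DEATH]
  ly_cyc <- alive * d / DAYS_PER_YEAR
  qaly_cyc <- as.numeric(occ0 %*% u) * d / DAYS_PER_YEAR

  cc <- state_cycle_costs(sc, ps)
  ec <- entry_costs(sc, ps)
  df_c_end <- discount_factor(t1, ps$discount_rate_costs)
  cost_cyc <- matrix(0, n, length(cost_categories()),
                     dimnames = list(NULL, cost_categories()))
  cost_cyc[, "drug"] <- as.numeric(occ0 %*% cc$drug)
  cost_cyc[, "administration"] <- as.numeric(occ0 %*% cc$administration)
  cost_cyc[, "visits_diagnostics"] <- as.numeric(occ0 %*% cc$visits_diagnostics)
  cost_cyc[, "bsc"] <- as.numeric(occ0 %*% cc$bsc)
  # adverse events + diagnostics charged to the flow entering each line
  ae_cyc <- ec$doc * inflow_doc + ec$cab * inflow_cab
  assay_pp <- ps$ctdna_n_samples * d_mean(ps$ctdna_cost_per_sample)
  alive_28 <- 1 - trace[2L, S_DEATH]
  assay_undisc <- if (isTRUE(sc$assay)) assay_pp * alive_28 else 0

  undisc <- colSums(cost_cyc)
  undisc["adverse_events"] <- sum(ae_cyc) + ec$arpi
  undisc["ctdna_assay"] <- assay_undisc

  cost_cyc <- cost_cyc * df_c
  cost_cyc[, "adverse_events"] <- ae_cyc * df_c_end
  cost_cyc[1L, "adverse_events"] <- cost_cyc[1L, "adverse_events"] + ec$arpi
  if (isTRUE(sc$assay))
    cost_cyc[1L, "ctdna_assay"] <- assay_pp * alive_28 *
      discount_factor(grid$boundaries[2L], ps$discount_rate_costs)

  costs_disc <- colSums(cost_cyc)
  res <- list(
    life_years = sum(ly_cyc * df_e), life_years_undisc = sum(ly_cyc),
    qalys = sum(qaly_cyc * df_e), qalys_undisc = sum(qaly_cyc),
    costs = costs_disc, cost_total = sum(costs_disc),
    costs_undisc = undisc, cost_total_undisc = sum(undisc),
    trace = trace, cycle_costs = cost_cyc,
    cycle_qalys = qaly_cyc * df_e, grid = grid)
  class(res) <- "arm_result"
  res
}

weight_results <- function(results, weights) {
  stopifnot(length(results) == length(weights))
  agg <- results[[1L]]
  num <- c("life_years", "life_years_undisc", "qalys", "qalys_undisc",
           "costs", "cost_total", "costs_undisc", "cost_total_undisc",
           "trace", "cycle_costs", "cycle_qalys")
  for (f in num) agg[[f]] <- agg[[f]] * weights[1L]
  if (length(results) > 1L) {
    for (j in 2:length(results)) {
      for (f in num) agg[[f]] <- agg[[f]] + results[[j]][[f]] * weights[j]
    }
  }
  agg
}

#' Run one strategy arm through the cohort engine
#'
#' Evolves every sub-cohort of the arm over the cycle grid by repeated
#' vector-matrix products from an initial cohort fully occupying the ARPI
#' state, and aggregates the weighted discounted/undiscounted life-years,
#' QALYs and disaggregated costs. No half-cycle correction is applied:
#' occupancy is valued, and discounting evaluated, at cycle start.
#'
#' @param arm A `strategy_arm` from [build_soc_arm()] or [build_ctdna_arm()].
#' @param params A `cea_params` object.
#' @return An `arm_result`: life-years, QALYs (discounted and not), costs by
#'   category, the aggregated occupancy trace, and per-cycle ledgers.
#' @export
run_arm <- function(arm, params) {
  grid <- model_grid(params)
  res <- lapply(arm$subcohorts, run_subcohort, ps = params, grid = grid)
  out <- weight_results(res, vapply(arm$subcohorts, `[[`, numeric(1), "weight"))
  out$arm <- arm$label
  check_arm_result(out, params)
  out
}

#' Run a strategy arm by label
#'
#' Convenience wrapper building the arm from the parameter set and running
#' it: `run_cohort(params, "ctdna_guided")` is
#' `run_arm(build_ctdna_arm(params), params)`.
#'
#' @param params A `cea_params` object.
#' @param arm `"standard_of_care"` or `"ctdna_guided"`.
#' @return An `arm_result`.
#' @export
run_cohort <- function(params, arm = c("standard_of_care", "ctdna_guided")) {
  arm <- match.arg(arm)
  builder <- if (arm == "standard_of_care") build_soc_arm else build_ctdna_arm
  run_arm(builder(params), params)
}

check_arm_result <- function(res, ps) {
  rs <- rowSums(res$trace)
  if (any(abs(rs - 1) > 1e-9))
    stop("cohort trace lost mass: max deviation ", max(abs(rs - 1)))
  if (any(diff(res$trace[, S_DEATH]) < -1e-12))
    stop("death occupancy must be nondecreasing")
  invisible(res)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result %s>\n", x$arm %||% "subcohort"))
  cat(sprintf("  life-years %.4f (undisc %.4f) | QALYs %.4f (undisc %.4f)\n",
              x$life_years, x$life_years_undisc, x$qalys, x$qalys_undisc))
  cat(sprintf("  total cost EUR %.2f (undisc %.2f)\n",
              x$cost_total, x$cost_total_undisc))
  bc <- paste(sprintf("%s %.0f", names(x$costs), x$costs), collapse = ", ")
  cat("  by category:", bc, "\n")
  invisible(x)
}

#' Export the cohort trace as a long data frame
#'
#' @param res An `arm_result`.
#' @return A `data.frame` with one row per cycle per state: `cycle`,
#'   `day` (cycle-start day), `state`, `occupancy`.
#' @export
trace_table <- function(res) {
  tr <- res$trace
  n <- nrow(tr)
  data.frame(cycle = rep(0:(n - 1L), times = ncol(tr)),
             day = rep(res$grid$boundaries[seq_len(n)], times = ncol(tr)),
             state = rep(colnames(tr), each = n),
             occupancy = as.vector(tr))
}
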