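test_that("transition matrices are row-stochastic with the declared topology", {
  ps <- generate_parameter_set("base_like")
  A <- allowed_transitions()
  arms <- list(build_soc_arm(ps), build_ctdna_arm(ps))
  for (arm in arms) {
    for (sc in arm$subcohorts) {
      for (cyc in c(1L, 2L, 9L, 40L, 86L)) {
        P <- build_transition_matrix(cyc, ps, sc)
        expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
        expect_true(all(P >= 0))
        expect_true(all(P[!A] == 0))
        expect_equal(unname(P["DEATH", ]),
                     as.numeric(state_space() == "DEATH"))
      }
    }
  }
})

test_that("zero hazards leave only tunnel advancement", {
  ps <- toy_params(bsc_entry_rate_per_day = 0)
  for (nm in names(ps$lines)) {
    if (!is.null(ps$lines[[nm]]$pfs)) ps$lines[[nm]]$pfs$median <- 1e9
    ps$lines[[nm]]$os$median <- 1e9
  }
  sc <- build_ctdna_arm(ps)$subcohorts[[2]]  # durable: no hold, no switch
  P <- build_transition_matrix(5L, ps, sc)
  expect_equal(P["ARPI", "ARPI"], 1, tolerance = 1e-6)
  expect_equal(P["DOC_3", "DOC_4"], 1, tolerance = 1e-6)
  expect_equal(P["DOC_10", "DOC_NP"], 1, tolerance = 1e-6)
  expect_equal(P["CAB_7", "CAB_8"], 1, tolerance = 1e-6)
  expect_equal(P["CAB_NP", "CAB_NP"], 1, tolerance = 1e-6)
  expect_equal(P["BSC", "BSC"], 1, tolerance = 1e-6)
})

test_that("the ARPI row reproduces the cause-specific conversion", {
  ps <- toy_params(bsc_entry_rate_per_day = 0)
  sc <- build_soc_arm(ps)$subcohorts[[1]]  # abiraterone, hold active early
  lam_pfs <- median_to_rate(10)
  lam_death <- median_to_rate(24)
  pr <- cause_specific_cycle_probs(lam_pfs, lam_death, 21)
  P <- build_transition_matrix(20L, ps, sc)  # beyond the 6-month hold
  expect_equal(P["ARPI", "DOC_1"], pr$p_prog, tolerance = 1e-12)
  expect_equal(P["ARPI", "DEATH"], pr$p_death, tolerance = 1e-12)
  expect_equal(P["ARPI", "ARPI"], pr$p_stay, tolerance = 1e-12)
})

test_that("discounting follows the annual convention", {
  expect_equal(discount_factor(0, 0.04), 1)
  expect_equal(discount_factor(365.25, 0.04), 1 / 1.04, tolerance = 1e-12)
  expect_equal(discount_factor(1826.25, 0.015), 1.015^-5, tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.04), "non-negative")
})

test_that("a single-risk chain matches the closed-form geometric series", {
  # ARPI -> DEATH only: equal PFS/OS medians kill the progression hazard
  ps <- toy_params(arpi_abi_share = 1, bsc_entry_rate_per_day = 0)
  ps$lines$abiraterone$pfs$median <- 12
  ps$lines$abiraterone$os$median <- 12
  res <- run_cohort(ps, "standard_of_care")
  g <- cycle_grid(2)
  lam <- median_to_rate(12)
  t0 <- g$boundaries[seq_len(g$n_cycles)]
  surv <- exp(-lam * t0)
  ly_oracle <- sum(surv * g$intervals / 365.25 * (1.015)^(-t0 / 365.25))
  expect_equal(res$life_years, ly_oracle, tolerance = 1e-9)
  expect_equal(res$qalys, 0.8 * ly_oracle, tolerance = 1e-9)
  # only ARPI and DEATH ever occupied
  expect_true(all(res$trace[, setdiff(colnames(res$trace),
                                      c("ARPI", "DEATH"))] == 0))
})

test_that("occupancy is conserved and death is absorbing over the horizon", {
  for (profile in c("base_like", "stress")) {
    ps <- generate_parameter_set(profile)
    for (arm in c("standard_of_care", "ctdna_guided")) {
      res <- run_cohort(ps, arm)
      expect_lt(max(abs(rowSums(res$trace) - 1)), 1e-12)
      expect_true(all(res$trace >= 0 & res$trace <= 1))
      expect_true(all(diff(res$trace[, "DEATH"]) >= -1e-15))
      expect_lte(res$qalys, res$life_years)
      expect_lte(res$life_years, ps$horizon_years)
      expect_lte(res$life_years, res$life_years_undisc)
      expect_lte(res$qalys, res$qalys_undisc)
      expect_lte(res$cost_total, res$cost_total_undisc)
    }
  }
})

test_that("tunnel states respect time-on-treatment", {
  ps <- generate_parameter_set("base_like")
  res <- run_cohort(ps, "ctdna_guided")
  # earliest docetaxel entry is cycle 2; DOC_NP reachable 10 cycles later
  expect_true(all(res$trace[1:11, "DOC_NP"] == 0))
  expect_gt(res$trace[13, "DOC_NP"], 0)
  # cabazitaxel unreachable before a docetaxel course can progress
  expect_true(all(res$trace[1:2, c(paste0("CAB_", 1:10), "CAB_NP")] == 0))
})

test_that("raising a death hazard weakly lowers life-years and QALYs", {
  ps <- toy_params()
  worse <- ps
  worse$lines$docetaxel$os$median <- 9  # vs 18
  for (arm in c("standard_of_care", "ctdna_guided")) {
    a <- run_cohort(ps, arm)
    b <- run_cohort(worse, arm)
    expect_lte(b$life_years, a$life_years)
    expect_lte(b$qalys, a$qalys)
  }
})

test_that("zero discounting and unit utilities collapse the identities", {
  ps <- toy_params(discount_rate_costs = 0, discount_rate_effects = 0)
  res <- run_cohort(ps, "ctdna_guided")
  expect_equal(res$life_years, res$life_years_undisc, tolerance = 1e-12)
  expect_equal(res$qalys, res$qalys_undisc, tolerance = 1e-12)
  expect_equal(res$cost_total, res$cost_total_undisc, tolerance = 1e-12)

  ps2 <- toy_params()
  for (nm in names(ps2$lines)) ps2$lines[[nm]]$utility <- dist_spec("fixed", 1)
  res2 <- run_cohort(ps2, "standard_of_care")
  expect_equal(res2$qalys, res2$life_years, tolerance = 1e-12)
})

test_that("the cohort engine matches the microsimulation on a toy model", {
  ps <- toy_params()
  res <- run_cohort(ps, "ctdna_guided")
  ms <- microsim_oracle(ps, "ctdna_guided", 40000, seed = 17)
  expect_lt(abs(ms$mean_life_years - res$life_years), 3 * ms$se_life_years)
  expect_lt(abs(ms$mean_qalys - res$qalys), 3 * ms$se_qalys)
  expect_lt(abs(ms$mean_cost - res$cost_total), 3 * ms$se_cost)
})

test_that("trace export is tidy and complete", {
  ps <- toy_params()
  res <- run_cohort(ps, "standard_of_care")
  tab <- trace_table(res)
  expect_equal(nrow(tab), nrow(res$trace) * 25)
  expect_equal(sort(unique(tab$state)), sort(state_space()))
  expect_equal(sum(tab$occupancy[tab$cycle == 0]), 1)
})
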