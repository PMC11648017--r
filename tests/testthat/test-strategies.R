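test_that("degenerate ARPI mixtures collapse to single sub-cohorts", {
  ps <- toy_params(arpi_abi_share = 1)
  arm <- build_soc_arm(ps)
  expect_length(arm$subcohorts, 1)
  expect_equal(arm$subcohorts[[1]]$arpi_surv_line, "abiraterone")
  arm_i <- build_ctdna_arm(ps)
  expect_equal(sum(vapply(arm_i$subcohorts, `[[`, numeric(1), "weight")), 1)
})

test_that("standard of care holds progression for six months", {
  ps <- generate_parameter_set("base_like")
  res <- run_cohort(ps, "standard_of_care")
  doc_cols <- c(paste0("DOC_", 1:10), "DOC_NP")
  g <- res$grid
  before <- g$boundaries < 182.625
  expect_true(all(res$trace[before, doc_cols] == 0))
  # flow lands exactly at the first boundary >= 182.625 days (day 196)
  first_on <- which(g$boundaries >= 182.625)[1]
  expect_equal(g$boundaries[first_on], 196)
  expect_gt(res$trace[first_on, "DOC_1"], 0)
})

test_that("arm results are affine in the ARPI share", {
  ps <- generate_parameter_set("base_like")
  r0 <- run_cohort(set_param(ps, "arpi_abi_share", 0), "ctdna_guided")
  r1 <- run_cohort(set_param(ps, "arpi_abi_share", 1), "ctdna_guided")
  rh <- run_cohort(ps, "ctdna_guided")  # share 0.5
  expect_equal(rh$qalys, (r0$qalys + r1$qalys) / 2, tolerance = 1e-9)
  expect_equal(rh$cost_total, (r0$cost_total + r1$cost_total) / 2,
               tolerance = 1e-9)
  expect_equal(rh$life_years, (r0$life_years + r1$life_years) / 2,
               tolerance = 1e-9)
})

test_that("flagged patients reach docetaxel at the end of cycle 1", {
  ps <- toy_params(bsc_entry_rate_per_day = 0, durable_hold = TRUE)
  res <- run_cohort(ps, "ctdna_guided")
  flag <- 0.4
  surv_d <- function(med_pfs, med_os) {
    lam_pfs <- median_to_rate(med_pfs); lam_d <- median_to_rate(med_os)
    p_event <- 1 - exp(-lam_pfs * 28)
    1 - p_event * lam_d / lam_pfs  # survivors of the 28-day cycle
  }
  expected <- flag * (0.5 * surv_d(10, 24) + 0.5 * surv_d(12, 26))
  expect_equal(unname(res$trace[2, "DOC_1"]), expected, tolerance = 1e-12)
})

test_that("with no flagged patients the arm is SOC on durable curves plus assay", {
  ps <- toy_params(durable_hold = TRUE)
  ps$ctdna_flag_fraction <- dist_spec("fixed", 0)
  int <- run_cohort(ps, "ctdna_guided")
  # reference: standard of care whose ARPI curves are the durable curves
  ref <- ps
  for (nm in c("abiraterone", "enzalutamide")) {
    ref$lines[[nm]]$pfs <- ps$lines$arpi_durable_responder$pfs
    ref$lines[[nm]]$os <- ps$lines$arpi_durable_responder$os
  }
  soc_ref <- run_cohort(ref, "standard_of_care")
  expect_equal(int$qalys, soc_ref$qalys, tolerance = 1e-12)
  expect_equal(int$life_years, soc_ref$life_years, tolerance = 1e-12)
  expect_equal(int$cost_total - int$costs[["ctdna_assay"]],
               soc_ref$cost_total, tolerance = 1e-9)
  expect_gt(int$costs[["ctdna_assay"]], 0)
})

test_that("assay cost is three samples for every week-4 survivor", {
  ps <- generate_parameter_set("base_like")
  res <- run_cohort(ps, "ctdna_guided")
  alive_28 <- unname(1 - res$trace[2, "DEATH"])
  expected <- 3 * 350 * alive_28 * discount_factor(28, 0.04)
  expect_equal(res$costs[["ctdna_assay"]], expected, tolerance = 1e-9)
  soc <- run_cohort(ps, "standard_of_care")
  expect_equal(soc$costs[["ctdna_assay"]], 0)
})

test_that("iNMB is exactly linear in the ctDNA price", {
  ps <- generate_parameter_set("base_like")
  inmb_at <- function(price)
    run_cea(set_param(ps, "ctdna_cost_per_sample", price))$inmb
  v <- vapply(c(0, 175, 350), inmb_at, numeric(1))
  expect_equal(v[1] - v[2], v[2] - v[3], tolerance = 1e-8)
  # slope: n_samples x discounted week-4 survivor fraction
  res <- run_cohort(ps, "ctdna_guided")
  alive_28 <- unname(1 - res$trace[2, "DEATH"])
  expect_equal((v[2] - v[3]) / 175, 3 * alive_28 * discount_factor(28, 0.04),
               tolerance = 1e-9)
})

test_that("arms share all machinery apart from the switch rules", {
  ps <- toy_params(durable_hold = TRUE)
  ps$flags <- list(durable_uses_trial_curves = TRUE)
  soc <- build_soc_arm(ps)
  int <- build_ctdna_arm(ps)
  # durable sub-cohorts then generate the exact SOC transition matrices
  durable <- Filter(function(sc) is.na(sc$forced_switch_cycle),
                    int$subcohorts)
  for (k in seq_along(durable)) {
    for (cyc in c(1L, 5L, 20L)) {
      expect_equal(build_transition_matrix(cyc, ps, durable[[k]]),
                   build_transition_matrix(cyc, ps, soc$subcohorts[[k]]))
    }
  }
  # switcher matrices differ from SOC only in the ARPI row
  sw <- int$subcohorts[[1]]
  P_sw <- build_transition_matrix(5L, ps, sw)
  P_soc <- build_transition_matrix(5L, ps, soc$subcohorts[[1]])
  expect_equal(P_sw[-1, ], P_soc[-1, ])
})

test_that("invalid test characteristics are rejected", {
  ps <- toy_params()
  ps$ctdna_ppv <- list(kind = "fixed", mean = 1.4, se = 0)
  class(ps$ctdna_ppv) <- "dist_spec"
  expect_error(build_ctdna_arm(ps), "ctdna_ppv")
})
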