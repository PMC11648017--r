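#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param dc Incremental cost (intervention minus comparator), EUR.
#' @param de Incremental effect, QALYs.
#' @return List with `value` (EUR/QALY; `NA` when `de == 0`) and `label`:
#'   `"icer"` (north-east quadrant), `"dominant"` (cheaper and more
#'   effective), `"dominated"` (costlier and less effective),
#'   `"cost_saving_less_effective"` (south-west), or `"undefined"`.
#' @examples
#' icer(12169, 0.186)
#' @export
icer <- function(dc, de) {
  if (de == 0) return(list(value = NA_real_, label = "undefined"))
  label <- if (de > 0 && dc >= 0) "icer"
  else if (de > 0) "dominant"
  else if (dc > 0) "dominated"
  else "cost_saving_less_effective"
  list(value = dc / de, label = label)
}

#' Incremental net monetary benefit
#'
#' `wtp * de - dc`; positive values favour the intervention at the stated
#' willingness-to-pay threshold.
#'
#' @param dc Incremental cost, EUR.
#' @param de Incremental effect, QALYs.
#' @param wtp Willingness to pay, EUR per QALY, >= 0.
#' @return EUR.
#' @examples
#' inmb(12169, 0.186, 80000)
#' @export
inmb <- function(dc, de, wtp) {
  if (wtp < 0) stop("inmb requires wtp >= 0")
  wtp * de - dc
}

#' Deterministic cost-effectiveness analysis
#'
#' Runs both strategy arms at the parameter point estimates and derives the
#' incremental results.
#'
#' @param params A `cea_params` object.
#' @return A `cea_result`: per-arm discounted cost/QALYs/life-years, deltas,
#'   ICER (with dominance label) and iNMB at `params$wtp`.
#' @export
run_cea <- function(params) {
  soc <- run_cohort(params, "standard_of_care")
  int <- run_cohort(params, "ctdna_guided")
  dc <- int$cost_total - soc$cost_total
  de <- int$qalys - soc$qalys
  structure(list(
    soc = soc, intervention = int,
    dc = dc, de = de, dly = int$life_years - soc$life_years,
    icer = icer(dc, de), inmb = inmb(dc, de, params$wtp),
    wtp = params$wtp), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> ctDNA-guided vs standard of care\n")
  cat(sprintf("  SOC:  cost %10.2f  QALY %.4f  LY %.4f\n",
              x$soc$cost_total, x$soc$qalys, x$soc$life_years))
  cat(sprintf("  ctDNA: cost %10.2f  QALY %.4f  LY %.4f\n",
              x$intervention$cost_total, x$intervention$qalys,
              x$intervention$life_years))
  cat(sprintf("  dC = %.2f, dE = %.4f, ICER = %s, iNMB@%.0f = %.2f\n",
              x$dc, x$de,
              if (x$icer$label == "icer") sprintf("%.2f", x$icer$value)
              else x$icer$label,
              x$wtp, x$inmb))
  invisible(x)
}

psa_iter_seed <- function(seed, i) (as.numeric(seed) + i) %% 2147483647

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the parameter distributions: each iteration
#' draws one parameter set ([sample_parameters()], common random parameters
#' shared by both arms within the iteration), runs both arms, and records
#' (cost, QALY) pairs. The mean ICER is the ratio of mean incremental costs
#' to mean incremental effects; 95\% intervals are 2.5th/97.5th percentile
#' order statistics. Iteration seeds follow the documented counter scheme
#' `(seed + i) mod (2^31 - 1)`, so any subset is reproducible.
#'
#' @param params A `cea_params` object.
#' @param n Number of iterations (the analysis default is 5000).
#' @param seed Master seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return A `psa_result` with the per-iteration draws, mean ICER, percentile
#'   intervals, probability of cost-effectiveness at `params$wtp`, and CEAC.
#' @export
run_psa <- function(params, n = 5000L, seed = 1L,
                    wtp_grid = seq(0, 200000, by = 1000)) {
  stopifnot(n >= 1)
  cols <- c("cost_soc", "qaly_soc", "cost_int", "qaly_int")
  draws <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  failed <- 0L
  for (i in seq_len(n)) {
    ok <- tryCatch({
      psi <- sample_parameters(params, psa_iter_seed(seed, i))
      soc <- run_cohort(psi, "standard_of_care")
      int <- run_cohort(psi, "ctdna_guided")
      draws[i, ] <- c(soc$cost_total, soc$qalys, int$cost_total, int$qalys)
      TRUE
    }, error = function(e) {
      message("PSA iteration ", i, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failed <- failed + 1L
  }
  draws <- as.data.frame(draws[stats::complete.cases(draws), , drop = FALSE])
  draws$dc <- draws$cost_int - draws$cost_soc
  draws$de <- draws$qaly_int - draws$qaly_soc
  draws$inmb <- params$wtp * draws$de - draws$dc

  q95 <- function(x) stats::quantile(x, c(0.025, 0.975), type = 1, names = FALSE)
  res <- structure(list(
    n_iterations = n, n_failed = failed, seed = seed, wtp = params$wtp,
    draws = draws,
    mean = vapply(draws, mean, numeric(1)),
    ci = vapply(draws[cols], q95, numeric(2)),
    mean_icer = icer(mean(draws$dc), mean(draws$de)),
    prob_cost_effective = mean(draws$inmb > 0)), class = "psa_result")
  res$ceac <- ceac(res, wtp_grid)
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with a
#' positive incremental net monetary benefit. Computed on the same iteration
#' set as the CE plane, with no resampling.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty vector of WTP values, EUR/QALY, >= 0.
#' @return A `data.frame` with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1, all(wtp_grid >= 0))
  p <- vapply(wtp_grid,
              function(w) mean(w * psa$draws$de - psa$draws$dc > 0),
              numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = p)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %s, %d failed)\n",
              x$n_iterations, format(x$seed), x$n_failed))
  cat(sprintf("  mean dC = %.2f, mean dE = %.4f\n", x$mean[["dc"]], x$mean[["de"]]))
  cat(sprintf("  mean ICER = %s, iNMB@%.0f = %.2f, P(CE) = %.3f\n",
              if (x$mean_icer$label == "icer") sprintf("%.2f", x$mean_icer$value)
              else x$mean_icer$label,
              x$wtp, x$mean[["inmb"]], x$prob_cost_effective))
  for (cn in colnames(x$ci))
    cat(sprintf("  %-9s 95%% CI [%.3f, %.3f]\n", cn, x$ci[1, cn], x$ci[2, cn]))
  invisible(x)
}

#' Tabulate a PSA in the reporting format of the analysis
#'
#' One row with arm costs and QALYs (means and 95\% percentile intervals),
#' the mean ICER and the probability of cost-effectiveness at the stated
#' threshold.
#'
#' @param psa A `psa_result`.
#' @param label Row label.
#' @return A one-row `data.frame`.
#' @export
psa_summary_row <- function(psa, label = "base_case") {
  data.frame(
    analysis = label,
    cost_ctdna = psa$mean[["cost_int"]],
    cost_ctdna_lo = psa$ci[1, "cost_int"], cost_ctdna_hi = psa$ci[2, "cost_int"],
    qaly_ctdna = psa$mean[["qaly_int"]],
    qaly_ctdna_lo = psa$ci[1, "qaly_int"], qaly_ctdna_hi = psa$ci[2, "qaly_int"],
    cost_soc = psa$mean[["cost_soc"]],
    cost_soc_lo = psa$ci[1, "cost_soc"], cost_soc_hi = psa$ci[2, "cost_soc"],
    qaly_soc = psa$mean[["qaly_soc"]],
    qaly_soc_lo = psa$ci[1, "qaly_soc"], qaly_soc_hi = psa$ci[2, "qaly_soc"],
    icer = psa$mean_icer$value, icer_label = psa$mean_icer$label,
    inmb = psa$mean[["inmb"]],
    prob_cost_effective = psa$prob_cost_effective,
    stringsAsFactors = FALSE)
}
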