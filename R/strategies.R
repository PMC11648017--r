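new_subcohort <- function(label, weight, arpi_surv_line, arpi_cost_line,
                          hold = FALSE, forced_switch_cycle = NA_integer_,
                          assay = FALSE, doc_line = "docetaxel",
                          cab_line = "cabazitaxel", doc_utility = NULL,
                          tp_fraction = NA_real_) {
  structure(list(label = label, weight = weight,
                 arpi_surv_line = arpi_surv_line,
                 arpi_cost_line = arpi_cost_line, hold = hold,
                 forced_switch_cycle = forced_switch_cycle, assay = assay,
                 doc_line = doc_line, cab_line = cab_line,
                 doc_utility = doc_utility, tp_fraction = tp_fraction),
            class = "subcohort")
}

new_arm <- function(label, subcohorts) {
  w <- vapply(subcohorts, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("sub-cohort weights must sum to 1, got ", sum(w))
  structure(list(label = label, subcohorts = subcohorts),
            class = "strategy_arm")
}

#' @export
print.strategy_arm <- function(x, ...) {
  cat(sprintf("<strategy_arm %s> %d sub-cohort(s)\n",
              x$label, length(x$subcohorts)))
  for (sc in x$subcohorts)
    cat(sprintf("  %-28s w = %.3f  surv = %s\n", sc$label, sc$weight,
                sc$arpi_surv_line))
  invisible(x)
}

#' Build the standard-of-care arm
#'
#' Two sub-cohorts (abiraterone with weight `arpi_abi_share`, enzalutamide
#' with the complement; zero-weight sub-cohorts are dropped), each driven by
#' its drug's trial PFS/OS. Progression out of the ARPI state is suppressed
#' -- the probability mass is held in ARPI -- until the first cycle boundary
#' at or after 182.625 days (day 196 on the default grid), reflecting a
#' switch to second-line treatment after 6 months at the earliest.
#'
#' @param params A `cea_params` object.
#' @return A `strategy_arm` labelled `standard_of_care`.
#' @export
build_soc_arm <- function(params) {
  w <- d_mean(params$arpi_abi_share)
  subs <- list()
  if (w > 0)
    subs <- c(subs, list(new_subcohort("soc_abiraterone", w,
                                       "abiraterone", "abiraterone",
                                       hold = TRUE)))
  if (w < 1)
    subs <- c(subs, list(new_subcohort("soc_enzalutamide", 1 - w,
                                       "enzalutamide", "enzalutamide",
                                       hold = TRUE)))
  new_arm("standard_of_care", subs)
}

#' Build the ctDNA-guided arm
#'
#' Every intervention patient is tested (assay cost
#' `ctdna_n_samples * ctdna_cost_per_sample` charged once to survivors of
#' the first 4-week cycle). At the end of cycle 1, a fraction
#' `ctdna_flag_fraction` of each drug sub-cohort -- patients with detectable
#' ctDNA at baseline and week 4 -- switches to docetaxel; of these, a
#' fraction `ctdna_ppv` are true non-durable responders and the rest are
#' false positives receiving identical docetaxel outcomes (the split is
#' retained for reporting only). The remaining, predicted-durable patients
#' follow the durable-responder PFS/OS and by default are not subject to the
#' 6-month switch hold (set `durable_hold = TRUE` to hold them like standard
#' of care).
#'
#' Scenario flags in `params$flags` are honoured:
#' `durable_uses_trial_curves` (durable sub-cohorts keep their drug's trial
#' PFS/OS), `switcher_cabazitaxel_line` (alternative cabazitaxel line for
#' switchers), `switcher_docetaxel_utility` (numeric, or `"mean_arpi"` for
#' the mean of the two ARPI utilities).
#'
#' @param params A `cea_params` object.
#' @return A `strategy_arm` labelled `ctdna_guided`.
#' @export
build_ctdna_arm <- function(params) {
  w <- d_mean(params$arpi_abi_share)
  flag <- d_mean(params$ctdna_flag_fraction)
  ppv <- d_mean(params$ctdna_ppv)
  if (flag < 0 || flag > 1) stop("ctdna_flag_fraction must be in [0, 1]")
  if (ppv < 0 || ppv > 1) stop("ctdna_ppv must be in [0, 1]")
  fl <- params$flags %||% list()

  sw_cab <- fl$switcher_cabazitaxel_line %||% "cabazitaxel"
  if (!sw_cab %in% names(params$lines))
    stop("flag switcher_cabazitaxel_line: unknown line `", sw_cab, "`")
  sw_du <- fl$switcher_docetaxel_utility
  if (identical(sw_du, "mean_arpi"))
    sw_du <- (d_mean(params$lines$abiraterone$utility) +
                d_mean(params$lines$enzalutamide$utility)) / 2
  durable_surv <- if (isTRUE(fl$durable_uses_trial_curves)) NULL
                  else "arpi_durable_responder"

  subs <- list()
  for (drug in c("abiraterone", "enzalutamide")) {
    wd <- if (drug == "abiraterone") w else 1 - w
    if (wd == 0) next
    if (flag > 0)
      subs <- c(subs, list(new_subcohort(
        paste0("ctdna_switch_", drug), wd * flag, drug, drug,
        forced_switch_cycle = 1L, assay = TRUE, cab_line = sw_cab,
        doc_utility = sw_du, tp_fraction = ppv)))
    if (flag < 1)
      subs <- c(subs, list(new_subcohort(
        paste0("ctdna_durable_", drug), wd * (1 - flag),
        durable_surv %||% drug, drug,
        hold = isTRUE(params$durable_hold), assay = TRUE)))
  }
  new_arm("ctdna_guided", subs)
}
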