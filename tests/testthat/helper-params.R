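# Small fully-fixed toy parameter set (2-year horizon) for structural and
# closed-form tests; all distributions degenerate so runs are deterministic.

toy_line <- function(pfs, os, drug = 0, admin = 0, util = 0.8,
                     max_cycles = Inf) {
  treatment_line(
    pfs = if (is.null(pfs)) NULL
          else surv_spec("exponential_median", median = pfs),
    os = surv_spec("exponential_median", median = os),
    drug_cost_per_cycle = dist_spec("fixed", drug),
    admin_cost_per_cycle = dist_spec("fixed", admin),
    utility = dist_spec("fixed", util),
    max_cycles = max_cycles)
}

toy_params <- function(...) {
  parameter_set(
    lines = list(
      abiraterone = toy_line(10, 24, drug = 100),
      enzalutamide = toy_line(12, 26, drug = 400),
      arpi_durable_responder = toy_line(20, 40),
      docetaxel = toy_line(6, 18, drug = 50, admin = 30, util = 0.7,
                           max_cycles = 10),
      cabazitaxel = toy_line(5, 12, drug = 200, admin = 30, util = 0.65,
                             max_cycles = 10),
      bsc = toy_line(NULL, 6, util = 0.5)),
    ctdna_ppv = dist_spec("fixed", 0.85),
    ctdna_flag_fraction = dist_spec("fixed", 0.4),
    ctdna_cost_per_sample = dist_spec("fixed", 350),
    visit_cost_per_cycle = dist_spec("fixed", 20),
    diagnostic_cost = dist_spec("fixed", 100),
    bsc_cost_per_cycle = dist_spec("fixed", 80),
    bsc_entry_rate_per_day = 1e-4,
    horizon_years = 2,
    ...)
}

# collapse every distributed parameter to its mean
freeze_params <- function(ps) {
  fx <- function(d) dist_spec("fixed", d_mean_t(d))
  d_mean_t <- function(d) if (inherits(d, "dist_spec")) d$mean else as.numeric(d)
  fs <- function(s) {
    if (is.null(s) || s$form != "exponential_median") return(s)
    surv_spec("exponential_median", median = s$median, median_se = 0)
  }
  for (nm in c("ctdna_ppv", "ctdna_flag_fraction", "ctdna_cost_per_sample",
               "visit_cost_per_cycle", "diagnostic_cost",
               "bsc_cost_per_cycle")) ps[[nm]] <- fx(ps[[nm]])
  for (nm in names(ps$lines)) {
    ln <- ps$lines[[nm]]
    ln$pfs <- fs(ln$pfs); ln$os <- fs(ln$os)
    ln$drug_cost_per_cycle <- fx(ln$drug_cost_per_cycle)
    ln$admin_cost_per_cycle <- fx(ln$admin_cost_per_cycle)
    ln$utility <- fx(ln$utility)
    ln$ae_events <- lapply(ln$ae_events, function(ev)
      list(prob = fx(ev$prob), cost = fx(ev$cost)))
    ps$lines[[nm]] <- ln
  }
  ps
}

# allowed transition topology of the expanded chain, as a logical mask
allowed_transitions <- function() {
  s <- state_space()
  A <- matrix(FALSE, length(s), length(s), dimnames = list(s, s))
  A["ARPI", c("ARPI", "DOC_1", "BSC", "DEATH")] <- TRUE
  for (i in 1:10) {
    nxt <- if (i < 10) paste0("DOC_", i + 1) else "DOC_NP"
    A[paste0("DOC_", i), c(nxt, "CAB_1", "BSC", "DEATH")] <- TRUE
    nxt <- if (i < 10) paste0("CAB_", i + 1) else "CAB_NP"
    A[paste0("CAB_", i), c(nxt, "BSC", "DEATH")] <- TRUE
  }
  A["DOC_NP", c("DOC_NP", "CAB_1", "BSC", "DEATH")] <- TRUE
  A["CAB_NP", c("CAB_NP", "BSC", "DEATH")] <- TRUE
  A["BSC", c("BSC", "DEATH")] <- TRUE
  A["DEATH", "DEATH"] <- TRUE
  A
}
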