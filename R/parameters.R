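#' Distribution specification for an uncertain parameter
#'
#' Every uncertain scalar in the model (costs, utilities, probabilities) is
#' described by a `dist_spec`: a distribution family plus the mean and
#' standard error on the natural scale. Probabilistic sensitivity analysis
#' samples beta distributions for quantities bounded in \[0, 1\] and gamma
#' distributions for non-negative quantities, both parameterized by method of
#' moments from `(mean, se)`. `kind = "fixed"` always returns the mean.
#'
#' @param kind One of `"fixed"`, `"beta"`, `"gamma"`.
#' @param mean Point estimate (mean of the distribution).
#' @param se Standard error of the mean; `0` behaves like `"fixed"`.
#' @param lo,hi Optional bounds used as one-way sensitivity ranges.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", 0.85, 0.03)
#' dist_spec("gamma", 350, 35)
#' @export
dist_spec <- function(kind = c("fixed", "beta", "gamma"), mean, se = 0,
                      lo = NULL, hi = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(se), length(se) == 1L, se >= 0)
  if (kind == "beta") {
    if (mean <= 0 || mean >= 1)
      stop("beta dist_spec requires 0 < mean < 1, got mean = ", mean)
    if (se > 0 && se^2 >= mean * (1 - mean))
      stop("beta dist_spec requires se^2 < mean*(1-mean): se = ", se,
           " infeasible for mean = ", mean)
  }
  if (kind == "gamma" && mean <= 0)
    stop("gamma dist_spec requires mean > 0, got mean = ", mean)
  structure(list(kind = kind, mean = mean, se = se, lo = lo, hi = hi),
            class = "dist_spec")
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s: mean = %g, se = %g>\n", x$kind, x$mean, x$se))
  invisible(x)
}

d_mean <- function(d) {
  if (is_dist_spec(d)) d$mean else as.numeric(d)
}

#' Fit a beta distribution by method of moments
#'
#' Returns the `(alpha, beta)` shape parameters of the beta distribution with
#' the requested mean and variance `se^2`, using
#' `alpha + beta = mean * (1 - mean) / se^2 - 1`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `0 < se^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' fit_beta(0.5, 0.05) # c(alpha = 49.5, beta = 49.5)
#' @export
fit_beta <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("fit_beta requires 0 < mean < 1")
  if (!is.finite(se) || se <= 0)
    stop("fit_beta requires se > 0")
  if (se^2 >= mean * (1 - mean))
    stop("fit_beta: infeasible variance, se^2 must be < mean*(1-mean)")
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by method of moments
#'
#' Returns `(shape, scale)` of the gamma distribution with the requested mean
#' and variance `se^2`: `shape = mean^2 / se^2`, `scale = se^2 / mean`.
#'
#' @param mean Mean, positive.
#' @param se Standard error, positive.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' fit_gamma(100, 10) # c(shape = 100, scale = 1)
#' @export
fit_gamma <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0)
    stop("fit_gamma requires mean > 0 and se > 0")
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Draw from a dist_spec
#'
#' @param d A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(d, n = 1L) {
  stopifnot(is_dist_spec(d))
  if (d$kind == "fixed" || d$se == 0) return(rep(d$mean, n))
  if (d$kind == "beta") {
    ab <- fit_beta(d$mean, d$se)
    stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
  } else {
    sh <- fit_gamma(d$mean, d$se)
    stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
  }
}

#' Survival summary specification
#'
#' Survival inputs enter the model either as an exponential distribution
#' identified by its median (the only summary universally printed by the
#' cited trials) or as a piecewise-constant hazard for users who digitize
#' full curves. Medians are in months; piecewise hazards are per month on
#' breakpoints in months starting at 0.
#'
#' @param form `"exponential_median"` or `"piecewise_hazard"`.
#' @param median Median in months (exponential form).
#' @param median_se Standard error of the median used when the median is
#'   sampled (gamma) in PSA; `0` keeps it fixed.
#' @param breakpoints Increasing vector of interval starts in months,
#'   beginning at 0 (piecewise form).
#' @param hazards Non-negative per-month hazard for each interval.
#' @return An object of class `surv_spec`.
#' @export
surv_spec <- function(form = c("exponential_median", "piecewise_hazard"),
                      median = NULL, median_se = 0,
                      breakpoints = NULL, hazards = NULL) {
  form <- match.arg(form)
  if (form == "exponential_median") {
    if (is.null(median) || !is.finite(median) || median <= 0)
      stop("surv_spec: exponential_median requires median > 0")
    if (!is.finite(median_se) || median_se < 0)
      stop("surv_spec: median_se must be >= 0")
  } else {
    if (is.null(breakpoints) || is.null(hazards) ||
        length(breakpoints) != length(hazards))
      stop("surv_spec: piecewise_hazard requires matching breakpoints and hazards")
    if (breakpoints[1] != 0 || any(diff(breakpoints) <= 0))
      stop("surv_spec: breakpoints must strictly increase from 0")
    if (any(hazards < 0)) stop("surv_spec: hazards must be >= 0")
  }
  structure(list(form = form, median = median, median_se = median_se,
                 breakpoints = breakpoints, hazards = hazards),
            class = "surv_spec")
}

is_surv_spec <- function(x) inherits(x, "surv_spec")

## ---- treatment lines -------------------------------------------------------

line_names <- function() {
  c("abiraterone", "enzalutamide", "arpi_durable_responder",
    "docetaxel", "cabazitaxel", "bsc")
}

#' Parameters of one treatment line
#'
#' @param pfs,os [surv_spec()] objects; `pfs` may be `NULL` for best
#'   supportive care, which has no further progression.
#' @param drug_cost_per_cycle,admin_cost_per_cycle Cost [dist_spec()]s (EUR
#'   per model cycle).
#' @param utility Utility weight [dist_spec()] with mean in \[0, 1\].
#' @param ae_events List of `list(prob = , cost = )` pairs: probability of a
#'   grade >= 3 adverse event over the treatment line and its management cost.
#' @param max_cycles Maximum number of on-treatment cycles (10 for the
#'   taxanes, `Inf` for unbounded lines).
#' @return A list of class `treatment_line`.
#' @export
treatment_line <- function(pfs = NULL, os, drug_cost_per_cycle = dist_spec("fixed", 0),
                           admin_cost_per_cycle = dist_spec("fixed", 0),
                           utility, ae_events = list(), max_cycles = Inf) {
  structure(list(pfs = pfs, os = os,
                 drug_cost_per_cycle = drug_cost_per_cycle,
                 admin_cost_per_cycle = admin_cost_per_cycle,
                 utility = utility, ae_events = ae_events,
                 max_cycles = max_cycles),
            class = "treatment_line")
}

## ---- parameter set ---------------------------------------------------------

param_defaults <- function() {
  list(
    schema_version = 1L,
    arpi_abi_share = 0.5,
    ctdna_ppv = dist_spec("fixed", 0.85),
    ctdna_flag_fraction = dist_spec("fixed", 0.4),
    ctdna_cost_per_sample = dist_spec("fixed", 350),
    ctdna_n_samples = 3L,
    visit_cost_per_cycle = dist_spec("fixed", 0),
    diagnostic_cost = dist_spec("fixed", 0),
    bsc_cost_per_cycle = dist_spec("fixed", 0),
    bsc_entry_rate_per_day = 0,
    discount_rate_costs = 0.04,
    discount_rate_effects = 0.015,
    wtp = 80000,
    horizon_years = 5,
    cycle1_days = 28,
    cycle_days = 21,
    cohort_size = 1000,
    durable_hold = FALSE,
    flags = list()
  )
}

top_level_dists <- function() {
  c("ctdna_ppv", "ctdna_flag_fraction", "ctdna_cost_per_sample",
    "visit_cost_per_cycle", "diagnostic_cost", "bsc_cost_per_cycle")
}

#' Assemble and validate a parameter set
#'
#' @param lines Named list of [treatment_line()]s covering
#'   `abiraterone`, `enzalutamide`, `arpi_durable_responder`, `docetaxel`,
#'   `cabazitaxel`, `bsc`.
#' @param ... Top-level parameters overriding the documented base-case
#'   defaults (ARPI split 0.5, PPV 0.85, assay 3 x EUR 350, discounting
#'   4\%/1.5\%, WTP 80,000, 5-year horizon, 28-day first cycle then 21-day
#'   cycles).
#' @return A validated object of class `cea_params`.
#' @export
parameter_set <- function(lines, ...) {
  ps <- param_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(ps))
  if (length(unknown))
    stop("unknown parameter `", unknown[1], "`; valid names: ",
         paste(names(ps), collapse = ", "), call. = FALSE)
  for (i in seq_along(dots)) ps[[names(dots)[i]]] <- dots[[i]]
  ps$lines <- lines
  for (nm in top_level_dists()) {
    if (!is_dist_spec(ps[[nm]])) {
      kind <- if (nm %in% c("ctdna_ppv", "ctdna_flag_fraction")) "beta" else "gamma"
      if (is.numeric(ps[[nm]]) && length(ps[[nm]]) == 1L) {
        ps[[nm]] <- dist_spec("fixed", as.numeric(ps[[nm]]))
      } else {
        ps[[nm]] <- plain_to_dist(ps[[nm]], kind)
      }
    }
  }
  class(ps) <- "cea_params"
  validate_parameters(ps)
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities in \[0, 1\], non-negative
#' rates and costs, positive cycle lengths, utilities in \[0, 1\], survival
#' medians positive, taxane cycle caps >= 1, and durable-responder medians at
#' least the share-weighted pooled ARPI medians. Errors name the offending
#' field.
#'
#' @param ps A `cea_params` object.
#' @return `ps`, invisibly unchanged, if valid.
#' @export
validate_parameters <- function(ps) {
  fail <- function(field, msg) stop("parameter `", field, "`: ", msg, call. = FALSE)
  chk_prob <- function(x, field) {
    v <- d_mean(x)
    if (!is.finite(v) || v < 0 || v > 1) fail(field, "must be in [0, 1]")
  }
  chk_prob(ps$arpi_abi_share, "arpi_abi_share")
  chk_prob(ps$ctdna_ppv, "ctdna_ppv")
  chk_prob(ps$ctdna_flag_fraction, "ctdna_flag_fraction")
  if (ps$discount_rate_costs < 0) fail("discount_rate_costs", "must be >= 0")
  if (ps$discount_rate_effects < 0) fail("discount_rate_effects", "must be >= 0")
  if (ps$wtp < 0) fail("wtp", "must be >= 0")
  if (ps$cycle1_days <= 0) fail("cycle1_days", "must be > 0")
  if (ps$cycle_days <= 0) fail("cycle_days", "must be > 0")
  if (ps$horizon_years * 365.25 <= ps$cycle1_days)
    fail("horizon_years", "horizon must exceed the first cycle")
  if (ps$bsc_entry_rate_per_day < 0) fail("bsc_entry_rate_per_day", "must be >= 0")
  if (ps$ctdna_n_samples < 0) fail("ctdna_n_samples", "must be >= 0")
  for (nm in c("ctdna_cost_per_sample", "visit_cost_per_cycle",
               "diagnostic_cost", "bsc_cost_per_cycle")) {
    if (d_mean(ps[[nm]]) < 0) fail(nm, "must be >= 0")
  }
  missing <- setdiff(line_names(), names(ps$lines))
  if (length(missing))
    fail(paste0("lines.", missing[1]), "treatment line missing")
  for (nm in line_names()) {
    ln <- ps$lines[[nm]]
    pre <- paste0("lines.", nm, ".")
    if (is.null(ln$os)) fail(paste0(pre, "os"), "required")
    if (nm != "bsc" && is.null(ln$pfs)) fail(paste0(pre, "pfs"), "required")
    u <- d_mean(ln$utility)
    if (!is.finite(u) || u < 0 || u > 1)
      fail(paste0(pre, "utility"), "mean must be in [0, 1]")
    for (cn in c("drug_cost_per_cycle", "admin_cost_per_cycle")) {
      if (d_mean(ln[[cn]]) < 0) fail(paste0(pre, cn), "mean must be >= 0")
    }
    if (is.finite(ln$max_cycles) && ln$max_cycles < 1)
      fail(paste0(pre, "max_cycles"), "must be >= 1 when bounded")
    for (i in seq_along(ln$ae_events)) {
      ev <- ln$ae_events[[i]]
      chk_prob(ev$prob, paste0(pre, "ae_events[", i, "].prob"))
      if (d_mean(ev$cost) < 0)
        fail(paste0(pre, "ae_events[", i, "].cost"), "must be >= 0")
    }
  }
  # durable responders outlive the pooled trial medians by construction;
  # checked on point estimates only (PSA draws may cross by sampling noise)
  if (!isTRUE(attr(ps, "sampled"))) {
    w <- d_mean(ps$arpi_abi_share)
    for (ep in c("pfs", "os")) {
      dm <- exp_median_of(ps$lines$arpi_durable_responder[[ep]])
      pm <- w * exp_median_of(ps$lines$abiraterone[[ep]]) +
        (1 - w) * exp_median_of(ps$lines$enzalutamide[[ep]])
      if (!is.na(dm) && !is.na(pm) && dm < pm)
        fail(paste0("lines.arpi_durable_responder.", ep),
             sprintf("median (%g) must be >= pooled ARPI median (%g)", dm, pm))
    }
  }
  invisible(ps)
}

exp_median_of <- function(s) {
  if (is_surv_spec(s) && s$form == "exponential_median") s$median else NA_real_
}

#' @export
print.cea_params <- function(x, ...) {
  cat("<cea_params> ctDNA-guided switch decision model parameters\n")
  cat(sprintf("  ARPI abi share %.2f | PPV %.2f | flag fraction %.2f\n",
              d_mean(x$arpi_abi_share), d_mean(x$ctdna_ppv),
              d_mean(x$ctdna_flag_fraction)))
  cat(sprintf("  assay %d x EUR %.0f | WTP %.0f | discount %.3f/%.3f | horizon %g y\n",
              x$ctdna_n_samples, d_mean(x$ctdna_cost_per_sample), x$wtp,
              x$discount_rate_costs, x$discount_rate_effects, x$horizon_years))
  cat("  lines:", paste(names(x$lines), collapse = ", "), "\n")
  invisible(x)
}

## ---- YAML (de)serialization ------------------------------------------------

dist_to_plain <- function(d) {
  if (!is_dist_spec(d)) return(d)
  if (d$kind == "fixed") return(d$mean)
  out <- list(dist = d$kind, mean = d$mean, se = d$se)
  if (!is.null(d$lo)) out$lo <- d$lo
  if (!is.null(d$hi)) out$hi <- d$hi
  out
}

plain_to_dist <- function(x, default_kind) {
  if (is_dist_spec(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_spec("fixed", x))
  if (is.list(x)) {
    kind <- x$dist %||% x$kind %||% default_kind
    return(dist_spec(kind, x$mean, x$se %||% 0, x$lo, x$hi))
  }
  stop("cannot interpret value as a distribution: ", deparse(x))
}

surv_to_plain <- function(s) {
  if (is.null(s)) return(NULL)
  if (s$form == "exponential_median") {
    out <- list(form = "exponential_median", median = s$median)
    if (s$median_se > 0) out$median_se <- s$median_se
    out
  } else {
    list(form = "piecewise_hazard", breakpoints = s$breakpoints,
         hazards = s$hazards)
  }
}

plain_to_surv <- function(x, field) {
  if (is.null(x)) return(NULL)
  if (is_surv_spec(x)) return(x)
  if (!is.list(x) || is.null(x$form))
    stop("parameter `", field, "`: survival spec needs a `form` field")
  if (x$form == "exponential_median") {
    surv_spec("exponential_median", median = x$median,
              median_se = x$median_se %||% 0)
  } else if (x$form == "piecewise_hazard") {
    surv_spec("piecewise_hazard", breakpoints = unlist(x$breakpoints),
              hazards = unlist(x$hazards))
  } else stop("parameter `", field, "`: unknown survival form ", x$form)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

line_from_plain <- function(x, nm) {
  pre <- paste0("lines.", nm, ".")
  ae <- lapply(x$ae_events %||% list(), function(ev) {
    list(prob = plain_to_dist(ev$prob, "beta"),
         cost = plain_to_dist(ev$cost, "gamma"))
  })
  mc <- x$max_cycles %||% (if (nm %in% c("docetaxel", "cabazitaxel")) 10 else Inf)
  if (is.character(mc)) mc <- Inf
  treatment_line(
    pfs = plain_to_surv(x$pfs, paste0(pre, "pfs")),
    os = plain_to_surv(x$os, paste0(pre, "os")),
    drug_cost_per_cycle = plain_to_dist(x$drug_cost_per_cycle %||% 0, "gamma"),
    admin_cost_per_cycle = plain_to_dist(x$admin_cost_per_cycle %||% 0, "gamma"),
    utility = plain_to_dist(x$utility, "beta"),
    ae_events = ae, max_cycles = mc)
}

#' Load a parameter file
#'
#' Reads a YAML parameter file, fills every missing optional field with the
#' documented base-case default, and validates all invariants.
#'
#' @param path Path to a YAML file with a `schema_version` field and a
#'   `lines:` block (see the shipped `base_like.yaml` under
#'   `system.file("extdata", package = "ctdnaCEA")` for the schema).
#' @return A validated [parameter_set()].
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$lines)) stop("parameter `lines`: block missing from ", path)
  lines <- list()
  for (nm in names(raw$lines)) lines[[nm]] <- line_from_plain(raw$lines[[nm]], nm)
  extra <- raw[setdiff(names(raw), c("lines", "schema_version"))]
  ps <- do.call(parameter_set, c(list(lines = lines), extra))
  ps$schema_version <- raw$schema_version %||% 1L
  ps
}

#' Save a parameter set to YAML
#'
#' `load_parameters(save_parameters(ps, path))` reproduces `ps` exactly.
#'
#' @param ps A `cea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(ps, path) {
  out <- list(schema_version = ps$schema_version)
  for (nm in setdiff(names(ps), c("lines", "schema_version", "flags"))) {
    out[[nm]] <- dist_to_plain(ps[[nm]])
  }
  if (length(ps$flags)) out$flags <- ps$flags
  out$lines <- lapply(ps$lines, function(ln) {
    pl <- list(pfs = surv_to_plain(ln$pfs), os = surv_to_plain(ln$os),
               drug_cost_per_cycle = dist_to_plain(ln$drug_cost_per_cycle),
               admin_cost_per_cycle = dist_to_plain(ln$admin_cost_per_cycle),
               utility = dist_to_plain(ln$utility),
               ae_events = lapply(ln$ae_events, function(ev)
                 list(prob = dist_to_plain(ev$prob),
                      cost = dist_to_plain(ev$cost))))
    if (is.finite(ln$max_cycles)) pl$max_cycles <- ln$max_cycles
    pl[!vapply(pl, is.null, logical(1))]
  })
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Resolved parameter table for audit
#'
#' Flattens a parameter set into one row per scalar parameter (name, point
#' estimate, distribution family, standard error), suitable for CSV export.
#'
#' @param ps A `cea_params` object.
#' @return A `data.frame` with columns `parameter`, `value`, `dist`, `se`.
#' @export
parameters_table <- function(ps) {
  rows <- list()
  add <- function(name, value, dist = "fixed", se = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, value = value, dist = dist, se = se,
      stringsAsFactors = FALSE)
  }
  add_d <- function(name, d) {
    if (is_dist_spec(d)) add(name, d$mean, d$kind, d$se) else add(name, d)
  }
  scalars <- c("arpi_abi_share", "ctdna_n_samples", "bsc_entry_rate_per_day",
               "discount_rate_costs", "discount_rate_effects", "wtp",
               "horizon_years", "cycle1_days", "cycle_days", "cohort_size")
  for (nm in scalars) add(nm, ps[[nm]])
  for (nm in top_level_dists()) add_d(nm, ps[[nm]])
  for (nm in names(ps$lines)) {
    ln <- ps$lines[[nm]]
    pre <- paste0("lines.", nm, ".")
    for (ep in c("pfs", "os")) {
      s <- ln[[ep]]
      if (is.null(s)) next
      if (s$form == "exponential_median")
        add(paste0(pre, ep, ".median"), s$median,
            if (s$median_se > 0) "gamma" else "fixed", s$median_se)
      else add(paste0(pre, ep, ".piecewise_pieces"), length(s$hazards))
    }
    add_d(paste0(pre, "drug_cost_per_cycle"), ln$drug_cost_per_cycle)
    add_d(paste0(pre, "admin_cost_per_cycle"), ln$admin_cost_per_cycle)
    add_d(paste0(pre, "utility"), ln$utility)
    add(paste0(pre, "max_cycles"), ln$max_cycles)
    for (i in seq_along(ln$ae_events)) {
      add_d(paste0(pre, "ae_events.", i, ".prob"), ln$ae_events[[i]]$prob)
      add_d(paste0(pre, "ae_events.", i, ".cost"), ln$ae_events[[i]]$cost)
    }
  }
  do.call(rbind, rows)
}

## ---- PSA sampling ----------------------------------------------------------

draw_fixed <- function(d) dist_spec("fixed", draw_dist(d, 1L), lo = d$lo, hi = d$hi)

sample_surv <- function(s) {
  if (is.null(s) || s$form != "exponential_median" || s$median_se == 0) return(s)
  sh <- fit_gamma(s$median, s$median_se)
  surv_spec("exponential_median",
            median = stats::rgamma(1L, shape = sh[["shape"]], scale = sh[["scale"]]),
            median_se = 0)
}

#' Draw one probabilistic parameter set
#'
#' Replaces every distributed parameter (beta for probabilities and
#' utilities, gamma for costs and survival medians) by a single random draw,
#' leaving fixed parameters unchanged. The draw order is fixed and
#' documented, so a given seed always yields the same parameter set.
#'
#' @param ps A `cea_params` object.
#' @param rng_seed Integer seed; the RNG state of the session is preserved.
#' @return A `cea_params` object with every `dist_spec` collapsed to `fixed`.
#' @export
sample_parameters <- function(ps, rng_seed) {
  withr::with_seed(rng_seed, {
    out <- ps
    # documented draw order: top-level dists, then lines alphabet-free fixed
    # order (abiraterone, enzalutamide, durable, docetaxel, cabazitaxel, bsc),
    # within a line: pfs, os, drug, admin, utility, ae (prob then cost)
    for (nm in top_level_dists()) out[[nm]] <- draw_fixed(out[[nm]])
    for (nm in names(out$lines)) {
      ln <- out$lines[[nm]]
      ln$pfs <- sample_surv(ln$pfs)
      ln$os <- sample_surv(ln$os)
      ln$drug_cost_per_cycle <- draw_fixed(ln$drug_cost_per_cycle)
      ln$admin_cost_per_cycle <- draw_fixed(ln$admin_cost_per_cycle)
      ln$utility <- draw_fixed(ln$utility)
      ln$ae_events <- lapply(ln$ae_events, function(ev)
        list(prob = draw_fixed(ev$prob), cost = draw_fixed(ev$cost)))
      out$lines[[nm]] <- ln
    }
    attr(out, "sampled") <- TRUE
    out
  })
}

## ---- parameter addressing (OWSA / scenarios) -------------------------------

#' Set a named model parameter
#'
#' Addresses parameters by dotted path, e.g. `"ctdna_cost_per_sample"`,
#' `"arpi_abi_share"`, `"lines.enzalutamide.drug_cost_per_cycle"`,
#' `"lines.docetaxel.os.median"`, `"lines.docetaxel.utility"`. Setting the
#' mean of a distributed parameter rescales its standard error to preserve
#' the coefficient of variation. Survival overrides may also pass a full
#' spec list (`list(form = "exponential_median", median = ...)`).
#'
#' @param ps A `cea_params` object.
#' @param name Dotted parameter path.
#' @param value New value.
#' @return The modified, re-validated parameter set.
#' @export
set_param <- function(ps, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  known_top <- setdiff(names(ps), "lines")
  set_leaf <- function(obj) {
    if (is_dist_spec(obj)) {
      cv <- if (obj$mean > 0) obj$se / obj$mean else 0
      if (as.numeric(value) == 0)
        return(dist_spec("fixed", 0, lo = obj$lo, hi = obj$hi))
      return(dist_spec(obj$kind, as.numeric(value), cv * as.numeric(value),
                       lo = obj$lo, hi = obj$hi))
    }
    as.numeric(value)
  }
  if (length(parts) == 1L) {
    if (!parts %in% known_top)
      stop("unknown parameter `", name, "`; valid top-level names: ",
           paste(known_top, collapse = ", "))
    ps[[parts]] <- set_leaf(ps[[parts]])
  } else if (parts[1] == "lines") {
    if (length(parts) < 3L || !parts[2] %in% names(ps$lines))
      stop("unknown parameter `", name, "`; valid lines: ",
           paste(names(ps$lines), collapse = ", "))
    ln <- ps$lines[[parts[2]]]
    field <- parts[3]
    if (!field %in% names(ln))
      stop("unknown parameter `", name, "`; valid line fields: ",
           paste(names(ln), collapse = ", "))
    if (field %in% c("pfs", "os")) {
      if (length(parts) == 4L && parts[4] == "median") {
        s <- ln[[field]]
        stopifnot(s$form == "exponential_median")
        s$median <- as.numeric(value)
        ln[[field]] <- s
      } else {
        ln[[field]] <- plain_to_surv(value, name)
      }
    } else {
      ln[[field]] <- set_leaf(ln[[field]])
    }
    ps$lines[[parts[2]]] <- ln
  } else {
    stop("unknown parameter `", name, "`")
  }
  validate_parameters(ps)
}
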