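#' One-way sensitivity analysis (tornado)
#'
#' For each parameter, the model is re-run with the parameter set first to
#' its low and then to its high value, everything else at base case, and the
#' mean incremental net monetary benefit recorded. By default each endpoint
#' is a full PSA mean (`n_psa` iterations, common master seed so endpoint
#' differences are attributable to the varied parameter); set
#' `deterministic = TRUE` for point-estimate endpoints.
#'
#' @param params Base-case `cea_params`.
#' @param specs `data.frame` with columns `name` (dotted parameter path, see
#'   [set_param()]), `lo`, `hi`.
#' @param n_psa PSA iterations per endpoint.
#' @param seed Master seed shared by all endpoints.
#' @param deterministic If `TRUE`, endpoints are deterministic runs.
#' @return A `tornado` `data.frame`: `parameter`, `lo`, `hi`, `inmb_lo`,
#'   `inmb_hi`, `width`, sorted by descending bar width, with the base-case
#'   iNMB in `attr(, "base_inmb")`.
#' @export
run_owsa <- function(params, specs, n_psa = 1000L, seed = 1L,
                     deterministic = FALSE) {
  stopifnot(all(c("name", "lo", "hi") %in% names(specs)),
            all(specs$lo <= specs$hi))
  endpoint <- function(ps) {
    if (deterministic) run_cea(ps)$inmb
    else run_psa(ps, n = n_psa, seed = seed)$mean[["inmb"]]
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    nm <- specs$name[i]
    lo <- endpoint(set_param(params, nm, specs$lo[i]))
    hi <- endpoint(set_param(params, nm, specs$hi[i]))
    data.frame(parameter = nm, lo = specs$lo[i], hi = specs$hi[i],
               inmb_lo = lo, inmb_hi = hi, width = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_inmb") <- if (deterministic) run_cea(params)$inmb
                            else run_psa(params, n = n_psa, seed = seed)$mean[["inmb"]]
  class(out) <- c("tornado", class(out))
  out
}

#' Default one-way sensitivity ranges
#'
#' The ranges examined in the analysis: ARPI drug split 0 to 1, ctDNA
#' predictive value 0.65 to 0.95, 90\% price reductions for enzalutamide,
#' abiraterone and cabazitaxel, and the ctDNA assay price down to EUR 100.
#'
#' @param params A `cea_params` object (supplies the base drug prices).
#' @return A `data.frame` suitable for [run_owsa()].
#' @export
default_owsa_specs <- function(params) {
  price <- function(line) d_mean(params$lines[[line]]$drug_cost_per_cycle)
  data.frame(
    name = c("arpi_abi_share", "ctdna_ppv",
             "lines.enzalutamide.drug_cost_per_cycle",
             "lines.abiraterone.drug_cost_per_cycle",
             "lines.cabazitaxel.drug_cost_per_cycle",
             "ctdna_cost_per_sample"),
    lo = c(0, 0.65, 0.1 * price("enzalutamide"), 0.1 * price("abiraterone"),
           0.1 * price("cabazitaxel"), 100),
    hi = c(1, 0.95, price("enzalutamide"), price("abiraterone"),
           price("cabazitaxel"), d_mean(params$ctdna_cost_per_sample)),
    stringsAsFactors = FALSE)
}

## ---- scenarios -------------------------------------------------------------

#' Declare a scenario overlay
#'
#' A scenario is a pure overlay on the base configuration: dotted-path
#' parameter overrides (see [set_param()]) plus structural flags interpreted
#' by [build_ctdna_arm()].
#'
#' @param id Scenario identifier.
#' @param overrides Named list of `path = value` overrides; survival
#'   overrides may pass `list(form = "exponential_median", median = ...)`.
#' @param flags Named list of structural flags
#'   (`durable_uses_trial_curves`, `switcher_cabazitaxel_line`,
#'   `switcher_docetaxel_utility`).
#' @param description Free-text description.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id, overrides = list(), flags = list(),
                          description = "") {
  structure(list(id = id, overrides = overrides, flags = flags,
                 description = description), class = "scenario_spec")
}

#' Load a scenario overlay file
#'
#' @param path YAML file with optional `overrides:` and `flags:` blocks.
#' @return A `scenario_spec`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario overlay file not found: ", path)
  raw <- yaml::read_yaml(path)
  scenario_spec(raw$id %||% tools::file_path_sans_ext(basename(path)),
                overrides = raw$overrides %||% list(),
                flags = raw$flags %||% list(),
                description = raw$description %||% "")
}

apply_scenario <- function(params, spec) {
  ps <- params
  for (nm in names(spec$overrides)) ps <- set_param(ps, nm, spec$overrides[[nm]])
  if (length(spec$flags)) ps$flags <- utils::modifyList(ps$flags %||% list(),
                                                        spec$flags)
  validate_parameters(ps)
  ps
}

#' Run a scenario analysis
#'
#' Applies the overlay to a copy of the base parameters (the base set is
#' never modified), runs the deterministic analysis and a PSA, and returns a
#' summary row in the reporting format of the scenario table.
#'
#' @param base Base-case `cea_params`.
#' @param spec A [scenario_spec()] or path to an overlay file.
#' @param n_psa PSA iterations.
#' @param seed Master seed.
#' @return List with `params` (the overlaid set), `cea` (deterministic
#'   [run_cea()] result), `psa` ([run_psa()] result) and `row`
#'   ([psa_summary_row()]).
#' @export
run_scenario <- function(base, spec, n_psa = 1000L, seed = 1L) {
  if (is.character(spec)) spec <- load_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  ps <- apply_scenario(base, spec)
  cea <- run_cea(ps)
  psa <- run_psa(ps, n = n_psa, seed = seed)
  list(params = ps, cea = cea, psa = psa,
       row = psa_summary_row(psa, label = spec$id))
}

#' The four built-in scenario overlays
#'
#' * `s1_registration_pfs_os` -- the intervention arm's predicted-durable
#'   patients keep their drug's registration-trial PFS/OS instead of the
#'   durable-responder curves, removing the survival advantage of the
#'   guided arm.
#' * `s2_proselica_cabazitaxel` -- switchers' cabazitaxel uses
#'   second-line-setting survival data instead of third-line data.
#' * `s3_docetaxel_utility` -- switchers on docetaxel keep the mean ARPI
#'   utility (quality of life assumed not to drop after an early switch).
#' * `s4_reallife_docetaxel` -- docetaxel PFS/OS replaced by real-world
#'   second-line data in both arms.
#'
#' Scenarios needing alternative survival inputs reference lines shipped in
#' the parameter file (`cabazitaxel_proselica`) or override medians from the
#' overlay file.
#'
#' @param dir Directory of overlay files; defaults to the installed package
#'   data.
#' @return Named list of `scenario_spec`s.
#' @export
builtin_scenarios <- function(dir = system.file("extdata", package = "ctdnaCEA")) {
  ids <- c("s1_registration_pfs_os", "s2_proselica_cabazitaxel",
           "s3_docetaxel_utility", "s4_reallife_docetaxel")
  specs <- lapply(ids, function(id) load_scenario(file.path(dir, paste0(id, ".yaml"))))
  names(specs) <- ids
  specs
}
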