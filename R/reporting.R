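# exit-status classes shared by the command entry points:
# 0 success, 2 configuration/validation error, 1 runtime error

cmd_fail <- function(status, msg) {
  structure(list(status = status, message = msg), class = "cmd_status")
}

cmd_ok <- function(files) {
  structure(list(status = 0L, files = files), class = "cmd_status")
}

#' @export
print.cmd_status <- function(x, ...) {
  if (x$status == 0L) {
    cat("OK;", length(x$files), "file(s) written\n")
  } else {
    cat("FAILED (status ", x$status, "): ", x$message, "\n", sep = "")
  }
  invisible(x)
}

write_manifest <- function(outdir, config, seed, n_iterations, files) {
  manifest <- list(
    config = basename(config),
    config_md5 = unname(tools::md5sum(config)),
    schema_version = 1L,
    seed = seed, n_iterations = n_iterations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("ctdnaCEA")),
    outputs = basename(files))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

load_config_or_fail <- function(config) {
  tryCatch(load_parameters(config), error = function(e) e)
}

#' Run the analysis from a parameter file
#'
#' Deterministic mode writes the deterministic cost-effectiveness summary;
#' PSA mode additionally writes the per-iteration draws, the CEAC table and
#' the CE-plane/CEAC figures. A manifest records config hash, seed and
#' package version so every output is reproducible.
#'
#' @param config Path to a YAML parameter file.
#' @param mode `"deterministic"` or `"psa"`.
#' @param seed Master seed (all randomness flows from it).
#' @param n PSA iterations.
#' @param outdir Output directory, created if missing.
#' @return A `cmd_status` object; `$status` is 0 on success, 2 on a
#'   configuration error.
#' @export
cmd_run <- function(config, mode = c("deterministic", "psa"), seed = 1L,
                    n = 5000L, outdir = ".") {
  mode <- match.arg(mode)
  ps <- load_config_or_fail(config)
  if (inherits(ps, "error"))
    return(cmd_fail(2L, conditionMessage(ps)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  cea <- run_cea(ps)
  cea_df <- data.frame(
    arm = c("ctdna_guided", "standard_of_care"),
    cost = c(cea$intervention$cost_total, cea$soc$cost_total),
    qalys = c(cea$intervention$qalys, cea$soc$qalys),
    life_years = c(cea$intervention$life_years, cea$soc$life_years))
  f <- file.path(outdir, "cea_deterministic.csv")
  utils::write.csv(cea_df, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "cea_deterministic.json")
  jsonlite::write_json(list(dc = cea$dc, de = cea$de,
                            icer = cea$icer$value, icer_label = cea$icer$label,
                            inmb = cea$inmb, wtp = cea$wtp),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (mode == "psa") {
    psa <- run_psa(ps, n = n, seed = seed)
    f <- file.path(outdir, "psa_draws.csv")
    utils::write.csv(psa$draws, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(outdir, "psa_summary.csv")
    utils::write.csv(psa_summary_row(psa), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(outdir, "ceac.csv")
    utils::write.csv(psa$ceac, f, row.names = FALSE)
    files <- c(files, f)
    for (nm in c("ce_plane", "ceac")) {
      p <- if (nm == "ce_plane") plot_ce_plane(psa) else plot_ceac(psa)
      f <- file.path(outdir, paste0(nm, ".png"))
      ggplot2::ggsave(f, p, width = 6, height = 4.5, dpi = 150)
      files <- c(files, f)
    }
  }
  files <- c(files, write_manifest(outdir, config, seed,
                                   if (mode == "psa") n else 0L, files))
  cmd_ok(files)
}

#' Run the base case plus the four scenario analyses
#'
#' Writes a five-row scenario table (arm costs and QALYs with percentile
#' intervals, ICER, probability cost-effective) in the layout of the
#' analysis' scenario table.
#'
#' @param config Path to a YAML parameter file.
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n PSA iterations per row.
#' @param scenario_dir Directory holding the scenario overlay files.
#' @return A `cmd_status` object.
#' @export
cmd_scenarios <- function(config, outdir = ".", seed = 1L, n = 1000L,
                          scenario_dir = system.file("extdata",
                                                     package = "ctdnaCEA")) {
  ps <- load_config_or_fail(config)
  if (inherits(ps, "error"))
    return(cmd_fail(2L, conditionMessage(ps)))
  specs <- tryCatch(builtin_scenarios(scenario_dir),
                    error = function(e) e)
  if (inherits(specs, "error"))
    return(cmd_fail(2L, conditionMessage(specs)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- run_psa(ps, n = n, seed = seed)
  rows <- list(psa_summary_row(base, "base_case"))
  for (sp in specs)
    rows <- c(rows, list(run_scenario(ps, sp, n_psa = n, seed = seed)$row))
  tab <- do.call(rbind, rows)
  f <- file.path(outdir, "scenario_table.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(f, write_manifest(outdir, config, seed, n, f))
  cmd_ok(files)
}

#' Run the one-way sensitivity analysis
#'
#' @param config Path to a YAML parameter file.
#' @param ranges Optional CSV with columns `name`, `lo`, `hi`; defaults to
#'   [default_owsa_specs()].
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param n PSA iterations per endpoint.
#' @param deterministic Use deterministic endpoints.
#' @return A `cmd_status` object.
#' @export
cmd_owsa <- function(config, ranges = NULL, outdir = ".", seed = 1L,
                     n = 1000L, deterministic = FALSE) {
  ps <- load_config_or_fail(config)
  if (inherits(ps, "error"))
    return(cmd_fail(2L, conditionMessage(ps)))
  specs <- if (is.null(ranges)) default_owsa_specs(ps)
           else tryCatch(utils::read.csv(ranges, stringsAsFactors = FALSE),
                         error = function(e) e)
  if (inherits(specs, "error"))
    return(cmd_fail(2L, conditionMessage(specs)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tor <- run_owsa(ps, specs, n_psa = n, seed = seed,
                  deterministic = deterministic)
  f_csv <- file.path(outdir, "tornado.csv")
  df <- as.data.frame(tor)
  df$base_inmb <- attr(tor, "base_inmb")
  utils::write.csv(df, f_csv, row.names = FALSE)
  f_png <- file.path(outdir, "tornado.png")
  ggplot2::ggsave(f_png, plot_tornado(tor), width = 6, height = 4, dpi = 150)
  files <- c(f_csv, f_png,
             write_manifest(outdir, config, seed, n, c(f_csv, f_png)))
  cmd_ok(files)
}
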