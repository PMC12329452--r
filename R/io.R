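#' Write simulation samples with a metadata sidecar
#'
#' Writes the accepted step-time vectors as CSV (one row per successful
#' planet, columns `t_1..t_n`) and the run metadata — mode, seed, model
#' parameters, planets simulated, acceptance fraction, package version —
#' as a JSON sidecar, so a run is reproducible from its metadata record
#' alone.
#'
#' @param result A `"simulation_result"`.
#' @param dir Output directory (created if needed).
#' @param basename File stem; writes `<basename>.csv` and
#'   `<basename>_meta.json`.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(result, dir, basename = "samples") {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(basename, ".csv"))
  meta <- file.path(dir, paste0(basename, "_meta.json"))
  utils::write.csv(as.data.frame(result$samples), csv, row.names = FALSE)
  jsonlite::write_json(
    simulation_metadata(result), meta,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(c(samples = csv, metadata = meta))
}

simulation_metadata <- function(result) {
  m <- result$model
  list(
    package = "hardsteps",
    version = as.character(utils::packageVersion("hardsteps")),
    mode = result$mode,
    seed = result$seed,
    model = list(n = m$n, t_h = m$t_h, delays = m$delays,
                 Delta = m$Delta),
    rates = if (!is.null(result$config)) result$config$rates,
    n_accepted = nrow(result$samples),
    planets_simulated = result$planets_simulated,
    acceptance_fraction = result$acceptance_fraction,
    truncated = result$truncated
  )
}

#' Write a fit profile and result
#'
#' The per-`n` profile goes to CSV and the fit result (scenario
#' parameters, `n_best`, `n_star`, method, package version) to JSON.
#'
#' @param fit A `"hardsteps_fit"`.
#' @param dir Output directory (created if needed).
#' @param basename File stem; writes `<basename>_profile.csv` and
#'   `<basename>.json`.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, basename = "fit") {
  stopifnot(inherits(fit, "hardsteps_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(basename, "_profile.csv"))
  json <- file.path(dir, paste0(basename, ".json"))
  utils::write.csv(fit$profile, csv, row.names = FALSE)
  jsonlite::write_json(
    list(package = "hardsteps",
         version = as.character(utils::packageVersion("hardsteps")),
         name = fit$name, method = fit$method, t_obs = fit$t_obs,
         t_h = fit$t_h, Delta = fit$Delta, n_best = fit$n_best,
         n_star = fit$n_star),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(profile = csv, fit = json))
}

#' Read a run configuration file
#'
#' Configuration files are YAML with a JSON-compatible schema: flat
#' keys matching the command-line flag names (e.g. `t_h`, `t_obs`,
#' `delta`, `rates`, `samples`, `seed`).  Command-line flags override
#' file values.
#'
#' @param path Path to a YAML (or JSON) config file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  # YAML 1.1 would read the bare key `n` as a boolean; keep the
  # single-letter spellings literal so `n: 4` means what it says
  keep_letter <- function(x, to) {
    if (x %in% c("y", "Y", "n", "N")) x else to
  }
  cfg <- yaml::read_yaml(
    path,
    handlers = list(
      "bool#yes" = function(x) keep_letter(x, TRUE),
      "bool#no" = function(x) keep_letter(x, FALSE)
    )
  )
  if (!is.list(cfg)) {
    stop("config file must contain a mapping of option names to values",
         call. = FALSE)
  }
  cfg
}
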