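#' The catalogue of Earth scenarios
#'
#' Four pre-parameterised Earth cases, all durations in Gyr:
#'
#' * `carter_1983` — the original parameterisation: habitable lifetime
#'   `t_h = 10` (the Sun's main-sequence lifetime), human emergence at
#'   `t_obs = 4.5`, no delays.
#' * `modern_th` — the revised habitable lifetime: emergence at 0.8 of
#'   the habitable window with `t_h = 5.7`, so `t_obs = 4.56`, no
#'   delays.
#' * `delayed` — as `modern_th` but with a cumulative forbidden time
#'   `Delta = 1.5` Gyr of whole Earth-system reorganisation, split as
#'   0.5 Gyr between oxygenic photosynthesis and the Great Oxidation
#'   Event and 1.0 Gyr between eukaryogenesis and the late-Proterozoic
#'   transitions.  Only `Delta` enters the expectation formula; the
#'   split matters only when visualising simulated step times.
#' * `revised_th_6` — the upper end of the revised 5-6 Gyr lifetime
#'   range: `t_h = 6`, emergence at `t_obs = 4.5`, no delays.
#'
#' A note on `t_obs`: emergence at 0.8 of the habitable lifetime
#' together with `t_h = 5.7` gives `t_obs = 4.56` Gyr, slightly above
#' the 4.5 Gyr age of the Earth (4.5 / 0.8 would give `t_h = 5.625`).
#' The catalogue keeps `0.8 * 5.7 = 4.56` for the modern scenarios and
#' records the discrepancy here rather than resolving it.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
earth_scenarios <- function() {
  list(
    carter_1983 = scenario_spec("carter_1983", t_obs = 4.5, t_h = 10,
                                Delta = 0),
    modern_th = scenario_spec("modern_th", t_obs = 0.8 * 5.7, t_h = 5.7,
                              Delta = 0),
    delayed = scenario_spec("delayed", t_obs = 0.8 * 5.7, t_h = 5.7,
                            Delta = 1.5),
    revised_th_6 = scenario_spec("revised_th_6", t_obs = 4.5, t_h = 6,
                                 Delta = 0)
  )
}

# Delta = 1.5 Gyr split used by the delayed scenario when a full delay
# vector is needed (simulation/visualisation): GOE then Proterozoic.
delayed_scenario_delays <- c(goe = 0.5, proterozoic = 1.0)

#' Fit the step count for every Earth scenario
#'
#' Runs [fit_n_expectation()] on each catalogue entry and tabulates the
#' results.  Fully deterministic: the report is identical across runs.
#'
#' @param scenarios List of [scenario_spec()]s (default
#'   [earth_scenarios()]).
#' @return Data frame with columns `name`, `t_obs`, `t_h`, `Delta`,
#'   `n_best`, `n_star`.
#' @examples
#' run_earth_scenarios()
#' @export
run_earth_scenarios <- function(scenarios = earth_scenarios()) {
  fits <- lapply(scenarios, fit_n_expectation)
  data.frame(
    name = vapply(fits, `[[`, character(1), "name"),
    t_obs = vapply(fits, `[[`, numeric(1), "t_obs"),
    t_h = vapply(fits, `[[`, numeric(1), "t_h"),
    Delta = vapply(fits, `[[`, numeric(1), "Delta"),
    n_best = vapply(fits, `[[`, integer(1), "n_best"),
    n_star = vapply(fits, `[[`, numeric(1), "n_star"),
    row.names = NULL
  )
}

#' Tabulate the conditional step-time densities
#'
#' Long-format table of the conditional density of every step
#' `m = 1..n` for each requested `n`, on an even grid of `t / t_h` over
#' `[0, 1]` — the data behind the classic family of curves showing that
#' for longer sequences the last step crowds toward the end of the
#' habitable lifetime.
#'
#' @param n_values Step counts to tabulate (subset of 1..10; default
#'   1:4).
#' @param grid_points Number of evenly spaced grid points on `[0, 1]`
#'   (>= 2; default 201).
#' @return Data frame with columns `n`, `m`, `t_frac` (time as a
#'   fraction of the habitable lifetime) and `density` (in units of
#'   1 / t_h).
#' @examples
#' head(figure1_table(n_values = 2, grid_points = 5))
#' @export
figure1_table <- function(n_values = 1:4, grid_points = 201L) {
  if (any(!is.finite(n_values)) || any(n_values < 1 | n_values > 10) ||
      any(n_values != round(n_values))) {
    stop("`n_values` must be integers in 1..10", call. = FALSE)
  }
  if (grid_points < 2 || grid_points != round(grid_points)) {
    stop("`grid_points` must be an integer >= 2", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = grid_points)
  rows <- list()
  for (n in as.integer(n_values)) {
    for (m in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, m = m, t_frac = grid,
        density = step_time_pdf(m, n, 1, grid)
      )
    }
  }
  do.call(rbind, rows)
}
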