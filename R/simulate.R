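#' Configure a Monte Carlo run
#'
#' Bundles everything a simulation needs: the model, the sampling mode,
#' per-step occurrence rates (rejection mode only), the requested number
#' of accepted successful-planet samples, a cap on the number of planets
#' simulated, and the RNG seed.
#'
#' Two modes are available.  `"exact_lowrate"` (the default) draws
#' directly from the conditional law in the hard-step limit
#' `lambda * t_h -> 0` and needs no rates; it is exact in that limit and
#' costs one sort per sample.  `"rejection"` simulates planets forward
#' — sequential exponential waiting times, step m at
#' `t_(m-1) + delay_(m-1) + Exponential(lambda_m)` — and keeps only
#' planets whose last step lands within `t_h`.  At realistically hard
#' rates the acceptance probability is astronomically small (see
#' [completion_probability_lowrate()]), so rejection mode is intended
#' for validation at moderate rates and refuses to run when the
#' projected acceptance falls below `acceptance_floor`.
#'
#' @param model A [hard_steps_model()].
#' @param mode `"exact_lowrate"` or `"rejection"`.
#' @param rates Numeric vector of `n` positive per-step rates
#'   (probability per unit time); required in rejection mode.
#' @param n_target Number of accepted samples requested (>= 1).
#' @param max_planets Cap on planets simulated in rejection mode.
#' @param seed Integer RNG seed, recorded in all outputs.
#' @param acceptance_floor Refuse rejection runs whose projected
#'   acceptance probability is below this (default 1e-9).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(model,
                              mode = c("exact_lowrate", "rejection"),
                              rates = NULL,
                              n_target = 1000L,
                              max_planets = 1e8,
                              seed = 1L,
                              acceptance_floor = 1e-9) {
  stopifnot(inherits(model, "hard_steps_model"))
  mode <- match.arg(mode)
  if (!is.numeric(n_target) || length(n_target) != 1L || n_target < 1 ||
      n_target != round(n_target)) {
    stop("`n_target` must be a positive integer", call. = FALSE)
  }
  if (mode == "rejection") {
    if (is.null(rates)) {
      stop("rejection mode requires per-step `rates`", call. = FALSE)
    }
    if (length(rates) != model$n || any(!is.finite(rates)) ||
        any(rates <= 0)) {
      stop("`rates` must be ", model$n, " positive finite numbers",
           call. = FALSE)
    }
  }
  structure(
    list(model = model, mode = mode, rates = rates,
         n_target = as.integer(n_target), max_planets = max_planets,
         seed = seed, acceptance_floor = acceptance_floor),
    class = "simulation_config"
  )
}

#' Run a configured simulation
#'
#' Dispatches on `config$mode` to [simulate_rejection()] or
#' [sample_conditional_exact()].
#'
#' @param config A [simulation_config()].
#' @param verbose Log batch progress to stderr (rejection mode).
#' @return A `"simulation_result"`; see [simulate_rejection()].
#' @export
simulate_hard_steps <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$mode == "rejection") {
    simulate_rejection(config, verbose = verbose)
  } else {
    sample_conditional_exact(config$model, config$n_target,
                             seed = config$seed, config = config)
  }
}

#' Rejection sampler over a planet population
#'
#' Simulates the forward model planet by planet: step m occurs at
#' `t_(m-1) + delay_(m-1) + Exponential(lambda_m)` (with `t_0 = 0`), and
#' a planet is accepted iff its last step lands within the habitable
#' lifetime.  Returns the accepted step-time vectors together with the
#' number of planets simulated and the acceptance fraction — the
#' observer-self-selection bookkeeping made explicit.
#'
#' Planets are processed in large vectorised batches.  Within a batch
#' the first-step filter is applied analytically: the number of planets
#' whose first step falls inside its feasibility window is drawn as a
#' binomial count and their times by inverse-CDF sampling of the
#' truncated exponential, after which steps 2..n are drawn literally as
#' exponential waits with early pruning of planets that have already
#' overrun.  This is distributionally identical to a per-planet loop
#' (same joint law of accepted rows and acceptance count) and makes
#' acceptance probabilities down to ~1e-8 tractable.  Because planets
#' within a batch are exchangeable, the sampler returns *all* accepted
#' rows from the batches it processed — at least `n_target` on success —
#' so that `acceptance_fraction * planets_simulated` equals the number
#' of rows exactly.
#'
#' If the projected acceptance probability (leading-order, capped at 1)
#' is below `config$acceptance_floor` the sampler refuses and suggests
#' the exact low-rate sampler instead.
#'
#' @param config A [simulation_config()] with `mode = "rejection"`.
#' @param verbose Log batch progress to stderr.
#' @return An object of class `"simulation_result"`: list with `samples`
#'   (matrix, one row per accepted planet, columns `t_1..t_n`),
#'   `planets_simulated`, `acceptance_fraction`, `truncated` (TRUE if
#'   `max_planets` was hit first), `mode`, `seed`, `config`.
#' @examples
#' cfg <- simulation_config(hard_steps_model(1, 1), mode = "rejection",
#'                          rates = 5, n_target = 1000, seed = 42)
#' res <- simulate_rejection(cfg)
#' res$acceptance_fraction   # close to 1 - exp(-5)
#' @export
simulate_rejection <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$mode != "rejection") {
    stop("config mode is not \"rejection\"", call. = FALSE)
  }
  model <- config$model
  rates <- config$rates
  n <- model$n
  t_h <- model$t_h
  delays <- model$delays

  p_proj <- min(1, completion_probability_lowrate(model, rates))
  if (p_proj < config$acceptance_floor) {
    stop("projected acceptance probability ", format(p_proj, digits = 3),
         " is below the floor ", format(config$acceptance_floor),
         "; use the exact low-rate sampler (mode = \"exact_lowrate\") ",
         "instead", call. = FALSE)
  }

  # a planet can only ever be accepted if step m clears the forbidden
  # time still owed to the remaining steps
  cdel <- c(0, cumsum(delays))            # cum_delay(1..n)
  thresh <- t_h - (model$Delta - cdel)    # per-step pruning thresholds
  p1 <- stats::pexp(thresh[1], rate = rates[1])

  n_target <- config$n_target
  acc <- vector("list", 0L)
  n_acc <- 0
  done <- 0
  with_seed(config$seed, {
    while (n_acc < n_target && done < config$max_planets) {
      # size the batch so expected first-step survivors stay ~<= 2e6
      want <- ceiling(1.5 * (n_target - n_acc) / max(p_proj, 1e-12))
      batch <- min(config$max_planets - done, max(1e5, want),
                   ceiling(2e6 / max(p1, 2e-9)), 1e9)
      batch <- floor(batch)
      k <- stats::rbinom(1L, size = batch, prob = p1)
      done <- done + batch
      if (k > 0) {
        tm <- stats::qexp(stats::runif(k) * p1, rate = rates[1])
        mat <- matrix(tm, ncol = 1L)
        m <- 2L
        while (m <= n && nrow(mat) > 0L) {
          tm <- mat[, m - 1L] + delays[m - 1L] +
            stats::rexp(nrow(mat), rate = rates[m])
          keep <- tm <= thresh[m]
          mat <- cbind(mat[keep, , drop = FALSE], tm[keep])
          m <- m + 1L
        }
        if (nrow(mat) > 0L) {
          acc[[length(acc) + 1L]] <- mat
          n_acc <- n_acc + nrow(mat)
        }
      }
      if (verbose) {
        message(sprintf("simulated %.3g planets, accepted %d", done, n_acc))
      }
    }
  })

  samples <- if (n_acc > 0) do.call(rbind, acc) else matrix(numeric(0), 0L, n)
  colnames(samples) <- paste0("t_", seq_len(n))
  truncated <- n_acc < n_target
  if (truncated) {
    warning("max_planets reached with only ", n_acc, " of ", n_target,
            " requested samples accepted", call. = FALSE)
  }
  new_simulation_result(samples, model = model, mode = "rejection",
                        seed = config$seed, planets_simulated = done,
                        acceptance_fraction = n_acc / done,
                        truncated = truncated, config = config)
}

#' Exact conditional sampler in the hard-step limit
#'
#' Draws conditioned step-time vectors directly, without rejection.  In
#' the limit where every rate satisfies `lambda * t_h -> 0`, the
#' conditional joint density of the step times given that all steps
#' complete within `t_h` is uniform over the feasible ordered region, so
#' a sample is obtained by drawing `n` iid uniforms on
#' `[0, t_h - Delta]`, sorting them, and adding to the m-th order
#' statistic the cumulative forbidden time preceding step m.  Every row
#' satisfies the ordering-and-gap constraints by construction.
#'
#' @param model A [hard_steps_model()].
#' @param n_samples Number of conditioned samples to draw.
#' @param seed Integer RNG seed (`NULL` uses the current RNG stream).
#' @param config Optional [simulation_config()] to echo in the result.
#' @return A `"simulation_result"` (no acceptance bookkeeping: every
#'   draw is a successful planet).
#' @examples
#' res <- sample_conditional_exact(hard_steps_model(4, 1), 1e4, seed = 1)
#' colMeans(res$samples)  # close to (1, 2, 3, 4) / 5
#' @export
sample_conditional_exact <- function(model, n_samples, seed = NULL,
                                     config = NULL) {
  stopifnot(inherits(model, "hard_steps_model"))
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  n <- model$n
  span <- model$t_h - model$Delta
  u <- with_seed(seed, matrix(stats::runif(n_samples * n, 0, span),
                              nrow = n_samples, ncol = n))
  if (n > 1L) {
    u <- matrix(u[order(row(u), u)], nrow = n_samples, ncol = n,
                byrow = TRUE)
    cdel <- c(0, cumsum(model$delays))
    u <- u + rep(cdel, each = n_samples)
  }
  colnames(u) <- paste0("t_", seq_len(n))
  new_simulation_result(u, model = model, mode = "exact_lowrate",
                        seed = seed, planets_simulated = n_samples,
                        acceptance_fraction = NA_real_, truncated = FALSE,
                        config = config)
}

new_simulation_result <- function(samples, model, mode, seed,
                                  planets_simulated, acceptance_fraction,
                                  truncated, config) {
  structure(
    list(samples = samples, model = model, mode = mode, seed = seed,
         planets_simulated = planets_simulated,
         acceptance_fraction = acceptance_fraction,
         truncated = truncated, config = config),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Hard-steps simulation (", x$mode, " mode)\n", sep = "")
  cat("  accepted samples:  ", nrow(x$samples), "\n", sep = "")
  cat("  planets simulated: ", format(x$planets_simulated), "\n", sep = "")
  if (!is.na(x$acceptance_fraction)) {
    cat("  acceptance:        ",
        format(x$acceptance_fraction, digits = 4), "\n", sep = "")
  }
  cat("  seed:              ", format(x$seed), "\n", sep = "")
  invisible(x)
}

#' Summarise conditioned step times
#'
#' Per-step mean, standard deviation, Monte Carlo standard error of the
#' mean, and selected quantiles of the accepted step-time vectors.
#'
#' @param object A `"simulation_result"`.
#' @param probs Quantile probabilities to report.
#' @param ... Unused.
#' @return A data frame with one row per step and the
#'   `acceptance_fraction` attached as an attribute when applicable.
#' @export
summary.simulation_result <- function(object,
                                      probs = c(0.025, 0.25, 0.5,
                                                0.75, 0.975),
                                      ...) {
  s <- object$samples
  if (nrow(s) == 0L) {
    stop("no accepted samples to summarise", call. = FALSE)
  }
  sds <- if (nrow(s) == 1L) rep(0, ncol(s)) else apply(s, 2, stats::sd)
  qs <- t(apply(s, 2, stats::quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", probs * 100)
  out <- data.frame(
    step = seq_len(ncol(s)),
    mean = unname(colMeans(s)),
    sd = sds,
    se = sds / sqrt(nrow(s)),
    qs,
    row.names = NULL,
    check.names = FALSE
  )
  attr(out, "n_samples") <- nrow(s)
  attr(out, "acceptance_fraction") <- object$acceptance_fraction
  out
}
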