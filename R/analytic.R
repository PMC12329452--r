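#' Expected time of the m-th of n hard steps
#'
#' On the rare subset of planets where all `n` hard steps complete
#' within the habitable lifetime `t_h`, the conditional distribution of
#' the m-th step time is Beta(m, n - m + 1) scaled to `[0, t_h]`
#' (see [step_time_pdf()]), so its expectation is
#' `m * t_h / (n + 1)`: the steps fall, on average, evenly spaced
#' through the habitable window.
#'
#' @param m Step index, `1 <= m <= n` (vectorised over `m`).
#' @param n Total number of hard steps.
#' @param t_h Habitable lifetime (> 0).
#' @return Expected occurrence time(s), same unit as `t_h`.
#' @examples
#' expected_step_time(4, 4, 5.7)   # 4.56 = 0.8 * t_h
#' expected_step_time(1:3, 3, 1)   # evenly spaced: 0.25 0.50 0.75
#' @export
expected_step_time <- function(m, n, t_h) {
  check_mn(m, n)
  check_th(t_h)
  m * t_h / (n + 1)
}

#' Expected time of the last step under Earth-system delays
#'
#' In the delayed hard-steps model, each of the first `n - 1` steps may
#' be followed by a "forbidden" period during which the next step cannot
#' occur; `Delta` is the cumulative total of those periods.  Conditional
#' on all `n` steps completing within `t_h`, the expected time of the
#' last step is `(n * t_h + Delta) / (n + 1)`.  With `Delta = 0` this
#' reduces to [expected_step_time()] with `m = n`.
#'
#' The result follows from a shifted order-statistics construction: in
#' the low-rate limit the step times minus their accumulated preceding
#' delays are distributed as the order statistics of `n` iid uniforms on
#' `[0, t_h - Delta]`, so the last step occurs at
#' `n * (t_h - Delta) / (n + 1) + Delta`.
#'
#' @param n Number of hard steps (>= 1, vectorised).
#' @param t_h Habitable lifetime (> 0).
#' @param Delta Cumulative forbidden time over the `n - 1` earlier
#'   steps, `0 <= Delta < t_h`.
#' @return Expected last-step time(s).
#' @examples
#' expected_last_step_delayed(3, 5.7, 1.5)  # 4.65
#' expected_last_step_delayed(4, 5.7, 0)    # 4.56, same as Eq. without delays
#' @export
expected_last_step_delayed <- function(n, t_h, Delta = 0) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  check_th(t_h)
  if (!is.numeric(Delta) || any(!is.finite(Delta)) || any(Delta < 0)) {
    stop("`Delta` must be a non-negative number", call. = FALSE)
  }
  if (any(Delta >= t_h)) {
    stop("infeasible model: Delta >= t_h admits no successful planet",
         call. = FALSE)
  }
  (n * t_h + Delta) / (n + 1)
}

#' Conditional density, distribution and quantile of the m-th step time
#'
#' Conditional on all `n` hard steps occurring within `[0, t_h]` (and no
#' delays), the m-th step time has density proportional to
#' `t^(m-1) * (t_h - t)^(n-m)`; equivalently `t / t_h` follows a
#' Beta(m, n - m + 1) law.  `step_time_pdf` evaluates the normalised
#' density, `step_time_cdf` the distribution function, and
#' `step_time_quantile` its inverse.
#'
#' By convention the density is 0 (and the cdf 0 or 1) outside
#' `[0, t_h]` rather than an error, which keeps quadrature and plotting
#' code simple.  The quantile is Newton-polished so that
#' `cdf(quantile(p)) = p` to ~1e-12; on the time scale the inversion is
#' limited by the precision of `p` itself where the cdf saturates near
#' 1.
#'
#' @param m Step index, `1 <= m <= n`.
#' @param n Total number of hard steps.
#' @param t_h Habitable lifetime (> 0).
#' @param t Time(s) at which to evaluate (vectorised).
#' @param p Probability(ies) in `[0, 1]` (vectorised).
#' @return `step_time_pdf`: density values (unit 1/time);
#'   `step_time_cdf`: probabilities; `step_time_quantile`: times in
#'   `[0, t_h]`.
#' @examples
#' step_time_pdf(1, 1, 2, 1.3)        # uniform: 0.5 anywhere in [0, 2]
#' step_time_cdf(2, 3, 1, 0.5)        # symmetric about the midpoint: 0.5
#' step_time_quantile(4, 4, 5.7, 0.5) # median of the last of four steps
#' @export
step_time_pdf <- function(m, n, t_h, t) {
  check_mn(m, n)
  check_th(t_h)
  out <- numeric(length(t))
  inside <- is.finite(t) & t >= 0 & t <= t_h
  out[inside] <- stats::dbeta(t[inside] / t_h, m, n - m + 1) / t_h
  out
}

#' @rdname step_time_pdf
#' @export
step_time_cdf <- function(m, n, t_h, t) {
  check_mn(m, n)
  check_th(t_h)
  stats::pbeta(pmin(pmax(t / t_h, 0), 1), m, n - m + 1)
}

#' @rdname step_time_pdf
#' @export
step_time_quantile <- function(m, n, t_h, p) {
  check_mn(m, n)
  check_th(t_h)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  x <- stats::qbeta(p, m, n - m + 1)
  # polish qbeta with a few Newton steps so the inverse holds to ~1e-12
  for (i in 1:3) {
    d <- stats::dbeta(x, m, n - m + 1)
    f <- stats::pbeta(x, m, n - m + 1) - p
    x <- pmin(pmax(x - ifelse(d > 0, f / d, 0), 0), 1)
  }
  t_h * x
}

#' Leading-order probability that all steps complete in time
#'
#' Each hard step, once its predecessor (and any following forbidden
#' period) is complete, occurs with a very low uniform probability per
#' unit time `lambda_i`.  To leading order in `lambda_i * t_h` (the
#' hard-step regime, `lambda_i * t_h << 1`), the per-planet probability
#' that all `n` steps complete within the habitable lifetime is
#'
#'   `prod(lambda) * (t_h - Delta)^n / n!`
#'
#' — the volume of the ordered feasible region times the product of the
#' rates.  This is the acceptance probability the rejection sampler
#' faces, and the reason naive forward simulation of realistic hard
#' steps is astronomically wasteful.
#'
#' @param model A [hard_steps_model()].
#' @param rates Numeric vector of `n` positive per-step rates
#'   (probability per unit time).
#' @return The leading-order completion probability (0 if no feasible
#'   time remains).
#' @examples
#' completion_probability_lowrate(hard_steps_model(2, 1), c(1e-3, 1e-3))
#' @export
completion_probability_lowrate <- function(model, rates) {
  stopifnot(inherits(model, "hard_steps_model"))
  if (length(rates) != model$n || any(!is.finite(rates)) || any(rates <= 0)) {
    stop("`rates` must be ", model$n, " positive finite numbers",
         call. = FALSE)
  }
  span <- model$t_h - model$Delta
  if (span <= 0) {
    return(0)
  }
  # log-space product guards against underflow for many very hard steps
  exp(sum(log(rates)) + model$n * log(span) - lgamma(model$n + 1))
}

check_mn <- function(m, n) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 1) || any(m > n) || any(m != round(m))) {
    stop("`m` must be an integer in 1..n", call. = FALSE)
  }
  invisible(TRUE)
}

check_th <- function(t_h) {
  if (!is.numeric(t_h) || any(!is.finite(t_h)) || any(t_h <= 0)) {
    stop("`t_h` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}
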