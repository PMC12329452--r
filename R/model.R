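#' Hard-steps model specification
#'
#' Bundle the parameters of a hard-steps model: the number of steps `n`,
#' the habitable lifetime `t_h`, and optional "forbidden" periods
#' (Earth-system reorganisation delays) following each of the first
#' `n - 1` steps, during which the next step cannot occur.
#'
#' Durations are plain numbers; the canonical unit is Gyr, but every
#' operation in the package is scale invariant, so `t_h = 1`
#' (dimensionless mode, times as fractions of the habitable lifetime)
#' works equally well.
#'
#' A model whose cumulative delay `Delta = sum(delays)` reaches or
#' exceeds `t_h` admits no successful planet at all (no time remains in
#' which the steps themselves can occur) and is rejected at
#' construction.  `Delta == t_h` is a probability-zero boundary and is
#' treated as infeasible too.
#'
#' @param n Positive integer, number of hard steps.
#' @param t_h Positive number, habitable lifetime.
#' @param delays Numeric vector of length `n - 1` of non-negative
#'   forbidden periods; `delays[i]` follows step `i`.  `NULL` (default)
#'   means no delays.
#' @return An object of class `"hard_steps_model"`: a list with fields
#'   `n`, `t_h`, `delays` and `Delta` (the cumulative delay).
#' @examples
#' hard_steps_model(4, 5.7)
#' hard_steps_model(3, 5.7, delays = c(0.5, 1.0))
#' @seealso [cum_delay()], [expected_last_step_delayed()],
#'   [sample_conditional_exact()]
#' @export
hard_steps_model <- function(n, t_h, delays = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(t_h) || length(t_h) != 1L || !is.finite(t_h) || t_h <= 0) {
    stop("`t_h` must be a single positive number", call. = FALSE)
  }
  if (is.null(delays)) {
    delays <- numeric(max(n - 1L, 0L))
  }
  delays <- as.numeric(delays)
  if (length(delays) != n - 1L) {
    stop("`delays` must have length n - 1 (one forbidden period after ",
         "each of the first n - 1 steps)", call. = FALSE)
  }
  if (any(!is.finite(delays)) || any(delays < 0)) {
    stop("all forbidden periods must be finite and non-negative",
         call. = FALSE)
  }
  Delta <- sum(delays)
  if (Delta >= t_h) {
    stop("infeasible model: cumulative delay Delta = ", format(Delta),
         " >= t_h = ", format(t_h),
         " leaves no time for the steps to occur", call. = FALSE)
  }
  structure(
    list(n = n, t_h = t_h, delays = delays, Delta = Delta),
    class = "hard_steps_model"
  )
}

#' Cumulative forbidden time preceding a step
#'
#' The total forbidden time accumulated before step `m` may occur:
#' `sum(delays[1..(m-1)])`.  `cum_delay(model, 1)` is 0 and
#' `cum_delay(model, n)` equals the total delay `Delta`.
#'
#' @param model A [hard_steps_model()].
#' @param m Step index (vectorised), `1 <= m <= n`.
#' @return Numeric vector of cumulative delays.
#' @export
cum_delay <- function(model, m) {
  stopifnot(inherits(model, "hard_steps_model"))
  if (any(m < 1 | m > model$n | m != round(m))) {
    stop("`m` must be an integer in 1..n", call. = FALSE)
  }
  cs <- c(0, cumsum(model$delays))
  cs[as.integer(m)]
}

#' @export
print.hard_steps_model <- function(x, ...) {
  cat("Hard-steps model\n")
  cat("  steps (n):          ", x$n, "\n", sep = "")
  cat("  habitable lifetime: ", format(x$t_h), "\n", sep = "")
  if (x$Delta > 0) {
    cat("  forbidden periods:  ", paste(format(x$delays), collapse = ", "),
        " (Delta = ", format(x$Delta), ")\n", sep = "")
  } else {
    cat("  forbidden periods:  none\n")
  }
  invisible(x)
}

# Internal: run `expr` under a seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
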