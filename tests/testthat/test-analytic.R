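test_that("expected step times are evenly spaced through the window", {
  expect_equal(expected_step_time(4, 4, 5.7), 4.56)     # 0.8 * t_h
  expect_equal(expected_step_time(1, 1, 10), 5)         # midpoint
  expect_equal(expected_step_time(2, 3, 1), 0.5)        # centre by symmetry
  expect_equal(expected_step_time(1:3, 3, 1), c(1, 2, 3) / 4)

  expect_error(expected_step_time(0, 2, 1), "1..n")
  expect_error(expected_step_time(3, 2, 1), "1..n")
  expect_error(expected_step_time(1, 1, 0), "positive")
})

test_that("delayed last-step expectation matches the closed form", {
  expect_equal(expected_last_step_delayed(3, 5.7, 1.5), (3 * 5.7 + 1.5) / 4)
  expect_equal(expected_last_step_delayed(3, 5.7, 1.5), 4.65)
  expect_equal(expected_last_step_delayed(2, 5.7, 1.5), 4.30)
  expect_equal(expected_last_step_delayed(5, 1, 0), 5 / 6)
  # Delta = 0 reduces to the undelayed last step
  for (n in 1:8) {
    expect_equal(expected_last_step_delayed(n, 3.3, 0),
                 expected_step_time(n, n, 3.3))
  }
  expect_error(expected_last_step_delayed(2, 1, 1), "infeasible")
  expect_error(expected_last_step_delayed(2, 1, 1.2), "infeasible")
})

test_that("delayed last-step expectation is monotone and saturates at t_h", {
  t_h <- 5.7
  by_n <- expected_last_step_delayed(1:20, t_h, 1.5)
  expect_true(all(diff(by_n) > 0))
  deltas <- seq(0, 5, by = 0.5)
  by_delta <- expected_last_step_delayed(3, t_h, deltas)
  expect_true(all(diff(by_delta) > 0))
  expect_lt(t_h - expected_last_step_delayed(1e6, t_h, 0), 1e-5)
})

test_that("step-time density matches the normalised Beta form", {
  # single step: uniform over the window
  ts <- c(0, 0.7, 1.9, 2)
  expect_equal(step_time_pdf(1, 1, 2, ts), rep(0.5, 4))
  # first of two: 2(1 - t) on [0, 1], so 2 at the origin; cross-check
  # the normalisation constant by quadrature of the raw kernel
  expect_equal(step_time_pdf(1, 2, 1, 0), 2)
  raw <- stats::integrate(function(t) (1 - t), 0, 1)$value
  expect_equal(step_time_pdf(1, 2, 1, 0.3), (1 - 0.3) / raw, tolerance = 1e-9)
  # mode of t (1-t)^2 is at (m-1)/(n-1) = 1/3
  peak <- stats::optimize(function(t) step_time_pdf(2, 4, 1, t),
                          c(0, 1), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(peak, 1 / 3, tolerance = 1e-6)
  # zero outside the support, by convention
  expect_equal(step_time_pdf(2, 3, 1, c(-0.5, 1.5)), c(0, 0))
  expect_error(step_time_pdf(0, 2, 1, 0.5), "1..n")
  expect_error(step_time_pdf(3, 2, 1, 0.5), "1..n")
})

test_that("densities integrate to one and reproduce the mean, all (m, n)", {
  t_h <- 5.7
  for (n in 1:10) {
    for (m in seq_len(n)) {
      total <- stats::integrate(function(t) step_time_pdf(m, n, t_h, t),
                                0, t_h, rel.tol = 1e-12)$value
      expect_equal(total, 1, tolerance = 1e-8)
      mu <- stats::integrate(function(t) t * step_time_pdf(m, n, t_h, t),
                             0, t_h, rel.tol = 1e-12)$value
      expect_equal(mu, expected_step_time(m, n, t_h), tolerance = 1e-8)
    }
  }
})

test_that("densities obey time-reversal symmetry", {
  t_h <- 2.3
  grid <- seq(0, t_h, length.out = 41)
  for (n in c(1, 2, 3, 4, 7)) {
    for (m in seq_len(n)) {
      expect_equal(step_time_pdf(m, n, t_h, grid),
                   step_time_pdf(n - m + 1, n, t_h, t_h - grid))
    }
  }
})

test_that("cdf and quantile are consistent inverses", {
  expect_equal(step_time_cdf(1, 1, 1, 0.25), 0.25)
  expect_equal(step_time_cdf(2, 3, 1, 0.5), 0.5)   # symmetric density
  expect_equal(step_time_cdf(2, 3, 1, c(-1, 0, 1, 2)), c(0, 0, 1, 1))
  grid <- seq(0.05, 5.65, length.out = 25)
  for (n in c(1, 3, 6)) {
    for (m in seq_len(n)) {
      p <- step_time_cdf(m, n, 5.7, grid)
      expect_true(all(diff(p) >= 0))
      # probability-scale inverse holds everywhere ...
      expect_equal(step_time_cdf(m, n, 5.7,
                                 step_time_quantile(m, n, 5.7, p)),
                   p, tolerance = 1e-10)
      # ... and the time-scale round trip wherever the cdf is not
      # saturated (1 - p above machine-precision loss in the far tail)
      ok <- p <= 1 - 1e-9
      expect_equal(step_time_quantile(m, n, 5.7, p[ok]), grid[ok],
                   tolerance = 1e-10)
    }
  }
  expect_error(step_time_quantile(1, 2, 1, 1.5), "\\[0, 1\\]")
  expect_error(step_time_quantile(1, 2, 1, -0.1), "\\[0, 1\\]")
})

test_that("low-rate completion probability matches brute-force integration", {
  # one step: leading order is just lambda * t_h
  expect_equal(
    completion_probability_lowrate(hard_steps_model(1, 1), 1e-3), 1e-3)
  # two steps: compare with the exact sequential-event probability,
  # P(T1 + T2 <= t_h), computed by nested numerical integration
  lam <- c(1e-3, 1e-3)
  approx <- completion_probability_lowrate(hard_steps_model(2, 1), lam)
  expect_equal(approx, 5e-7)
  exact <- stats::integrate(function(t1) {
    vapply(t1, function(a) {
      lam[1] * exp(-lam[1] * a) *
        stats::integrate(function(t2) lam[2] * exp(-lam[2] * (t2 - a)),
                         a, 1, rel.tol = 1e-12)$value
    }, numeric(1))
  }, 0, 1, rel.tol = 1e-12)$value
  expect_equal(approx, exact, tolerance = 2e-3)
  # heterogeneous rates enter through their product
  m3 <- hard_steps_model(3, 2)
  expect_equal(completion_probability_lowrate(m3, c(2e-3, 5e-4, 1e-3)),
               prod(c(2e-3, 5e-4, 1e-3)) * 2^3 / 6)
  expect_error(completion_probability_lowrate(m3, c(1e-3, 1e-3)),
               "positive finite")
})

test_that("low-rate completion probability predicts the acceptance rate", {
  model <- hard_steps_model(2, 1)
  rates <- c(0.01, 0.01)
  p_pred <- completion_probability_lowrate(model, rates)
  cfg <- simulation_config(model, mode = "rejection", rates = rates,
                           n_target = 400, max_planets = 1e9, seed = 11)
  res <- simulate_rejection(cfg)
  se <- sqrt(p_pred * (1 - p_pred) / res$planets_simulated)
  expect_lt(abs(res$acceptance_fraction - p_pred), 3 * se)
})
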