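# Shared helpers: Monte Carlo tolerance bands.

# three standard errors of the mean of `x`
mc_band <- function(x) 3 * stats::sd(x) / sqrt(length(x))

expect_within_3se <- function(x, target) {
  expect_lt(abs(mean(x) - target), mc_band(x))
}
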