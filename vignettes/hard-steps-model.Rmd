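---
title: "The hard-steps model: theory, simulators and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hard-steps model: theory, simulators and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hardsteps)
```

## The model and its assumptions

Consider a large population of planets, each habitable for complex
life for a period $t_h$.  Evolution towards a property of interest
(for Earth: intelligent observers) requires a fixed sequence of $n$
*hard steps*.  The assumptions are deliberately few:

1. Step $m$ can occur only after step $m-1$ is complete.
2. Once available, a step occurs with a uniform probability per unit
   time $\lambda_m$ (a Poisson clock).
3. Every step is *hard*: $\lambda_m t_h \ll 1$, so on almost all
   planets the sequence never completes.

Observers exist only on the rare planets where all $n$ steps did
complete within $t_h$ — the observer-self-selection correction — so
every quantity of interest is conditional on that event.  In the
hard-step limit the conditional joint law of the step times is uniform
over the ordered simplex $\{0 \le t_1 \le \dots \le t_n \le t_h\}$:
the sequential exponential density
$\prod_m \lambda_m e^{-\lambda_m(\cdot)}$ becomes flat as all
$\lambda_m t_h \to 0$, and only the ordering constraint survives.  The
step times are therefore distributed as the order statistics of $n$
iid uniforms on $[0, t_h]$, giving the marginal

$$ f_{m,n}(t) \;=\; \frac{t^{m-1} (t_h - t)^{n-m}}
   {t_h^{\,n}\, B(m,\, n-m+1)}, \qquad
   \frac{t_m}{t_h} \sim \mathrm{Beta}(m,\, n-m+1), $$

with expectation $\langle t_m \rangle = m\, t_h / (n+1)$.  The steps
are evenly spaced on average; the last one concentrates near the end
of the window as $n$ grows.  `step_time_pdf()`, `step_time_cdf()` and
`step_time_quantile()` evaluate this family through the scaled Beta
distribution, which also handles the normalising constant in log space
for large $n$.

A consequence worth stating: these conditional laws do not depend on
the $\lambda_m$ at all, provided all are small.  The package's
rate-invariance tests check exactly this.

## Delays: forbidden periods after a step

On Earth, a hard biological innovation did not instantly produce the
planetary conditions the next step needed: roughly 0.5 Gyr separate
oxygenic photosynthesis from the Great Oxidation Event, and more than
1 Gyr separate eukaryogenesis from the late-Proterozoic upheavals.
The delayed variant attaches a *forbidden period* $\delta_i \ge 0$
after step $i$ ($i = 1..n-1$), during which step $i+1$ cannot occur;
$\Delta = \sum_i \delta_i$ is the cumulative delay.  A delay after the
final step cannot influence anything observable, so `delays` has
length $n-1$ by construction.

The conditional law follows from a *shifted order-statistics
construction*.  Write $u_m = t_m - d_m$, where
$d_m = \sum_{i<m}\delta_i$ is the forbidden time accumulated before
step $m$ (`cum_delay()`).  The feasibility constraints
$t_m \ge t_{m-1} + \delta_{m-1}$, $t_n \le t_h$ map to
$0 \le u_1 \le \dots \le u_n \le t_h - \Delta$, and in the hard-step
limit the conditional density of $(u_1, \dots, u_n)$ is again uniform
over that simplex.  Hence $u_m$ are the order statistics of $n$ iid
uniforms on $[0, t_h - \Delta]$ and

$$ \langle t_n \rangle
   = \frac{n\,(t_h - \Delta)}{n+1} + \Delta
   = \frac{n\, t_h + \Delta}{n+1}. $$

With $\Delta = 0$ this reduces to the undelayed last-step expectation.
Because this derivation is indirect, the package validates it by
simulation: the rejection sampler (which knows nothing about order
statistics) must agree with the closed form and with the exact sampler
in distribution; see the test suite.  Intermediate-step laws under
delays are deliberately left to the simulator — no closed form is
provided.

$\Delta \ge t_h$ leaves no room for any step; the model constructor
rejects it, treating the measure-zero boundary $\Delta = t_h$ as
infeasible too.

## Simulators

`sample_conditional_exact()` implements the construction above
directly: draw $n$ uniforms on $[0, t_h - \Delta]$, sort, add the
cumulative delays.  It is exact in the hard-step limit, costs one sort
per sample, and is the default mode.

`simulate_rejection()` is the forward model: step $m$ occurs at
$t_{m-1} + \delta_{m-1} + \mathrm{Exp}(\lambda_m)$ and a planet is
accepted iff $t_n \le t_h$.  To leading order the per-planet
acceptance probability is

$$ P_{\text{accept}} \approx
   \Big(\prod_m \lambda_m\Big) \frac{(t_h - \Delta)^n}{n!}, $$

(`completion_probability_lowrate()`), which for realistic hard steps
is astronomically small — that is the model's point, and why rejection
mode is a *validation oracle* at moderate rates rather than a
production sampler.  Runs whose projected acceptance falls below
`acceptance_floor` (default $10^{-9}$) are refused with a pointer to
the exact sampler, which prevents accidental unbounded runs;
`max_planets` (default $10^8$) caps the rest.

Implementation choice: planets are processed in large vectorised
batches, and within a batch the first-step filter is applied
analytically — the number of planets whose first step lands inside its
feasibility window is drawn as a Binomial count and their times by
inverse-CDF sampling of the truncated exponential, after which steps
$2..n$ are drawn literally with early pruning of planets that have
already overrun.  This has exactly the same joint law of accepted rows
and acceptance bookkeeping as a per-planet loop, while making
acceptance probabilities down to $\sim 10^{-8}$ tractable on one CPU.
Because planets within a batch are exchangeable, the sampler returns
*all* accepted rows from the batches it processed (at least
`n_target` on success) so that
`acceptance_fraction * planets_simulated` equals the row count
exactly.

Reproducibility: one seeded generator per run; draws are consumed in a
fixed documented order (per batch: the binomial count, the survivor
uniforms, then one exponential vector per remaining step), so a given
seed and configuration reproduce results bit-for-bit.  Ties in the
sort are probability-zero events and receive no special handling
(stable sort).

## Inferring the number of hard steps

Given an observed emergence time $t_{obs}$, `fit_n_expectation()`
profiles $\langle t_n \rangle = (n t_h + \Delta)/(n+1)$ over
$n = 1..n_{max}$ (default 20) and returns the $n$ minimising
$|\langle t_n \rangle - t_{obs}|$, together with the exact real root

$$ n^\* = \frac{t_{obs} - \Delta}{t_h - t_{obs}}. $$

*Why expectation matching?*  The fitting criterion behind the classic
Earth results is never spelled out formally; matching the conditional
expectation is the operational definition that reproduces all three of
them — $n = 1$ for $(t_{obs}, t_h) = (4.5, 10)$ Gyr, $n = 4$ for
emergence at $0.8 \times 5.7$ Gyr, and $n^\*$ between 2 and 3 once
$\Delta = 1.5$ Gyr is allowed — so it is the package's primary
estimator.  Ties are broken toward smaller $n$ (parsimony), and the
full profile is always returned so near-ties are visible.

`fit_n_likelihood()` is a clearly-labelled alternative, *not* the
estimator behind those headline numbers: it maximises the exact
last-step log-density $\log[n\, t_{obs}^{n-1} / t_h^n]$ over integer
$n$ ($\Delta = 0$ only).  Its behaviour differs instructively: at
$t_{obs}/t_h = 0.8$ the $n=4$ and $n=5$ likelihoods tie exactly
($4 \times 0.8^3 = 5 \times 0.8^4$) and parsimony picks 4, while as
$t_{obs} \to t_h$ the argmax saturates at $n_{max}$.  Integer argmaxes
are compared with a $10^{-12}$ relative tolerance so that exact
mathematical ties are not resolved by floating-point noise.

Two monotonicity facts are useful sanity checks and are enforced as
property tests: $n^\*$ increases with $t_{obs}$ and decreases with
$\Delta$ — admitting Earth-system delays always *reduces* the inferred
number of hard steps.

## The Earth scenario catalogue

```{r}
run_earth_scenarios()
```

* `carter_1983`: $t_h = 10$ Gyr (solar main-sequence lifetime),
  $t_{obs} = 4.5$ Gyr, no delays.
* `modern_th`: $t_h = 5.7$ Gyr, emergence at $0.8\,t_h = 4.56$ Gyr.
* `delayed`: as `modern_th` with $\Delta = 1.5$ Gyr, stored as the
  split $\delta = (0.5, 1.0)$ Gyr — photosynthesis→GOE and
  eukaryogenesis→Neoproterozoic.  Only $\Delta$ enters the
  expectation; the split matters only for simulator visualisations,
  and which historical steps carry which share is genuinely loose —
  the API therefore accepts an arbitrary $\delta$ vector.
* `revised_th_6`: $t_h = 6$ Gyr, $t_{obs} = 4.5$ Gyr, the upper end of
  the revised 5–6 Gyr lifetime range, giving $n^\* = 3$ exactly.

Two recorded inconsistencies, kept rather than resolved: (i) emergence
at $0.8\,t_h$ with $t_h = 5.7$ gives $t_{obs} = 4.56$ Gyr, slightly
above the 4.5 Gyr age of the Earth ($4.5/0.8 = 5.625$); the catalogue
uses 4.56 for the modern scenarios.  (ii) The statement that a 5–6 Gyr
lifetime admits *between 3 and 6* steps is not reproducible by
expectation matching across that whole range — $t_h = 5$ Gyr with
$t_{obs} = 4.5$ gives $n^\* = 9$, not 6 — so the catalogue includes
the $t_h = 6$ end, where expectation matching gives exactly 3, and
notes the mismatch here.

## Tunable parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `n` | number of hard steps | — | required |
| `t_h` | habitable lifetime | Gyr (any fixed unit) | required |
| `delays` | forbidden period after each of steps $1..n-1$ | Gyr | none |
| `rates` | per-step occurrence probability per unit time | 1/Gyr | required (rejection) |
| `n_target` | accepted samples requested | — | 1000 |
| `max_planets` | planet cap, rejection mode | — | $10^8$ |
| `acceptance_floor` | refusal threshold on projected acceptance | — | $10^{-9}$ |
| `n_max` | largest step count profiled in fits | — | 20 |

All operations are scale invariant in the time unit: doubling
$t_h$, $t_{obs}$, $\Delta$ and halving the rates leaves every
dimensionless result unchanged, so dimensionless mode ($t_h = 1$) is
fully supported.

## What the synthetic draws do and do not show

The samplers generate data *from the model itself*: conditioned
ordered step times with exponential (or limit-uniform) waiting.
Agreement between samplers, closed forms and fits therefore
demonstrates internal consistency — that the algebra, the order
statistics construction and the estimators are right — not that the
hard-steps description applies to Earth.  Real evolutionary history
offers a single realisation, no independent replicate planets, step
identities that are themselves hypotheses, and delays that are neither
sharp nor known; none of that variability is emulated.  Problem sizes
used in the shipped checks: $10^5$ exact-sampler draws for moment
checks, 2000 samples per arm for two-sample Kolmogorov–Smirnov sampler
equivalence at $\lambda t_h = 0.01$ (acceptance $\sim 10^{-7}$, about
$10^{10}$ thinned planets), and $n \le 10$ grids for quadrature
identities — sizes chosen so each Monte Carlo assertion sits at
roughly three standard errors of resolution.

## Numerical choices and degenerate inputs

* Densities return 0 outside $[0, t_h]$ instead of erroring.
* Quantiles polish `qbeta` with three Newton iterations so
  `cdf(quantile(p)) = p` to $\sim 10^{-12}$; on the time scale the
  inversion is limited by the precision of $p$ where the cdf saturates
  near 1 (e.g. the far tail of the first of many steps).
* `completion_probability_lowrate()` works in log space to avoid
  underflow for many very hard steps.
* Infeasible inputs fail loudly and specifically: $\Delta \ge t_h$ at
  model construction, $t_{obs} \le \Delta$ or $t_{obs} \ge t_h$ at
  scenario construction, empty results at summary time (never silent
  `NaN`s).

## Known limitations

* No closed-form marginals for intermediate steps under delays — use
  the exact sampler.
* No Bayesian posterior over $n$, no joint $(n, \Delta)$ inference and
  no uncertainty interval on $n^\*$: the expectation-matching fit is a
  method-of-moments point estimate, and with a single observed
  emergence time there is little more the model licenses.
* Habitable-lifetime uncertainty is handled by comparing scenarios,
  not by placing a distribution on $t_h$.
* No variance-reduction schemes beyond the exact sampler, and no
  parallel execution contract.
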