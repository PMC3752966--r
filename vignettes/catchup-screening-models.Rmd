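---
title: "Two natural-history models for a single cancer screen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two natural-history models for a single cancer screen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchuptime)
```

## The problem

A screening test can find a cancer during its preclinical detectable phase
(PCDP): the window between the moment a tumour becomes detectable by the test
(onset, `Z`) and the moment it would have surfaced clinically through
symptoms (`X`). The length of that window is the sojourn time `Y = X - Z`,
and the amount by which a screen advances diagnosis is the lead time `L`.
Neither is ever observed directly; both must be inferred by confronting the
detection rate at a first screen with the background incidence of clinical
disease.

The classical route is the prevalence/incidence identity `P = I × μ`:
prevalence of the PCDP equals incidence times mean sojourn time when
incidence is constant. Prostate cancer breaks the premise — PSA-era incidence
rises steeply with time since study entry — and a popular workaround, the
*catch-up time method*, instead reads off the time needed for cumulative
clinical incidence in an unscreened population to catch up with the
first-round detection rate. This package implements the two probability
models under which that estimator can be analysed, together with the full
estimator suite built on them:

* **Catch-up time model** — the time of clinical diagnosis `X` is
  independent of the sojourn time `Y`, with `X` following the background
  incidence `I(x)`. Prevalence at the screen is the *expected cumulative
  incidence over a sojourn window*: `p(t) = E[C_t(Y)]`.
* **Classic Markov model** — onset `Z` is independent of `Y` (the
  breast-screening tradition). Prevalence is the mean cumulative *onset*
  incidence over the sojourn window before the screen, and the onset
  incidence is recovered from clinical incidence by deconvolution.

Both models use a quadratic cumulative incidence
`C(x) = β₁x + (β₂/2)x²` (so the hazard is linear, `I(x) = β₁ + β₂x`) and an
exponential sojourn distribution with mean `μ`. These are the two standing
assumptions of every closed form in the package; the Volterra solver and the
simulator accept more general ingredients.

## The estimators and what separates them

With the prostate worked example (`β₁ = 0.0034342704`,
`β₂ = 2 × 0.0001796227` per person-year, first-round detection rate 4%),
the three direct estimators give three different answers from the same data:

```{r estimators}
m <- erspc_incidence()
c(catchup_model = estimate_mu_catchup_model(m, 0.04),
  catchup_time  = estimate_catchup_time(m, 0.04),
  classic       = estimate_mu_classic(m, 0.04))
```

The ordering is structural, not accidental. Cumulative incidence is convex
when incidence rises, so by Jensen's inequality the cumulative incidence at
the *mean* sojourn time understates the *mean* cumulative incidence: the
catch-up time (8.16 y) therefore overshoots the catch-up model's own moment
estimator (6.80 y). The classic model, whose exponential-sojourn prevalence
`I(t)μ` ignores the future trend entirely, needs a still longer sojourn
(11.65 y) to explain the same prevalence. All three coincide the moment
`β₂ = 0`, which the test suite asserts as a property.

The moment estimator solves `β₂μ² + β₁μ = P`; the catch-up time solves
`(β₂/2)m² + β₁m = P`; the classic estimator is `P / I(t)`. Each is monotone
in `P`, which is why Poisson uncertainty in the detected count maps exactly
through the estimators: `estimate_sojourn()` propagates the
normal-approximation interval `count ± z√count` endpoint-by-endpoint. The
exact-gamma alternative was checked and rejected during development because
it does not reproduce the published intervals for this design; the
normal approximation is the default and only method.

## Onset deconvolution

In the classic model, clinical incidence is the convolution of onset
incidence with the sojourn density — a first-kind Volterra equation. For the
exponential/quadratic pair the deconvolution has the closed form
`I_o(x) = I(x) + μ I′(x) = β₁ + β₂(x + μ)`; `solve_volterra_onset()`
handles general densities numerically.

Numerical design: a first-kind convolution equation punishes naive
discretizations. The trapezoidal product rule, the first scheme tried, is
unstable here (its errors oscillate and grow — a known pathology of
trapezoidal methods for first-kind Volterra equations), so the solver uses
the stable product-*midpoint* rule: the onset rate is piecewise constant on
half-step cells, the kernel mass per cell is integrated exactly by
five-point Gauss quadrature, and the triangular system is solved by forward
substitution. That scheme is only first-order accurate, so the solver runs
it on `refine + 1` successively halved grids and removes the `O(h)` and
`O(h²)` error terms by Richardson extrapolation (default `refine = 2`).
At a grid step of 0.01 years this reaches ~5 × 10⁻⁵ relative error against
the closed form, comfortably inside the 10⁻⁴ the tests demand.

Two boundary choices matter. First, onset history: the convolution at time
`x` involves onset arbitrarily far in the past, so the solver extends its
grid leftward until the density tail mass is below `tail_tol` (the
incidence function must be evaluable there; the quadratic's positivity
bound caps how far left one may go, which is why the equivalence test uses
a short sojourn). Second, the returned rates are reported on the requested
grid; reconstruction near the left edge of that grid is truncated, so
round-trip checks compare on the grid interior.

## The positivity bound, and where the signed closed form parts company with physics

The quadratic hazard is negative below `x = -β₁/β₂` (about −9.6 years for
the prostate coefficients), and the classic model's onset incidence
`β₁ + β₂(x + μ)` is negative below `-β₁/β₂ - μ`. The package's evaluation
functions treat the bound as a hard domain edge and error rather than clamp.
The classic prevalence `I(t)μ`, however, is kept as the *signed* closed form
— it remains exact because the negative-rate region cancels in the algebra —
while the numeric `"quadrature"` path clamps onset at zero, as any physical
process must. The two agree to the tested 10⁻⁶ whenever the bound lies many
mean sojourns before the screen and differ by exactly `μ²β₂ e^{z₀/μ}`
(with `z₀` the onset bound) when it does not; a test asserts that identity
rather than pretending the difference away. The same applies to the
simulator: its classic kind truncates onset at the bound, so simulated
prevalence exceeds the signed closed form when `μ` is large relative to the
bound (about +20% at μ = 11.6 with the prostate coefficients). The
interval-incidence identities at sensitivity 1 are immune — the truncation
terms cancel — and the parameter-recovery experiments use configurations
where the bound sits at least five mean sojourns before the screen, so the
truncation effect is below 0.1%.

## Interval cancers and the joint likelihood

After a screen at `t` with episode sensitivity `s`, clinical incidence dips
below background because part of the prevalent pool was removed, then
recovers as `e^{-x/μ}`:

* catch-up model: `I_s(t+x) = I(t+x)(1 - s e^{-x/μ})`;
* classic model: `I_s(t+x) = I(t+x) - s I(t) e^{-x/μ}` (derived from the
  onset-convolution representation; the quadrature evaluation of the two
  convolution integrals is retained as the reference oracle and the closed
  form as the fast path, with an equivalence test at 10⁻⁶).

`fit_screening_mle()` assembles the Poisson likelihood of a single-screen
trial from three strata: control-arm bins (expectation `py × I(midpoint)`,
exact for a linear hazard), the first-round detection count
(`n × s × p(t)`, persons not person-years), and interval-cancer bins
(person-years times the *bin-averaged* interval incidence, with exact
antiderivatives — counts are Poisson totals over person-time, so midpoint
evaluation would be a small but needless bias). Optimisation runs on
transformed scales (log for `β₁`, `μ`; logit for `s`) with Nelder–Mead
restarts until the objective is stationary; the start is deterministic —
control-arm least squares for the hazard line and the matching direct
estimator for `μ`. Wald intervals come from the observed information on the
natural scale (the published intervals are symmetric, which is what Wald
gives; profile intervals are out of scope). A sensitivity estimate within
10⁻⁴ of 0 or 1 is flagged as a boundary solution rather than an error, with
`NA` intervals where the information matrix degenerates.

```{r fits}
library(generics)
glance(fit_screening_mle(screening_fixture("hip"), "catchup"))
glance(fit_screening_mle(screening_fixture("hip"), "classic"))
```

## The packaged trial tables and their reconstructions

Two published single-screen data sets ship as plain-text fixtures: the
ERSPC-Rotterdam prostate trial and the HIP breast trial. The CSVs store
exactly the printed summaries (counts plus per-1000 rates, with the footnoted
unit split between person-years and persons); person-years are back-derived
as `cases / rate`, the screened denominator as `detected / detection rate`.
Every reconstructed rate round-trips to the printed value at printed
precision, and the tests assert it.

Two reconstruction decisions deserve emphasis, because the joint fits are
sensitive to them:

* **ERSPC control arm.** The published table aggregates the control arm to
  a single figure (1067 cases at 5.26/1000 person-years over twelve years),
  but the joint fit needs a time-resolved control arm to identify `β₁` and
  `β₂` separately. The loader splits the person-years evenly across twelve
  yearly bins and allocates the 1067 cases proportionally to the published
  incidence quadratic at bin midpoints (largest-remainder rounding). This is
  the only in-paper-informed allocation available, and it is a documented
  assumption, not data: fits on this fixture inherit it. The practical
  consequence is visible in the classic-model fit, whose sensitivity
  profile is extremely flat (a few log-likelihood units across
  `s ∈ [0.85, 1]`), leaving the fitted `μ` anywhere between ~16 and ~18
  depending on exactly how the reconstructed control arm tilts `β₁`. The
  catch-up fit is far less sensitive. A staggered-entry person-year profile
  (declining person-years in years 9–12) was also explored; it reconciles
  the printed aggregate with the published quadratic slightly better but
  moves the fits by under 4%, so the simpler even split is kept.
* **HIP fixed trend.** The mammography analyses conventionally hold the
  background trend fixed rather than estimate it from five years of control
  follow-up. The published summary prints the fixed trend as 0.021/1000 per
  year; the same source prints its incidence polynomial in
  cumulative-quadratic form, i.e. as `β₂/2`. The fixture adopts that
  printing convention consistently and fixes the hazard trend at
  `β₂ = 0.042/1000` per person-year per year. Under this reading both
  models' fitted sojourn times land within ~3% of the published values
  (1.87 and 1.95 versus 1.93 and 1.98 years); under the literal reading
  they sit ~5.5% low. Either way the headline qualitative finding — the two
  models agree to within 0.1 years for breast screening while disagreeing
  by years for prostate screening — is reproduced.

## Lead time and length bias

Prevalent cases are a length-biased sample of sojourn times: a cancer whose
PCDP covers the screen is more likely to be caught the longer that PCDP is.
In the catch-up model the weight is the cumulative incidence accrued over
the sojourn, giving the conditional mean
`E[Y w(Y)]/E[w(Y)]` with `w(y) = β₁y + (β₂/2)y²`. The package computes it
twice — once as the simplified exponential closed form
`μ(2β₁ + 3β₂μ)/(β₁ + β₂μ)` and once literally as the moment ratio through
`sojourn_moment()` — and tests their equality, so a transcription slip in
either derivation would be caught by the other. Because the time from onset
to screen among prevalent cases is again exponential with mean `μ`, the mean
lead time is the conditional mean sojourn minus `μ`:

```{r leadtime}
mu_hat <- estimate_mu_catchup_model(m, 0.04)
lead_time_summary(m, mu_hat, kind = "catchup")
lead_time_summary(m, estimate_mu_classic(m, 0.04), kind = "classic")
```

In the classic exponential model, lead time and sojourn time share one
distribution (memorylessness), so its mean lead time *is* `μ`. The two
models' lead times (9.63 versus 11.65 years) are much closer than their
sojourn times (6.80 versus 11.65) — the models largely agree about where in
time screen-detected tumours would have surfaced, while disagreeing about
when they began. The same convergence shows in the predicted post-screen
incidence curves: over 0.5–10 years since a perfect screen the two
predicted interval-incidence curves differ by at most ~6% *of the background
incidence* (the tests bound this at 15%). Measured against the curves
themselves the early-window difference is larger (~24% at half a year, where
both are small); the background-relative scale is the one on which the
curves are visually and epidemiologically comparable, and it is the scale
the package's similarity property uses.

```{r fig3, fig.width = 6, fig.height = 3.5}
plot_interval_incidence(
  predict_interval_incidence(m, mu_catchup = 6.80, mu_classic = 11.64, s = 1))
```

## The simulator: what it emulates and what it does not

`simulate_cohort()` realises either independence structure at the individual
level and is the package's validation oracle. Events are generated as an
exact nonhomogeneous Poisson process by thinning (the envelope is the rate
at the window's right edge, since both hazards increase), not as a
one-cancer-per-subject Bernoulli draw: the models' prevalence is an expected
event count, and at the 10⁶-subject scale of the oracle tests the Bernoulli
approximation `1 - e^{-p}` versus `p` is already a detectable distortion. A
subject can therefore (rarely) carry two events; identities are asserted at
the event level, matching the expected-count semantics of the likelihood. A
warning fires if the per-subject expected event count over the follow-up
window exceeds 0.1, where the cohort reading of the records starts to blur.

For the catch-up kind, diagnosis times are drawn out to twelve mean sojourns
past the screen so the prevalent pool is complete; sojourn times are drawn
independently and onset is `Z = X - Y`. For the classic kind, onset is drawn
from the (truncated) onset incidence and `X = Z + Y`. Prevalent events at
the screen are detected with probability `s` and removed; the rest surface
clinically within follow-up or are censored. A single integer seed fully
determines a cohort.

Tabulation into a count table uses population person-years (cohort size
times bin width, no withdrawal of cases): the interval-incidence formulas
are intensities over the whole screened cohort, with the detected cases'
removal already encoded in the deficit term. Real trial tables, of course,
report at-risk person-years; at screening-trial event rates the difference
is far below the uncertainties involved, but for parameter-recovery tests at
10⁶ subjects the model-consistent convention matters and is used.

What the simulator does *not* emulate: competing mortality, overdiagnosis,
repeat screening rounds, age structure, and any sojourn distribution other
than the exponential (the distribution interface accepts alternatives, but
all closed forms and the ML fit are exponential-only). Passing recovery
tests therefore demonstrate internal consistency of estimator and generator
under the stated assumptions — not robustness of the estimators on real
screening data, where all of the above are in play.

## Problem sizes and numerical conventions

The distribution-identity and recovery oracles run at 10⁶ subjects with
fixed seeds (binomial/Poisson 3-standard-error bands); the
confidence-interval calibration experiment uses 200 cohorts per model kind
at trial scale (20,000 screened, ~200,000 control person-years), chosen to
mirror the fixtures' information content while keeping the full suite in the
low minutes. In that experiment the classic arm uses a gentler trend
(β₂ = 10⁻⁴) so the onset positivity bound sits seven mean sojourns before
the screen and the generator remains fully physical at a prostate-like
sojourn time. Wald coverage is assessed on interior fits only — on the
`s = 1` boundary the information matrix degenerates and no Wald interval
exists — and the boundary fraction is itself capped by the test.

Degenerate and edge inputs follow one rule: evaluation outside a model's
validity domain is an error, never a silent clamp; out-of-bounds likelihood
parameters return `+Inf` (never `NaN`) so optimisers backtrack cleanly; and
ties in the quadratic root selection cannot arise because the positive root
is unique under the estimators' preconditions (the negative root is
discarded explicitly).

## Known limitations

* The ERSPC control-arm expansion is a reconstruction; joint-fit results on
  that fixture carry its assumptions, and the classic-model fit in
  particular sits on a flat sensitivity ridge (see above).
* Direct-estimate intervals propagate Poisson uncertainty in the detected
  count only; uncertainty in the background-incidence coefficients is
  deliberately ignored, as in the source analyses.
* Exponential sojourn is baked into every closed form; the numeric utilities
  accept general densities but no non-exponential estimation is offered.
* The general joint density of diagnosis time and sojourn time is out of
  scope: only the two independence structures are modelled.
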