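---
title: "Modelling yeast-powered passive micropumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling yeast-powered passive micropumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermpump)
```

## The system and the model

A yeast-powered pump seals a small inoculum of instant dry yeast
(*Saccharomyces cerevisiae*) with a sucrose solution in an airtight
chamber. Fermentation produces CO2, the rising pressure drives a piston,
and the piston displaces liquid through a microchannel — a passive pump
that runs for hours to days on materials costing fractions of a cent. The
package models the one quantity that determines everything downstream: the
CO2 production rate $Q(t)$ from inoculation to exhaustion.

$Q(t)$ passes through three phases, each with a distinct biological
origin, and each modelled by one multiplicative factor:

* **Startup.** Rehydration of the dried cells, lag-phase adaptation and
  CO2 saturation of the 1 mL medium all delay steady gas release. These
  overlapping processes share sigmoidal kinetics and are lumped into a
  single logistic factor
  $s_f \, \sigma(s_t (t - t_i))$ with $\sigma(x) = e^x/(1+e^x)$:
  a rate scale $s_f$, a steepness $s_t$ (1/min) and a latency $t_i$ (min).
* **Stable / diauxic.** Sucrose hydrolyses into glucose and fructose;
  yeast consumes glucose first and dips transiently when it switches to
  fructose (the diauxic shift). The dip is modelled by a decreasing
  logistic multiplier $1 + 1/(1 + e^{(t - t_s)/t_{ds}})$ with onset $t_s$
  and transition scale $t_{ds}$ (both min).
* **Decline.** The last fermentable sugar is consumed in an exponentially
  decaying manner; the factor $\max(0,\; e - e^{t/t_e})$ forces the rate
  to exactly zero at the exhaustion time $t_e$ — the pump's runtime. Cell
  viability stays above 99% here: the pump stops because the cells go
  quiescent, not because they die.

The product of all three factors is the **six-parameter model**
(`pump_rate()` on a `six_params` object). Dropping the diauxic factor
gives the **four-parameter model** (`four_params`), which trades the
short-term wiggle for a far more stable fit and better cumulative-volume
accuracy; it is the workhorse of the package. Cumulative pumped volume is
the integral $V(t) = \int_0^t Q(\tau)\,d\tau$ (`cumulative_volume()`).

One structural quirk is kept exactly as the model defines it: the diauxic
multiplier tends to 2, not 1, at early times, so the six-parameter model
is not strictly nested in the four-parameter one — the factor exceeds 1 at
$t = 0$ for every valid onset. Tests that compare the two models therefore
allow a hundredth of a percentage point of slack instead of asserting
exact nesting.

## Units

Fitted $s_f$ values read from the published parameter charts are on a
mL/min scale (order $10^{-2}$), while quoted peak pump rates are in
uL/min. Every parameter set, trace and coefficient table in the package
therefore carries an explicit rate-unit tag, constructors refuse to guess,
and `convert_rate_unit()` converts by exactly 1000. This is what makes the
worked examples reproducible without silent rescaling: parameters
`(0.007291, 0.026052, 159.6, 1599.6)` tagged mL/min give a peak rate of
10.75 uL/min.

## Peak analytics

Differentiating the four-parameter rate and simplifying (the startup
sigmoid is effectively saturated by the time the decline matters) gives a
closed-form time of maximum performance,

$$t_{max} = t_i + \frac{1}{s_t}\ln(s_t t_e - 1), \qquad
  Q_{max} = Q(t_{max}),$$

implemented in `peak_time()`/`peak_rate()`. It requires $s_t t_e > 1$;
otherwise a classed error suggests the fallback. The closed form is an
approximation: `numeric_peak()` finds the true argmax by a deterministic
1-min scan plus golden-section refinement to 0.01-min resolution. On the
two published parameter regimes the two disagree by under 3% in time, and
because the closed form merely evaluates the true rate curve at an
approximate argmax, `peak_rate()` can never exceed the numeric maximum —
both facts are asserted in the test suite.

```{r}
p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
c(closed_form = peak_time(p), numeric = numeric_peak(p)$t_max)
```

## Fitting

`fit_pump_model()` estimates parameters from a rate trace by bounded
nonlinear least squares — the Levenberg–Marquardt trust-region
implementation in minpack.lm, with box constraints. The protocol mirrors
the original calibration: initial guesses $s_f = 0.005$ (mL/min scale,
rescaled to the trace's unit), $s_t = 0.005$, $t_i = 100$, $t_e = 1000$,
all parameters bounded below by zero, at most 400 iterations. Volume
traces are first differentiated (`rate_from_volume()`: centered
differences, one-sided at the edges, 3-sample moving average) because the
model is written on the rate scale.

Two numerical choices matter:

* **Multimodality of the six-parameter fit.** The residual surface is
  multimodal in the diauxic onset $t_s$; a single mid-span start can
  converge to a wrong local optimum even on noiseless data. The default
  initialisation therefore scans onset fractions 0.2–0.8 of the trace span
  and keeps the lowest-deviance optimum — still fully deterministic.
  Passing a fitted `four_params` as `init` instead warm-starts the
  six-parameter fit with a neutral diauxic term.
* **Degenerate traces.** All-zero or pre-startup-only recordings drive
  $s_f$ to the bound; fits with $s_f < 10^{-6}$ of the observed peak are
  flagged `degenerate` rather than raised as errors, and non-convergence
  is reported in the `converged` flag.

Fit quality is scored two ways, matching the two things a pump user cares
about. `nrmse_rate()` is the RMS rate residual normalized by the observed
range (a convention chosen here; the normalization is otherwise
ambiguous), in percent. `volume_error()` compares cumulative volumes:
$100 \cdot \mathrm{mean}_t\,|V_{model} - V_{obs}| / \mathrm{mean}_t\,
V_{obs}$ over the sampled times. The mean-over-mean normalization was
chosen so that scaling the fitted rate by $1 + a$ scores exactly
$100|a|$ percent while still penalizing drift accumulated anywhere in the
run, and both metrics are invariant under joint uL/mL rescaling of model
and data.

## The two-parameter layer

Across conditions, each of the four fitted parameters varies linearly with
the pump configuration — yeast inoculum mass $m$ (mg) and sucrose
concentration $s$ (wt%):

$$\theta(m, s) = C_{m\theta}\, m + C_{s\theta}\, s + C_{\theta},
\qquad \theta \in \{s_f, s_t, t_i, t_e\}.$$

The twelve published coefficients ship as `default_coefficients()`
(a JSON fixture in `inst/extdata/`). Two facts shape the implementation:

* **Two parameter sources.** The published worked-example parameter sets
  were read off the parameter charts and do **not** equal the coefficient
  table evaluated at the same configuration (the table at $(5, 3)$ gives
  $t_e \approx 921$, not the chart value 1002.6). The package keeps the
  two sources distinct and never mixes them silently.
* **Validity domain.** The maps were calibrated at $m \le 5$ mg, $s \le 5$
  wt% and extrapolate badly (demonstrated at 7 mg). Interpolation outside
  the box emits a classed warning; `inverse_design()` refuses to leave the
  closed box $[1,5] \times [1,5]$ entirely. Near the origin the affine
  $s_f$ map goes negative and a classed interpolation error is raised.

`fit_coefficients()` refits the twelve coefficients from at least three
calibrations (configuration + fitted parameters) by per-parameter
least-squares planes; three non-collinear calibrations interpolate
exactly, more are averaged, and collinear designs raise a rank error. This
is how the model is adapted to a new yeast strain or pump geometry.

`inverse_design()` mirrors the experimental control strategy — inoculum
mass sets the peak rate, sucrose fine-tunes the runtime. A single pass
(pick $m$ at a nominal mid-domain sucrose level, then solve the affine
runtime map for $s$) leaves a bias of up to ~10% in $m$ because the peak
rate depends weakly on $s$ too; the implementation therefore alternates
the same two stages to a fixed point, which round-trips in-domain targets
essentially exactly while remaining deterministic and explainable.
Unreachable targets raise an `fermpump_infeasible_design` error carrying
the closest achievable design.

## Trace pipeline and hydraulics

Kymography extracts piston displacement (pixels, every 3 min) from
time-lapse images; `displacement_to_volume()` multiplies displacement from
the first sample by the uL-per-pixel calibration, and `mean_flow_rate()`
reports the difference quotient over a window, interpolating the window
ends. Sub-pixel positions are accepted; image processing itself is out of
scope — the package consumes the extracted series.

`required_pressure()` is the Hagen–Poiseuille pressure
$\Delta p = 8 \mu Q L / (\pi R^4)$ for laminar flow in a circular
channel. All four inputs are required explicitly: the published
back-pressure figure cannot be recomputed because the channel length and
oil viscosity behind it were not printed, and fabricating defaults would
only hide that. The droplet channel's semicircular cross-section is not
modelled; the circular-radius form is applied as the original calculation
did.

## The synthetic-data generator

The raw experimental traces were never published, so the generator is the
package's test bed. It emulates what kymography-derived data look like:
model samples every 3 min (`dt` configurable) over $[0, t_e + 2\,dt]$,
additive Gaussian rate noise scaled to the peak (default 4%),
mean-preserving lognormal parameter jitter across replicates (default
cv = 5%, $N = 6$ per condition, matching the published min–max replicate
envelopes), and optional pixel quantization of volume traces. Defaults are
plausible stand-ins chosen once — the true experimental noise magnitude is
unknown — and every draw is a pure function of the inputs and an integer
seed (sub-seeds per replicate by fixed arithmetic), leaving the global RNG
untouched.

What the generator deliberately does not emulate: substrate-tracking
dynamics (no mechanistic fermentation ODEs), temperature dependence
(experiments ran at a constant 37 °C), osmotic inhibition at very high
sucrose, or autocorrelated measurement error. Passing tests therefore
demonstrate that the estimation and design machinery is correct under the
model's own assumptions plus white noise — not that the model captures
every feature of real pump data.

## Numerical choices and problem sizes

* Quadrature: composite trapezoid on a fixed 0.5-min grid clipped to
  $[0, t_e]$; verified against a 0.05-min oracle to 0.1% at $t_e$.
* Logistic terms always go through `plogis()`, never a naive
  `exp`-ratio; exponents reach ~75 at late times. At double precision the
  sigmoid saturates to its boundary once its argument exceeds ~37, so
  open-interval range properties are asserted strictly only away from
  saturation.
* Negative times are accepted by the bare phase factors (they are
  mathematically defined there) but rejected by rate and volume
  evaluators, since model time starts at inoculation.
* Test problem sizes: traces of ~550 samples (3-min cadence over a
  ~1600-min run), 20 random parameter draws for recovery properties, 20
  seeds per level for the noise-monotonicity property. The full suite runs
  in a few seconds on one core.

## Known limitations

* The closed-form peak time is used as published; its derivation (and the
  exact stationarity condition it approximates) is only validated
  numerically, on the two published parameter regimes.
* The coefficient table is taken as printed; whether it was fitted to
  per-replicate or condition-mean parameters is unknown, and the package
  fits whichever single trace it is given (with `mean_of_replicates()` as
  an optional pre-step).
* The validity domain is a hard box, not a confidence region; nothing is
  known about interpolation quality between the calibrated grid points
  beyond the published interpolation check at (3 mg, 3 wt%).
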