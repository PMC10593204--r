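---
title: "Constant input-sensitivity design for treadmill heart-rate control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant input-sensitivity design for treadmill heart-rate control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartpace)
```

## The control problem

During constant-intensity treadmill exercise, heart rate (HR, bpm) responds
to belt speed (m/s) with dynamics that are well captured by low-order linear
time-invariant deviation models around the resting baseline. The classical
description distinguishes a small immediate component (Phase I), a large
slower component (Phase II) and an ultra-slow drift (Phase III). heartpace
works with two nominal plant forms:

* first order, `P1(s) = k1 / (tau1 s + 1)`, lumping Phases I and II into one
  time constant;
* two-phase (second order),
  `P2(s) = k2 / ((tau21 s + 1)(tau22 s + 1))`, with a separate time constant
  per phase (`tau21 <= tau22` by convention).

The feedback compensator `C(s)` commands belt speed from the error between a
filtered reference and the measured HR, and is constrained to contain an
integrator (`C = G/(s H')`): integral action removes steady-state error and
absorbs the Phase III drift. A reference prefilter `C_pf` shapes the overall
target-to-HR response.

## The synthesis: a flat input sensitivity

Writing the plant `P = B/A` with `A` monic, the input sensitivity
`U = C/(1 + CP)` is the transfer from disturbances and reference to the
*speed command*. Its magnitude tells you how "nervous" the belt will be in
each frequency band — in particular across the conventional HRV analysis
bands delimited at 1/300, 0.04, 0.15 and 0.4 Hz (`hrv_band_edges()`), where
heart-rate variability continuously excites the loop.

`synthesize_constant_U()` makes `|U(jw)|` exactly constant at every
frequency by cancelling all closed-loop poles with the compensator numerator:

1. put `A` in the compensator numerator (`G = g0' A`), cancelling the plant
   poles;
2. place the remaining closed-loop poles back on the open-loop poles by
   solving `s H' + g0' B = A`.

Matching constant terms gives `g0' = A(0)/B(0)`, and `H'` follows by the
exact polynomial division `(A - g0' B)/s` — whose remainder vanishes by
construction and is asserted at run time. The closed-loop characteristic
polynomial becomes `A^2`, and

* `U = g0'` (a constant: `1/k1` and `1/k2` for the two nominal plants),
* `S = s H' / A`, `T = g0' B / A`.

No tuning parameter exists anywhere in this design; everything follows from
the identified plant. The package also carries the specialized closed forms
(`closed_form_first_order()`, `closed_form_second_order()`) which agree with
the general synthesis coefficient-by-coefficient and serve as its
cross-check, while `generic_sensitivities()` recomputes `S`, `T`, `U` from
the defining fractions `1/(1+CP)`, `CP/(1+CP)`, `C/(1+CP)` as an independent
oracle.

```{r}
d2 <- synthesize_constant_U(nominal_plant(2))
d2
```

The synthesis requires a stable (`A` Hurwitz), strictly proper plant with
`B(0) != 0`: the method cancels plant poles, and cancelling unstable poles
would be internally unstable, so such plants are rejected rather than
"best-effort" designed. If `H'` itself turns out non-Hurwitz (possible for
plants with awkward numerators) a warning is raised; the heart-rate models
never trigger it.

## Reference shaping

`design_Tcl(rise_time)` builds the target tracking response
`T_cl = p^2/(s+p)^2` — unit DC gain and a critically damped double pole, so
the step response is monotone — with `p` solved so the 10–90% rise time hits
the request (150 s by default; `p` is about 0.02239 s^-1). We use the 10–90%
convention throughout: it is the dominant convention in this literature and
`rise_time_10_90()` implements it by bisection on the exact step response.
`design_prefilter()` then sets `C_pf = T_cl / T_o`, which is proper because
`T_cl` rolls off at least as fast as either nominal `T_o`, and stable
because both nominal `T_o` are minimum phase.

## The closed-loop simulator

`simulate_session()` emulates one feedback-control test the way the
equipment ran it:

* HR sampled at 1 Hz; the compensator runs at 0.2 Hz (5 s interval) on the
  average of every five consecutive HR samples;
* the speed command is held constant between control updates (zero-order
  hold) and clamped to 0.5–6.0 m/s; while clamped, the newly computed
  command is written back into the compensator recursion so the integrator
  cannot wind up (release is immediate and bumpless);
* the participant's "true" dynamics are a two-phase plant advanced by exact
  zero-order-hold discretization at 1 s — exact because the input is
  piecewise constant — plus an additive HRV-like output disturbance and
  white measurement noise;
* the compensator is discretized by the bilinear (Tustin) map, which sends
  the integrator pole exactly to `z = 1` (integral action is preserved
  exactly) and is phase-faithful in the sub-0.4 Hz bands where the loop
  lives.

Two numerical choices deserve a note. First, the filtered reference: the
target HR is a known constant, so the reference path is pure feedforward and
`r'` is computed as the *exact continuous* step response of `C_pf` sampled
at the control instants. Discretizing the biproper prefilter at 5 s instead
leaves a ~2 bpm startup artifact in the reference; computing it exactly
costs nothing and removes a discretization error that has no physical
counterpart. Second, state-of-the-art accuracy matters at these time scales
(time constants 18–70 s probed at 1 s): step responses and ZOH maps are
computed through the matrix exponential, never by approximate integration.

The nominal simulated response `HR_sim` is the `T_cl` step scaled from the
resting baseline to the target. With the matched nominal plant, no
disturbance and no noise, the simulated loop reproduces it closely, but not
arbitrarily well: the 5 s multirate mechanics (sample-averaged measurement
plus held command) distort the closed loop at second order in the control
interval, leaving a peak transient deviation of about 1.4 bpm on a 75 bpm
reference step (about 2%). Refining the control interval to 1 s shrinks the
peak to 0.10 bpm, which is how we attribute the gap to the multirate
structure rather than to the algebra. Over the evaluation window the
residual is far smaller: the window RMSE against `HR_sim` is about
0.03 bpm.

## Synthetic participants

`sample_cohort()` draws participants whose true dynamics are two-phase
plants with parameters log-normally perturbed around the nominal identified
values (`k2 = 24.70` bpm/(m/s), `tau21 = 18.60` s, `tau22 = 37.95` s) at a
chosen coefficient of variation (0.2 by default — the spread one expects
between individuals given that the nominal values are averages over
individually identified models), ages uniform on 23–57 years (the study's
recruitment range; the target HR is `0.765 (220 - age)`), resting HR uniform
on 60–80 bpm.

The HRV-like disturbance is zero-mean Gaussian noise through a one-pole
low-pass (2 bpm SD, 0.05 Hz cutoff by default) added at the plant output,
and measurement noise is white with 1 bpm SD. These are deliberately simple,
configurable stand-ins: real HRV has band structure, nonstationarity and
respiratory coupling that the generator does not emulate, real plants are
nonlinear at the extremes of the speed range, and real measurements drop
out. Passing in-silico tests therefore demonstrates the *control-theoretic*
mechanism — model fidelity translating into tracking accuracy and control
activity — not field performance of any device.

## The paired experiment and its statistics

`run_paired_experiment()` mirrors the study structure: every participant
completes one session with the first-order-model compensator `C1` and one
with the two-phase-model compensator `C2`, both designed from the *fixed
nominal* models (one average model serves all participants), with identical
disturbance and noise realizations across the two arms. Outcomes are
computed at the control rate over the evaluation window (295–2095 s,
N = 361 samples; the truncated 295–1795 s variant gives N = 301):

* `RMSE` — root-mean-square deviation of the measured HR from the nominal
  simulated response, which during the window equals the constant target
  (the prefilter transient has settled; the tiny residual of the `T_cl`
  tail is the paper-convention simplification, and the full trajectory
  remains available via `session_outcomes(..., "trajectory")`);
* `P_grad_u` — the mean squared successive difference of the speed command
  (divisor N − 1), the measure of how dynamic a controller is.

`compare_controllers()` screens the paired differences for normality with a
Lilliefors-corrected Kolmogorov–Smirnov test and then applies one-sided
paired t-tests at level 0.05: RMSE tested for `C2` lower, control-signal
power for `C2` higher. The Lilliefors p-value is computed by a seeded Monte
Carlo null (default 10^4 replicates) rather than table interpolation — exact
to Monte-Carlo error at any sample size and fully reproducible.

```{r, eval = FALSE}
cohort <- sample_cohort(20, seed = 1, cv = 0.2)
outcomes <- run_paired_experiment(cohort)
compare_controllers(outcomes)
```

In a 20-participant synthetic cohort at these defaults the comparison goes
the expected way in the large majority of experiment seeds: `C2` tracks more
accurately and works the belt harder. Only the direction is claimed — the
magnitudes depend on the disturbance model, which is a stand-in.

## Numerical choices, sizes and limitations

* Polynomial coefficients are stored in descending powers of `s`,
  denominators normalized monic after every operation; products use direct
  (non-FFT) convolution so structural zeros stay exactly zero — the
  integrator pole must be *exactly* at the origin.
* `tf_minreal()` pairs roots within a relative tolerance of 1e-6 (scaled by
  `max(1, |root|)`). Numerical root finders split a repeated root of
  multiplicity m by roughly `eps^(1/m)` — about 1e-5 relative for the
  double and triple roots the `A^2` characteristic polynomial produces — so
  tighter pairing cannot realize the synthesis cancellations. Correctness
  does not rest on proximity alone: every candidate reduction is verified by
  cross-multiplying back against the original fraction and is reverted if
  the coefficient identity fails, and exact constant multiples short-circuit
  the root path entirely.
* Default problem sizes: sessions simulate the 2100 s measurement phase at
  1 Hz; the packaged experiment uses 20-participant cohorts; property
  checks run over 1000 random stable plants of orders 1–4 with poles spread
  over (0.001, 1) rad/s; the Lilliefors Monte Carlo uses a few hundred null
  replicates inside the test suite and 10^4 by default in analysis use.
* Out of scope: device I/O, real-time execution, treadmill incline,
  physiological nonlinearity and Phase III modelling beyond the additive
  disturbance, robustness margins beyond what the sensitivity magnitudes
  express, and any tuned or multi-objective variant of the design — the
  point of the synthesis is that it has no knobs.
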