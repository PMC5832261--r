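---
title: "Methods: short-term AP memory and electrical restitution under dynamic pacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term AP memory and electrical restitution under dynamic pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`apmem` studies how a human ventricular myocyte remembers its recent pacing
history: when the stimulation interval (cycle length, CL) changes beat to
beat, the action-potential duration (APD) of a beat stops being a function
of the preceding diastolic interval (DI) alone, and the cloud of
`(CL[n-1], APD[n])` states opens into a hysteresis loop. The package
simulates the ten Tusscher–Panfilov 2006 (TP06) epicardial myocyte under
constant, uniform-random and sinusoidal-periodic pacing, quantifies the
resulting "spaces of states", and probes how this short-term memory
stabilizes repolarization after perturbations such as a missing beat.

## The cell model and its integrator

The TP06 model has 19 state variables: membrane potential, 12
Hodgkin–Huxley gates, the sarcoplasmic-reticulum (SR) release gate, and the
Na^+^, K^+^ and Ca^2+^ concentrations (cytosolic, SR and dyadic subspace).
`tp06_params()` carries the full epicardial constant set; `tp06_derivatives()`
exposes the right-hand side (the signature is `deSolve`-compatible, so any
stiff solver can integrate it directly).

The beat engine (`run_train()`, `resume_train()`) uses a fixed-step scheme:
Rush–Larsen exponential updates for the 13 gate-like states (the SR release
gate is linear in its state and is treated the same way) and forward Euler
for the potential and concentrations, at `dt = 0.02` ms. This is the scheme
the model was originally published with; it is unconditionally stable for
the gates, fully deterministic (bitwise-reproducible trains, which the
snapshot/restore machinery and the paired perturbation experiments rely
on), and fast enough that a 300-beat conditioning train takes about two
seconds. Halving `dt` to 0.01 or 0.005 ms moves steady APDs by less than
0.1 ms and does not move the alternans-onset CL, which we take as evidence
that the default step resolves the dynamics of interest. Stimulus onsets
are quantized to the integration grid (≤ 0.01 ms error).

Stimuli are 3 ms current pulses at 1.5× the diastolic threshold; the
threshold is found by bisection to 1% (`find_threshold()`) and re-measured
for every parameter set. A beat is *captured* when V~m~ exceeds 0 mV within
20 ms of the stimulus with a genuine regenerative upstroke (dV/dt above
10 mV/ms and V~m~ below 0 at onset — a stimulus landing on an ongoing
plateau is not a new beat). APD is measured from the upstroke (the argmax
of dV/dt, refined by a local quadratic so it does not sit on the step grid)
to the interpolated downward −60 mV crossing, and DI = CL − APD. If V~m~ is
still above −60 mV when the next stimulus arrives the beat is flagged
*merged* and its APD is undefined; detection layers may censor such beats
at APD = CL, which simply states that repolarization outlasted the cycle.

## Pacing laws and timing conventions

`constant_schedule()`, `random_schedule()` (CL = CL\* + clv·U[−1, 1], seeded),
`periodic_schedule()` (CL(N) = CL\* + clv·sin(ωN), N starting at 1) and
`alternating_schedule()` generate beat plans; beat N is stimulated at the
cumulative sum t(N) of the cycle lengths, so a schedule's first stimulus
falls one CL after the start of the run. A snapshot taken by the engine is
always the full 19-variable state immediately before a stimulus, i.e. an
end-of-cycle state; `resume_train()` therefore fires its first stimulus at
t = 0. The beat records of both entry points book-keep identically:
`CL_ms[n]` is the cycle *initiated* by stimulus n, so the state of beat n
pairs with `CL_ms[n-1]`, the interval that preceded it.

`drop_beat()` silences one stimulus without resetting the pacing clock (the
missing-beat perturbation); `switch_schedule()` concatenates a constant
run-in with a dynamic phase on a continuous time axis.

## Conditioning

The full protocol conditions with 1000 beats per rate; the package
default is 300, backed by a convergence check: rate-dependence points move
by well under 1 ms between the two (the model keeps a much slower ionic
drift, a few ms of APD over thousands of beats, that neither length
resolves; wherever a tolerance of a couple of ms matters, comparisons are
made at matched beat horizons, as in `er_to_rd_beats()`).

Conductance-modified cells (e.g. `scale_conductances(p, c(IKs = 0.4))`) are
conditioned by applying the change *acutely to the control-conditioned
steady state* and pacing 300 further beats. This mirrors drug application
during ongoing pacing and is not cosmetic: pacing the modified cell at
350 ms straight from rest produces a long first AP, a failed second
stimulus, and permanent 2:1 block — a coexisting attractor. The same trap
is why the alternans-onset scan (`alternans_onset_scan()`) walks CL
*downward* in 5 ms steps from an established 1:1 rhythm.

## Restitution protocols and memory metrics

* `rd_curve()` — steady APD vs constant CL (rate dependence).
* `classic_er()` — condition at CL\*, snapshot the end-of-cycle state, then
  for each test CL restore, deliver the last conditioning beat and a test
  beat separated by the test CL, and record the test APD against CL
  (ER~CL~) and against the preceding DI (ER~DI~). Both curves come from the
  same sweep, so DI = CL − APD(conditioning beat) holds point-wise. The
  sweep half-width is a parameter: ±35 ms for the perturbation-figure
  protocols, ±20 ms otherwise.
* `dynamic_er_family()` — the same sweep launched from every stride-th beat
  of a dynamic train; the family's envelope bounds the space of states.
* `space_of_states()` — the lag-1 pairing `(CL[n-1], APD[n])` or
  `(DI[n-1], APD[n])`, with a rising/falling direction flag.
* `shift()` — the memory measure: the vertical width of the space of states
  at CL\*. For periodic sources the rising and falling branches are
  interpolated at the reference CL; for random sources the APD range within
  a ±2 ms bin is used (the bin width is a parameter and the estimate is
  insensitive to it between 2 and 5 ms); constant sources give 0.
* `der_slope()` — OLS slope of a unimodal cloud; it refuses clouds whose
  mean branch separation over the central half of the x-range exceeds 2 ms
  (the unimodal-vs-loop threshold, set at the same scale as the recovery tolerance)
  and directs the caller to `major_axis_slope()`, the first principal axis
  of the mean-centered cloud (no standardization, both axes in ms).
* `max_local_slope()` — "reaches values up to" slopes, computed by OLS in a
  sliding 8 ms x-window requiring at least 4 points covering at least half
  the window. A finite difference over a fixed number of consecutive sorted
  points is *not* usable here: quasi-periodic sampling places neighbouring
  x values arbitrarily close together, and dividing solver-level APD noise
  by a 0.01 ms x-span produces slopes an order of magnitude above anything
  real. Values are stable for window widths 4–16 ms.
* `fit_monoexponential()` — `a·exp(−x/τ) + c` by Levenberg–Marquardt, for
  relaxation-vs-CL and trend-vs-ω summaries.

## Stability assays

`missing_beat_experiment()` runs a schedule intact and with one stimulus
disabled, aligned by stimulus index (the dropped slot keeps its index with
a sentinel APD, so like compares with like). Nb is the number of beats
after the missing one before |ΔAPD| stays below 2 ms for 10 consecutive
beats; the sustainment guard is ours — with alternating recoveries a single
zero-crossing of ΔAPD would otherwise count as recovery. If the
perturbation triggers sustained alternans, Nb is reported as not recovered.
`missing_beat_scan()` shares one intact train across 20 drop positions
(restarting each perturbed run from the stored pre-drop snapshot), and
random-pacing results are averaged over 5 seeds as well.

`detect_alternans()` classifies a run of at least 40 beats of
sign-alternating APD differences with mean amplitude above 2 ms; it is
*sustained* if the run reaches the end of the series. `switch_experiment()`
triggers alternans by a missing beat during constant pacing, switches to a
dynamic law, and judges quenching against a paired no-drop reference run:
the post-switch APD difference must fall below tolerance — comparing
against a reference rather than against flatness matters because periodic
pacing itself makes APD oscillate. `cl_change_statistics()` reports the
fraction of beats with |ΔCL| above a threshold for matched periodic and
random schedules; the periodic law concentrates much larger beat-to-beat
jumps (|ΔCL| = 2·clv·|sin(ω/2)|·|cos ω(N−½)|) than the random law's
triangular difference distribution, which is the mechanical reason matched
`clv` does not mean matched rate-change stress.

## Removing a current's time-dependence

`fit_current_clamp()` replaces the gated I~CaL~, I~Kr~ or I~Ks~ by a
polynomial in V~m~ fitted to the current recorded during one steady AP at
the reference CL. The fit excludes the first 9 ms after the upstroke and
uses the monotone repolarization limb (from the post-blanking voltage
maximum through diastole), where the current–voltage trajectory is
single-valued; the polynomial order (3–12) is the lowest meeting an RMSE of
2% of the current's peak-to-peak range, evaluated in a centered and scaled
voltage basis and held at its boundary value outside the fitted range.
During simulation the clamp is suspended from each stimulus onset until
9 ms after the upstroke.

Self-consistency (re-simulating the fitting beat with the clamp) is within
1 ms of APD for I~CaL~ and I~Kr~. I~Ks~ keeps a ~4 ms residual that no
voltage-only function can remove: the current activates slowly, so its
early-plateau value at a given V~m~ is genuinely different from its
repolarization value at the same V~m~. We report this rather than widening
the blanking window, which is part of the protocol definition.

## The surrogate map

`surrogate_train()` iterates
APD~n+1~ = APD~max~ − a·exp(−DI~n~/τ~r~) − γ·M~n~ + ε~n~, with a memory
store M relaxing toward APD~n~/APD~max~ at rate CL/τ~m~. Defaults
(APD~max~ 320 ms, a 165 ms, τ~r~ 200 ms, γ 40 ms, τ~m~ 1500 ms, no noise)
put the fixed point near APD 230 ms at CL 350 ms with restitution slope
~0.45 — the ionic model's operating point — but the surrogate is a test
fixture, not a quantitative stand-in, and is never used for model-level
results.

One analytic point it makes precise: a *memoryless* nonlinear restitution
already produces a loop in the `(CL[n-1], APD[n])` pairing under fast
periodic pacing, because APD~n~ = f(CL~n−1~ − APD~n−1~) depends on the
previous APD through the bookkeeping. What memory — and only memory —
does is break the DI-determinism of the APD: with γ = 0 the
`(DI[n-1], APD[n])` cloud is exactly a curve, and its loop width grows from
zero with γ. The property suite asserts exactly this signature. (With the
accommodation sign of the memory term used here, γ > 0 *shrinks* the vs-CL
loop; in the ionic model the loop is carried by I~CaL~ kinetics, as the
clamp experiments show.)

What the surrogate does not emulate: capture failure dynamics, merged
beats, conduction-level phenomena, ionic drift. Tests passing on the
surrogate validate the metric layer's arithmetic, not the cell model.

## Problem sizes and reproducibility

Default analysis sizes, chosen to keep any single experiment in the
seconds-to-a-few-minutes range at `dt = 0.02` ms: 300 conditioning beats;
200-beat dynamic trains for spaces of states; 20 drop positions (and 5
seeds for random pacing) for recovery statistics; descending alternans
scans with 150 conditioning + 100 detection beats per CL. All randomness
enters only through schedule seeds, which are recorded in the schedule
metadata; identical inputs reproduce identical outputs bitwise.

## Known limitations

* Computed reference values: at constant CL 350 ms the control cell settles
  at DI 118.8 ms with a classic-ER slope of 0.53, and the three
  single-conductance recalibrations (G~Kr~ ×0.10, G~Ks~ ×0.40,
  G~CaL~ ×1.90) each prolong steady APD by 11.6–11.8% — values the
  acceptance suite recomputes. Quantities that hinge on the response to a
  long diastolic pause (post-pause APD prolongation, recovery beat counts,
  hysteresis widths under strong G~Ks~ reduction, the alternans-onset CL)
  are markedly more sensitive to equation-source variants of this model
  family than the steady-state quantities are; several published TP06
  encodings differ in exactly the slow-inactivation details that control
  that response. The package implements one encoding verbatim and reports
  what it computes.
* Under strong G~Ks~ reduction a missing beat at 350 ms drives this
  encoding into 2:1 block (sub-threshold even-beat responses) rather than
  captured 2:2 alternans; the quenching experiments therefore run, but
  their preconditions differ from the captured-alternans picture.
* Single cell only: no electrotonic coupling, no conduction, no ECG-level
  observables.
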