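---
title: "Equivalent-circuit analysis of transient fusion-pore openings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-circuit analysis of transient fusion-pore openings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreadmit)
```

## The model and its assumptions

Cell-attached capacitance measurement drives the pipette with a sine
carrier (1591 or 6400 Hz in the recordings this package emulates) and
demodulates the pipette current into real (`Re`) and imaginary (`Im`)
admittance channels. The patch is modelled as the access resistance `R_A`
in series with the membrane (`C_m` parallel `G_M`); a fused vesicle adds
its capacitance `Cv` behind a fusion-pore conductance `Gp`, in parallel
with the membrane. Relative to the closed-pore state the vesicle changes
the admittance by

$$\Delta Y = T^2(\omega)\left(\frac{(\omega C_v)^2/G_p}{1+(\omega
C_v/G_p)^2} + \frac{i\,\omega C_v}{1+(\omega C_v/G_p)^2}\right),\qquad
T^2(\omega) = \frac{1}{(1 + R_A G_M + i\omega C_m R_A)^2}.$$

The model assumes `Cv << C_m` and `omega Cv << 1/R_A` (a vesicle is a small
perturbation of the patch), that all circuit constants except `Gp` are
constant across an event, and that each event is a two-level (open/closed)
transition — no time-resolved `Gp(t)` within an episode.

Two limits organise everything downstream. Fully open (`Gp -> Inf`):
`dRe = 0`, `dY = i T^2 omega Cv`, so the Im step alone gives `Cv`. Fully
closed (`Gp = 0`): no signal; the package returns the analytic limit
`(0, 0)` rather than dividing by zero. In between, both components are
finite, and inverting the pair gives

$$\hat C_v = \frac{\Delta Re^2+\Delta Im^2}{\Delta Im\,\omega},\qquad
\hat G_p = \frac{\Delta Re^2+\Delta Im^2}{\Delta Re}.$$

Because the lock-in phase is adjusted during recording so pure capacitance
steps project only on `Im`, the default circuit is `T^2 = 1` exactly
(`circuit_params()` with `R_A = 0`); a full complex `T^2` is available for
simulating uncorrected recordings, and a global phase error is handled
separately by `sim_config(phase_error = ...)` and `estimate_phase()`.

### The three cases and the size effect

An event's case is read off its Re projection relative to a resolution
floor `eps`: case I (`|dRe| <= eps`), case II (`dRe > eps`), case III
(`dRe < -eps`). For a two-state step from `Gp_pre` to `Gp_open` (with
`T^2 = 1`),

$$\mathrm{sign}(\Delta Re) = \mathrm{sign}\big((\omega C_v)^2 - G_{p,pre}
G_{p,open}\big),$$

so a decremental projection requires a conducting ("nearly closed")
pre-fused pore and is favoured by small vesicles; `dRe(Gp)` for a
from-closed opening peaks at exactly `Gp* = omega Cv` (about 5 pS for a
0.5 fF vesicle at 1591 Hz). Both facts are verified in the test suite
against grid-search and bisection oracles.

## Tunable parameters

* `circuit_params()`: `R_A` (ohm, default 0), `G_M` (S, 0), `C_m` (F, 0),
  carrier (Hz, 1591). Defaults encode the phase-corrected analysis frame.
* `detection_params()`: `window` (samples, 20) — half-width of the
  mean-difference change statistic; `threshold_k` (5) — detection threshold
  in SDs of that statistic, putting the per-position false-positive rate at
  the Gaussian `2*pnorm(-5)` tail; `min_event_duration` (0.1 s);
  `pairing_tolerance` (0.25) — maximum relative on/off amplitude mismatch;
  `epsilon_re` (`"auto"`).
* `pore_diameter()`: pore length 15 nm and resistivity 1.0 ohm·m are
  arguments, never baked into results — reported diameters are only as good
  as these geometry constants, which published work does not agree on.

### The Re resolution floor

`epsilon_re = "auto"` resolves to three times the standard error of the
plateau-difference amplitude estimator, i.e. `3 * sd_Re * sqrt(2/window)`
with `sd_Re` the per-sample Re noise estimated robustly (median absolute
deviation of first differences, divided by `sqrt(2)`) from
calibration-free samples. The floor is compared against *measured step
amplitudes*, which are means over plateaus, so propagating the per-sample
SD through the estimator is the consistent choice; using the raw per-sample
SD would misclassify well-resolved small Re steps as case I. The same
floor is shared by classification and inversion, so "case I" and
"fully open" are the same statement.

## The synthetic-trace generator

`generate_trace()` emulates a demodulated cell-attached recording: zero
baseline; per event a plateau offset equal to the forward-model two-state
step; 10 fF calibration pulses every 10 s (0.5 s wide, a pure `Im` step of
`omega * 10 fF`, about 100 pS at 1591 Hz); optional global phase rotation;
independent white Gaussian noise per channel. Ground truth (times,
amplitudes, case labels, pore parameters) rides along for validation.

Choices the emulated recordings do not pin down, fixed here once:

* demodulated sampling rate 100 Hz — typical for lock-in capacitance
  traces;
* event open durations uniform on 0.2–5 s, with 0.5 s of clear baseline
  around each event — long enough to estimate plateaus;
* simulation at the demodulated level, not the raw carrier current: the
  analysis consumes lock-in outputs, so the 111 mV carrier amplitude is
  metadata only;
* instantaneous step edges and uncorrelated noise between channels.

`cell_profile()` anchors ensemble distributions on representative unitary
events: lactotrophs (larger vesicles, log-normal median 1.2 fF) versus
astrocytes (smaller, median 0.6 fF, with case III considerably more
frequent); nearly closed pre-fused conductances centred on ~5 pS
(lactotroph) / ~2 pS (astrocyte), incompletely open conductances 20–60 pS.
Intended cases are realised by resampling against the analytic sign
boundary, and case I is generated as a fully-closed-to-fully-open
transition so its zero Re projection is exact. What passing tests on these
ensembles show is that the pipeline inverts its own forward model under
realistic amplitudes and noise — not that real membranes lack drift,
flicker within episodes, correlated demodulation noise or staircase
multi-vesicle events, none of which are modelled.

## Detection and measurement

Change points are detected on the Im channel only — an event is *defined*
by its capacitance step; its Re projection may legitimately be zero — by a
difference-of-adjacent-window-means statistic (CUSUM-like, chosen for
transparency), with contiguous same-sign excursions collapsed to their
extremum. Calibration epochs are masked from both detection and plateau
averaging. Amplitudes on both channels are differences of plateau means
around the Im-defined edges, excluding half a window next to each edge
(shrunk for short plateaus, keeping at least a third of the segment); the
noiseless case has a tiny relative threshold floor so exact plateaus do not
generate spurious flags. On-steps pair with the next off-step when
amplitudes agree within the pairing tolerance; unpaired on-steps are
reported, never dropped. Phase is recovered from the calibration pulses as
the argument of their summed complex steps minus `pi/2`, a least-squares
rotation to pure Im.

## Case III inversion: a visible model violation

The from-closed estimators are undefined for decremental steps. The
package still reports `Cv`/`Gp` magnitudes for case III events — evaluated
on `|dRe|`, so scatter analyses across cases share axes — but flags them
`applicable = FALSE` with provenance `"two-state"`. These numbers are
biased relative to the generating parameters (the test suite asserts
recovery only for `gp_pre = 0` events); treating them as point estimates of
vesicle size is a known limitation, inherited from the estimator, not a
bug.

## Numerical choices

* Fully open is an explicit flag (`Inf` internally, serialised as a string
  in JSON sidecars), never a large sentinel conductance.
* `Gp = 0` and `Gp -> Inf` limits are analytic continuations.
* The `dRe` zero crossing in size is located by 200 bisection steps
  (relative accuracy ~1e-9 on femtofarad scales) in the tests, against the
  closed form `sqrt(Gp_pre * Gp_open)/omega`.
* All randomness flows through explicit integer seeds; generation restores
  the caller's RNG state, and identical configurations give byte-identical
  traces and pipeline outputs.

## Problem sizes

The validation suite runs ensembles of 100 events on 900 s traces at
100 Hz (90,000 samples) for end-to-end recovery, 20 seeded replicates of
50 + 50 events for the per-case correlation contrast, and
three-decade × two-carrier grids for forward/inverse consistency; the
whole suite completes in well under a minute on a single core.
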