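---
title: "Models and methods behind frapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind frapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapkit)
```

frapkit quantifies three live-cell readouts of a fluorescently tagged
DNA-repair factor — strip-FRAP recovery, accumulation at a local damage
site, and flow-cytometry protein levels — and ships simulators that generate
each input with known ground truth. This vignette is the package's own
account of the underlying models, the defaults and why they were chosen,
the numerical decisions, and what the recovery tests do and do not
demonstrate about real data.

## The strip-FRAP model

A nucleus is collapsed to a one-dimensional domain along the axis normal to
the bleached strip; because the strip spans the nucleus in the orthogonal
direction, the concentration profile is effectively one-dimensional after a
strip bleach, and a 1-D model captures the geometry at desk-scale cost.
Three states partition the tagged protein:

* **free**, diffusing with coefficient `D` (µm²/s);
* **exchanging bound**, chromatin-bound but turning over with association
  rate `kon*` (pseudo-first-order, 1/s) and dissociation rate `koff` (1/s);
  bound molecules do not diffuse;
* **immobile**, a damage-induced fraction `f_imm` treated as `koff = 0`
  within the acquisition window. This mirrors what the immobile-fraction
  statistic actually measures — non-recovery within ≤ 12 s — rather than
  asserting that damage-bound molecules never exchange.

At equilibrium the mobile pool `1 − f_imm` splits between free and bound as
`koff : kon*`. Bleaching multiplies all three species inside the strip by
`bleach_depth` with a sharp top-hat profile; the acquisition protocols in
the literature state laser powers but no bleach profile, and the top-hat is
the testable choice. Observation is the strip mean times a per-cell
brightness factor and a whole-field monitor-bleaching factor
`exp(−monitor_bleach_rate · t)`, plus additive background and measurement
noise.

### Numerical scheme

Integration uses operator splitting per internal step: an explicit
conservative diffusion update with reflecting boundaries, then the exact
exponential relaxation of the linear binding reaction (so the reaction
introduces no step-size error). The internal step is decoupled from the
frame interval and refined automatically so that `D·dt/dx² ≤ 0.45`, safely
inside the explicit-scheme stability bound of 1/2; if more than 10⁶
substeps per frame would be needed the simulator raises an explicit error
rather than degrading. The flux-form diffusion update conserves total
signal to machine precision, which the conservation test checks at relative
1e-9.

### Bleach timing and the meaning of I0

The beam is on during each bleach frame, so the simulator applies the pulse
of bleach frame *k* at the end of that frame's interval — the first
recovery frame is recorded immediately after the final pulse. This matches
the statistic's definition of `I0` as the intensity *immediately after*
bleaching. The alternative convention (pulse at the frame's start, first
sample one interval later) lets a fifth to a quarter of the mobile pool
re-enter the strip before `I0` is read, which inflates the immobile
fraction estimate by 0.06–0.08 in realistic regimes; under the convention
used here the estimator is unbiased whenever the reference plateau is
measured in the same window (complete recovery inside the window is not
required, because the renormalization divides it out).

### Simulator defaults

The defaults of `frap_sim_config()` are the package's study conditions for
parameter-recovery tests: a 25 µm domain in 125 bins, a 2 µm central strip,
`D = 30` µm²/s (fast free diffusion, so the free pool re-equilibrates
within a frame), `kon* = 5`/s and `koff = 0.15`/s (a reaction-dominant
mobile pool, ~97% bound, ~7 s residence time), full bleach, Gaussian noise
with CV 5% (single-cell curves from confocal acquisitions are visually
smooth; a Poisson option exists), per-cell brightness CV 10%, and 3
experiments × 10 cells — the replication structure typical of published
FRAP figures. Monitor bleaching defaults to 0 because the normalization
pipeline deliberately does not correct for it; an optional rate exists for
stress-testing.

The protocol presets mirror standard strip-FRAP acquisition: 5 pre-bleach
frames, 2 bleach frames, 0.4 s frame interval, then 30 recovery frames with
steady window 8–12 s (CSB preset) or 20 recovery frames with window 5–8 s
(UVSSA preset). For the UVSSA preset a 200 ms pre-bleach interval is also
plausible from the acquisition description, but 20 recovery frames can only
contain a 5–8 s window at 0.4 s per frame, so 0.4 s is used for both
presets; a custom `frap_protocol()` covers any other combination.

## The immobile-fraction statistic

`immobile_fraction()` computes
`F_imm = 1 − (I_final,UV − I_0,UV)/(I_final,unc − I_0,UV)` literally:

* `I0` is the single first post-bleach frame, not a minimum over frames
  (configurable per-cell variants can be built from
  `immobile_fraction_cells()`);
* both numerator and denominator use the *treated* curve's `I0` — a
  regression test pins this against the tempting but wrong variant that
  uses the reference's own post-bleach floor;
* window endpoints are inclusive and frame membership is decided on time
  with 1e-9 tolerance;
* the result is not clamped: noisy data may legitimately yield values
  slightly outside [0, 1], and reporting the raw value keeps the statistic
  unbiased and testable.

The default computes the statistic on hierarchically averaged ensemble
curves (cells within experiment, then unweighted experiment means), which
matches how published recovery curves are plotted and renormalized; whether
the original analyses averaged before or after renormalizing is not
deducible from the text, so the per-cell mode reports the distribution
instead of guessing. Whether reference cells were measured in the same
session is likewise left to the caller's condition mapping.

`fit_two_state()` inverts the closed-form recovery model
`F(t) = β + (1−β)[f_free(1−e^{−t/τ_diff}) + f_exch(1−e^{−koff·t})]`
by bounded Levenberg–Marquardt least squares. Starting values come from the
curve itself (first value → bleach depth, late plateau → immobile fraction,
half-recovery time → rates). Flat curves are returned as degenerate rather
than errors, and non-convergence is always flagged. The fit assumes the
bleached pool is a negligible fraction of the total; in small nuclei the
bleached-pool dilution is absorbed into an inflated apparent immobile
fraction, which is why recovery tests for the fit run with a strip that is
0.25% of the domain.

## Accumulation kinetics

`simulate_accumulation()` draws per-cell traces
`baseline·[1 + (fold−1)(1−e^{−rise·t})]·e^{−decay·t}` plus background and
noise. Defaults: fold 1.4 (the modest saturation observed for repair-factor
recruitment to local UV damage), rise 0.05/s, no decay (the decay term
exists to emulate factors that slowly leave the damage site), 5 pre-damage
frames, 120 frames at 2 s, 40 cells. The pipeline normalizes to the
pre-damage mean (exactly 1), re-zeroes time at damage induction, reports a
plateau as the mean over a caller-chosen late window, and integrates AUC by
the trapezoid rule — the published quantity names the area, not the rule,
and the trapezoid on the acquisition grid is the standard choice.
Endpoints inside a frame interval are linearly interpolated, which makes
AUC exactly additive over adjacent ranges. The integration range is a
required argument of the comparison workflow: no default pretends to be a
published choice.

Group comparison uses the unpaired two-sample t test on per-cell AUCs,
equal-variance by default to match common graphing-software behaviour, with
a Welch flag. Its type-I error under the simulator's null (identical
configurations, independent seeds) is checked at α = 0.05 over 2000
replicates.

## Flow cytometry and transcription scores

`simulate_flow()` draws intact single cells with log-normal reporter
intensity (σ = 0.35 by default, a typical ~36% CV for protein abundance)
inside a compact FSC-A/SSC-A cluster, plus low-scatter debris with dim
autofluorescence and doublets at twice the scatter and summed reporter
signal; a treated sample's reporter is scaled by `1 − degradation_fraction`.
The default gate is rectangular on FSC-A/SSC-A (published gates rarely come
with coordinates; the rectangle is logged and a quantile-style custom gate
can be supplied), separates the populations by more than four standard
deviations, and is idempotent by construction. `relative_levels()` uses the
arithmetic mean of linear fluorescence — the "average FI" statistic — with
a geometric option, and sets the reference sample to exactly 100.
Significance testing between samples is deliberately delegated to standard
routines (e.g. `stats::aov` two-way ANOVA on the per-sample summaries);
the package does not re-implement inferential statistics.

`rrs_score()` scores recovery of RNA synthesis as
`100 · mean(treated)/mean(mock)` on per-cell integrated intensities and
returns per-cell relative values for plotting or ANOVA.

## The image mode

`render_image_stack()` exists to exercise the image-reading path: it paints
a nucleus ellipse, a strip whose per-frame mean reproduces a supplied
profile, and an extracellular background region into 16-bit frames, and
returns the label masks (`0` outside, `1` background, `2` nucleus, `3`
strip). `extract_trace()` inverts it; the round-trip is tested at 0.02 RMS
on normalized curves. This is a rendering of the measurement geometry, not
an optical simulation: there is no point-spread function, no laser physics
and no cell movement.

## What the simulations do and do not establish

Passing recovery tests show that the pipeline's arithmetic is faithful and
that its estimators are calibrated *under the generative model*: Gaussian
or Poisson noise around a deterministic 1-D reaction–diffusion profile,
log-normal cell brightness, stationary cells, and noise-free condition
labels. Real data add focus drift, cell movement, heterogeneous expression,
detector nonlinearity and monitor bleaching — none of which the generator
emulates (monitor bleaching can be switched on, but the pipeline, like the
published normalization, does not correct for it). Published immobile
fractions from living knockin cells (for example a rise from ~13% to a
~50% plateau with UV dose) are therefore not reproduction targets; the
package instead checks the qualitative saturating shape of a simulated dose
series.

## Problem sizes

The shipped tests and the acceptance script use 3 experiments × 10 cells
per FRAP condition (37 frames each), 40-cell accumulation ensembles (120
frames), 2000 Monte-Carlo replicates for t-test calibration at 10 cells per
group, and 5000 events per flow sample — the replication structure the
analyses are designed for, at which every stochastic tolerance in the test
suite has comfortable margin.
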