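---
title: "Detecting patient-ventilator asynchrony by hysteresis loop analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting patient-ventilator asynchrony by hysteresis loop analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventasync)
```

## The problem and the model

Patient-ventilator asynchrony — the mismatch between a mechanically
ventilated patient's own respiratory effort and the ventilator's delivery
cycle — is common in intensive care, is associated with prolonged weaning
and worse outcomes, and is usually detected by skilled visual inspection of
pressure and flow waveforms. `ventasync` automates that inspection by
analysing the breath's pressure-volume (PV) loop as a hysteresis loop.

Each breath's PV loop is split at the turning point of maximum volume into
an inspiratory and an expiratory half-cycle. A half-cycle is approximated
by an r-segment piecewise linear regression

P(i) = k_s · V(i) + P_b + e(i), one (k_s, P_b) pair per volume segment,

where the segment slopes k_s are local elastances (cmH2O/L), the P_b are
pressure-axis intercepts and e is measurement noise. A non-asynchronous
half-cycle is assumed to follow a two-segment model (divided by the lower
or upper inflection point); patient effort superimposes extra segments
with characteristic slope-sign patterns. Classification therefore reduces
to identifying r, the breakpoints, and the signs and relative sizes of the
fitted slopes.

### Breakpoint search

For a given r the breakpoints minimise the total residual sum of squared
errors (RSSE) over all admissible combinations of candidate breakpoints,
each segment fitted by ordinary least squares. The search is implemented
as a dynamic program over prefix segment costs; on the same candidate grid
it is provably equivalent to exhaustive enumeration (the test suite checks
bit-for-bit agreement against an enumeration oracle on small problems).
Candidate breakpoints are the observed data points, capped at 400 evenly
spaced positions; at 100 Hz and ordinary respiratory rates every half-cycle
is searched exhaustively, and the cap only engages for unusually long
breaths. Segments are non-overlapping contiguous index runs (segment i
ends at breakpoint i; segment i+1 starts at the next sample): under this
convention an exact sampled polyline attains RSSE = 0, which keeps the
noise-free ground truth of the simulator well defined. Ties (totals equal
within 1e-12 relative) resolve to the lexicographically earliest
combination in traversal order. Each segment must contain at least
`min_segment_points = 5` samples (50 ms at 100 Hz), preventing degenerate
one-point segments.

### Model-order selection

The segment count starts at the non-asynchronous null of r = 2 and is
tested against r + 1 by the improvement ratio

F(r+1 | r) = (RSSE_r − RSSE_{r+1}) / σ²,

where σ² is the model variance calibrated from breaths assumed
non-asynchronous: the mean (or, in the record-level pipeline, the median)
of the two-segment RSSE/(N − 4) over the calibration window, floored at
1e-6 cmH2O² so noise-free synthetic data cannot produce a degenerate
divisor. The cascade stops at the first acceptance of the null or at
`r_max` (default 5).

Because the added breakpoint is optimised over the whole candidate grid,
the null distribution of F is a sup-type statistic, far heavier than a
fixed-breakpoint F distribution. We calibrated the critical value on the
null model (true two-segment polyline plus Gaussian noise, σ² known):
naive critical values such as qf(1−α, 2, N−2(r+1)) reject the null for
over 90% of normal half-cycles, whereas a Bonferroni union bound over the
candidate positions,

crit = 2 · qf(1 − α / n_cand, 2, N − 2(r+1)),

gives an empirical type-I rate of about 0.5% at α = 0.01 (slightly
conservative, as union bounds are) while leaving power untouched: archetype
distortions at default amplitude produce F in the 10³–10⁴ range. Both the
numerator df and α are configuration knobs recorded in run manifests.

The calibration window defaults to the first 20 breaths of a record with
the median estimator. The median, rather than the mean, is used by the
pipeline because the window is not guaranteed to be asynchrony-free: a
contaminated mean inflates σ² several-fold and silences the cascade,
whereas the median tolerates up to half the window being distorted.

## The classification rules

Seven types are recognised by predicates on the selected fits (slopes in
traversal order; V_T tidal volume; PEEP estimated as the pressure at the
breath's first sample):

| type | phase | signature |
|------|-------|-----------|
| fa (flow asynchrony) | inspiration | r = 4, signs (+,−,+,+), not the dc condition |
| rt (reverse triggering) | inspiration | r = 4, signs (+,+,−,+) |
| pc (premature cycling) | expiration | r = 4, signs (+,−,+,+), V(N0)−V(N1) < V_T/2 |
| dt (double triggering) | inspiration | r = 5, k1 > 0, k1 > k2, k3 > k2, k4 > k5, P(N3) < PEEP, P(N2) > P(N3), P(N4) > P(N3) |
| dc (delayed cycling) | inspiration | r = 4, signs (+,−,+,+), k4 > 2·k3 |
| ie (ineffective effort) | expiration | r = 4, signs (+,+,−,+), V(N0)−V(N2) > V_T/2 |
| at (auto triggering) | whole loop | both halves r = 2, all slopes > 0, end-expiratory volume gap > ε |

Design choices where the rule set was genuinely open:

* **Phase assignment** is not intrinsic to the sign patterns; it follows
  the type descriptions (fa/rt/dc/dt are inspiratory phenomena, pc/ie
  expiratory, at a whole-loop leak signature) and is fixed and covered by
  archetype tests. rt and ie share a sign pattern and are disambiguated by
  phase alone; no inspiratory ie is ever emitted.
* **fa vs dc**: the dc condition strictly implies the fa signs, so fa is
  defined as the signs *minus* the dc condition, making the two disjoint
  and letting every breath carry exactly one primary label.
* **Precedence** (dt, dc, fa, rt, pc, ie, at) resolves multi-matches; all
  matches are retained as evidence. The order puts the most specific
  inspiratory patterns first and the leak signature last.
* **ε** defaults to 0.1 · V_T per breath (an absolute override is
  supported), since no absolute leak magnitude is canonical.
* **dt** is fixed at r = 5 (`r_max = 5` by default); deeper searches are
  configurable but not default.
* A relaxed 3-segment fa variant (clear early-inspiratory pressure drop
  without the recovery segment) is available behind `relaxed_fa = TRUE`,
  off by default.

## The simulator: what it emulates and what it does not

The simulator is the package's study-condition generator: a
single-compartment equation of motion P = E·V + R·Q + PEEP − Pmus with a
two-regime elastance (default E = 12/20 cmH2O/L around an inflection at
0.22 L, R = 8 cmH2O·s/L, PEEP = 5 cmH2O, 15 breaths/min, I:E = 1:2,
V_T = 0.45 L, 100 Hz), volume-controlled (square flow) or
pressure-controlled (pressurisation ramp) delivery, additive i.i.d.
Gaussian measurement noise (defaults 0.2 cmH2O on pressure, 0.01 L/s on
flow), and per-type effort distortions.

Distortions are piecewise-linear in PV space rather than smooth effort
bumps. This is deliberate: a smooth bump has no well-defined true segment
count, so "the noise-free archetype selects its true r" would not be a
meaningful oracle. With polyline distortions the noise-free breath is an
exact polyline, its segment count and slope signs are ground truth by
construction, and the emitted flow is built to integrate (trapezoidally)
back to the volume trace exactly. Reverse triggering places its sag late
in insufflation — consistent with its delayed, ventilator-triggered
aetiology — which also keeps the two base-elastance segments long enough
to be statistically separable at default noise. Double triggering is
realised as a second, truncated ventilator cycle beginning before the
first exhalation completes; the segmenter merges a candidate breath whose
end volume exceeds 30% of its tidal volume into the following one, so the
merged breath's inspiratory half exposes the 5-segment pattern. The
auto-triggering leak is injected as an end-expiratory volume gap (default
20% of V_T, safely below the merge threshold and above the default ε).

The default evaluation mix assigns 7% of breaths to each type (49%
asynchronous overall, of the order of the high-incidence episodes reported
clinically); `n_breaths = 500` mirrors the per-patient evaluation unit of
bedside studies.

What passing tests on these data do **not** show: the simulator produces
idealised geometry. Real breaths have curvilinear limbs, baseline drift,
within-breath effort variability, secretions and cardiogenic oscillations;
real asynchronies blur into each other and into normality at low effort.
Synthetic sensitivity/specificity therefore bound the method's behaviour
under its own assumptions and validate the implementation, not bedside
performance.

## Numerical choices and degenerate inputs

* Vertical segments (all volumes identical) are flagged degenerate: slope
  undefined, SSE measured against the mean pressure.
* RSSE is always re-scored as the plain left-to-right sum of per-segment
  OLS residuals after the search, so reported values are independent of
  the dynamic program's internal arithmetic.
* A half-cycle with fewer than 2·(r_max + 1) points, or with its volume
  peak at the first or last sample, is flagged unfittable; rules inspecting
  it return false with "unfittable" evidence rather than erroring.
* Candidate breaths with tidal volume under 0.02 L are dropped as noise
  artifacts.
* Breath onset uses a two-threshold detector (sustained crossing of
  0.05 L/s with near-zero flow in a 3-sample look-back); placing the onset
  at the crossing sample keeps noisy expiratory-tail samples out of the
  next breath's first segment.
* The peak-volume tie (several samples at the maximum) resolves to the
  first such sample.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run: the seven noise-free
archetypes; a 500-breath noisy cohort at the default mix; 1000 normal
half-cycles for the type-I rate; 50 small half-cycles (N ≤ 30) for the
enumeration equivalence; 200 half-cycles for monotonicity/equivariance;
and a 4-point amplitude grid with 20 breaths per type and point. These
sizes give stable rates while keeping a full run in a few minutes on one
CPU.

## Known limitations

* PEEP is estimated from the breath's first pressure sample; on machines
  reporting set PEEP the estimate can be substituted upstream.
* The PSV preset approximates pressure support as PC with flow-cycled
  expiration and is marked experimental.
* Only one primary label is emitted per breath (matches are kept as
  evidence); magnitude grading of asynchrony and reconstruction of the
  unaffected loop are out of scope.
* The F-cascade's critical value is a union bound; its mild conservatism
  trades a fraction of a percent of sensitivity near the detection
  threshold for robust type-I control.
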