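---
title: "Measuring intrinsic excitability from current-clamp step protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intrinsic excitability from current-clamp step protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package measures

`stepclamp` analyses whole-cell current-clamp recordings acquired with a
serial square-pulse protocol: by default 14 steps of 100 pA from −400 to
+900 pA, 800 ms each, three trials per amplitude, sampled at 10 kHz. From
each cell's sweep set it extracts the measurement battery standard in
studies of neuronal intrinsic excitability, with operational definitions
fixed as follows.

**Passive properties.** The resting membrane potential (RMP) is the mean
voltage over the final 100 ms before step onset; by default the baseline
of the first recorded sweep set (the most hyperpolarized amplitude,
trials averaged) is used, since a per-sweep window is protocol-local and
testable, and an "all sweeps" variant is available. Every steady-state
quantity uses one convention: the mean over the final 160 ms of the
stimulus epoch. Input resistance is the steady-state deflection at
−100 pA divided by the injected current — measured at the smallest
hyperpolarizing step deliberately, because the hyperpolarization-activated
cation current (I~h~) that produces voltage sag is essentially inactive
there. The membrane time constant follows the 67% rule: the first time
after step onset at which the trial-averaged voltage crosses 67% of its
steady-state deflection, located by linear interpolation between samples
(for an ideal RC membrane this equals 1.109 τ). Sag at −400 pA is the
difference between the steady-state voltage and the most negative peak
during the step; the normalized sag divides this by the steady-state
voltage response so that cells of different input resistance are
comparable. A negative raw sag is reported as-is and flagged, never
clamped.

**Active properties.** Spikes are local maxima at or above −10 mV
preceded within 5 ms by a depolarization rate of at least 20 mV/ms, with
a 1 ms minimum separation; the threshold point is the first sample of the
sustained fast-upstroke run leading into the peak. These criteria are the
common dV/dt-based practice and every one of them is configuration
exposed. Rheobase is the smallest protocol amplitude evoking at least one
spike during the step; detection is per trial and the per-trial minima
are averaged. Waveform morphometrics (amplitude, half-width at 50% of the
threshold-to-peak amplitude, 10–90% rise, 90–10% decay, and
afterhyperpolarization relative to threshold) are taken from the first
spike of the minimal firing step, before sodium-channel inactivation or
hyperpolarization-activated currents distort the shape; level crossings
are interpolated linearly and the AHP trough is searched from the peak to
the next spike's threshold or 50 ms, whichever comes first. Instantaneous
frequency is the reciprocal of each interspike interval indexed by
interval number, and accommodation is summarized by the first three
interval frequencies plus the mean over a late inclusive range —
intervals 15–20 at +200 pA and 19–25 at +300 pA. (Published range
descriptions sometimes give an interval count and an index range that
disagree by one; when both are stated, the explicit index range wins.)
The per-cell firing indicator at
a step is 1 when a majority of trials contain at least one spike; an
"any trial" rule is available, since published per-cell indicators rarely
state their trial handling.

**Trial aggregation.** Passive measures are computed on the pointwise
trial-averaged trace, with detected spikes on depolarizing sweeps clipped
per trial (replaced threshold-to-threshold by linear interpolation)
*before* averaging. Spike-dependent measures are computed per trial and
aggregated afterwards — means for counts and delays, per-trial minima
then the mean for rheobase — because pointwise averaging destroys action
potential waveforms.

## Quality control and statistics

Cells are excluded when the series resistance drifts by 20% or more
between trial start and end (the boundary is inclusive); synthetic cells
without access resistance pass with a "not assessed" flag. Accommodation
analyses require more than 5 spikes at +100 pA, and 17+ spikes at steps
of +200 pA and above; both rules sit in a per-amplitude table that can be
overridden. Outliers are screened per measure within each group by a
two-sided, single-iteration Grubbs test at α = 0.05 — the common settings
of the widely used commercial implementation — and everything excluded
stays visible in the QC report with the triggering value.

Group comparison runs one two-sided test per measure: Welch's
unequal-variance t-test, or the Mann–Whitney U-test when either group
rejects normality by a Shapiro–Wilk gate at α = 0.05 (the criterion for
"non-parametric data" is rarely stated in papers; the gate is an explicit
stand-in, and fixed per-measure assignments or forced choices are also
available). U is reported as min(U₁, U₂) with midrank ties; the p-value
is exact by enumeration for tie-free pooled samples of 20 or fewer, else
the normal approximation with tie and continuity corrections. No
multiple-comparison correction is applied by default, matching the
per-measure reporting style of the field; a Holm option exists. Binary
per-cell indicators (firing at a step, resting below −80 mV) are
summarized descriptively as k/n fractions, not tested.

## The synthetic cohort

Because the recordings behind the study this pipeline emulates are not
deposited, validation uses simulated cohorts with known ground truth. The
generator is an adaptive exponential integrate-and-fire (AdEx) neuron
extended with a first-order H-type conductance:

$$C \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - g_h h (V - E_h) - w + I(t) + \xi(t),$$

with adaptation $\tau_w \dot w = a (V - E_L) - w$, sag activation
$\tau_h \dot h = h_\infty(V) - h$,
$h_\infty(V) = 1/(1 + e^{(V - V_h)/k_h})$, and optional
Ornstein–Uhlenbeck current noise $\xi$. This is the simplest model that
produces every measured phenomenon — sag and rebound, spike-frequency
accommodation, delay to first spike, an f–I curve — so conductance-based
multichannel models were rejected as disproportionate. The adaptation
current is a phenomenological stand-in for whatever potassium currents
drive accommodation in real granule cells, not a mechanistic claim.

Units are mV, ms, pA, nS and pF throughout, chosen so that nS·mV = pA and
pF/nS = ms make the ground-truth arithmetic exact: the passive input
resistance is 1000/g~L~ MΩ, the time constant C/g~L~ ms, and for a pure
exponential integrate-and-fire cell the rheobase is
g~L~(V~T~ − E~L~ − Δ~T~) pA. With subthreshold adaptation (a > 0) the
steady-state input conductance is g~L~ + a, and with g~h~ > 0 the numeric
rheobase is found by bisection on noise-free simulations instead.

The sag channel's activation midpoint sits at V~h~ = −108 mV with slope
5 mV. This is deliberate: the protocol premise is that sag is
*undetectable* at −100 pA (where input resistance is measured) while
prominent at −400 to −200 pA. A more depolarized midpoint violates that
premise — at V~h~ = −95 mV the H-current contaminates the −100 pA
deflection by roughly 20% — so the default encodes the measurement
assumption.

**Default group regimes.** Two regimes emulate the study's genotypes and
were calibrated once, to the published anchors only: the wild-type-like
group centres its *extracted* input resistance near 134 MΩ (g~L~ = 6.2 nS
plus a = 1 nS coupling), carries a prominent sag conductance (2 nS) and a
moderate adaptation increment (11 pA); the transgenic-like group has a
lower leak (4.9 nS, extracted R~I~ ≈ 168 MΩ), a resting level depolarized
by 2.5 mV, roughly half the sag conductance, and twice the adaptation
increment. These choices reproduce the directions reported in the study —
higher input resistance, lower rheobase, readier firing at +100 pA,
reduced normalized sag, stronger late accommodation — and its
accommodation scale at +200 pA (tens of Hz early, 20–30 Hz late). No
claim of quantitative biophysical fidelity is made; in particular the
transgenic-like firing fraction at +100 pA runs above the published 69%
because the depolarized resting level and the input-resistance anchor
jointly over-excite the model at that step.

**What the simulation does not emulate.** Spikes on output traces are
stylized one-sample excursions to the cutoff voltage, so that detector
tests exercise peak finding without modelling sodium kinetics. Waveform
morphometrics are therefore validated on parametric spike-shape fixtures
with closed-form geometry, not on simulated traces. Similarly, the
depolarized interspike envelope of a real cell is not reproduced, so the
steady-state voltage response of a *spiking* sweep reflects the model's
reset trajectory rather than a biological plateau. Passing tests
demonstrate that the measurement code implements its operational
definitions correctly and recovers known parameters; they do not certify
the simulator as a granule-cell model.

## Numerical choices

Integration uses exponential Euler on the linear parts with the
spike-initiation exponential treated explicitly, at an internal step of
0.05 ms resampled to the 10 kHz protocol grid; the exponential argument
is capped at (V~cut~ − V~T~)/Δ~T~ to avoid overflow. Each sweep starts
from the resting state found by settling 2 s at zero current, mirroring
the inter-sweep rest of the experimental protocol. Halving the step
changes noise-free subthreshold samples by less than 0.1 mV and the first
spike time of a train by less than 0.2 ms; later spikes in a long
adapting train accumulate a slow phase drift (about 1 ms by the
fifteenth spike), which is inherent to threshold-crossing integrators and
harmless for count-, threshold- and interval-based measures at the
protocol's resolution. All level crossings (67% time, half-width,
rise/decay points) use linear interpolation, bounding discretization
error at 10 kHz by about 0.1 ms. Noise is off by default; when enabled,
per-sweep streams are derived from (cohort seed, cell, amplitude, trial)
so any single sweep is reproducible in isolation. Degenerate inputs are
handled explicitly: non-firing cells carry missing values in every
spike-dependent column while passive columns stay defined, zero-variance
vectors yield no Grubbs outlier, and validation reports rather than
raises.

On a dV/dt-based detector the measured threshold necessarily sits above
the AdEx parameter V~T~ by about Δ~T~·ln(θ·C/(g~L~Δ~T~)) — the voltage at
which the exponential current first drives the commanded rate θ — roughly
11 mV for the default cell at θ = 20 mV/ms. Tests assert this closed-form
relationship rather than proximity to V~T~ itself.

## Validation suite design

The test suite validates each operation against an independent oracle:
closed-form RC responses and parametric spike geometries built without
the simulator, full-split enumeration for the exact Mann–Whitney p, the
hand closed form for Welch's t, the t-quantile formula for the Grubbs
critical value, and the simulator's own event log for spike detection.
End-to-end checks use a 20-cell noise-free recovery cohort (input
resistance within 2% and 67% time within 5% on the sag-free subgroup —
with g~h~ > 0 the H-current biases the −100 pA deflection by more than
2%, so passive-limit recovery is only exact where the mechanism is
absent — and exact rheobase-step agreement on all cells), plus a
directional check on the default regimes at seed 42 with 20 cells per
group.

Type-I calibration runs 100 cohorts of 12 cells per group drawn from
identical distributions and checks each measure's rejection rate at
α = 0.05 against a binomial interval. Because ~36 strongly correlated
measures are screened simultaneously, the per-measure interval is taken
at the Bonferroni-corrected level so that the whole calibration check has
roughly 95% joint coverage; with 36 simultaneous uncorrected 95%
intervals, at least one spurious failure would be the expected outcome of
a correctly calibrated system. The problem sizes above (12–20 cells per
group, 100 replicate cohorts, 0.05 ms integration) were chosen to keep
the full suite comfortably interactive while leaving every estimate's
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

Cells are treated as independent units, as in the emulated study; a
nested (cells-within-animal) mixed model would be more conservative and
is deliberately out of scope. The sweep-bundle format trades compactness
for diffability (one long CSV plus a JSON manifest); adapters for binary
acquisition formats (ABF, NWB) are specified as a generic conversion
contract, and the core never requires them. The Grubbs screen is applied
once per measure per group — iterated or ROUT-style procedures are not
implemented. Whether outlier screening in the emulated study pooled
groups or not is unknowable from the text; per-group application is the
more conservative reading.
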