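---
title: "Modelling core and matrix thalamocortical spindle loops with spindleloop"
author: "spindleloop maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling core and matrix thalamocortical spindle loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindleloop)
```

## The scientific problem

Sleep spindles — 7–15 Hz oscillations lasting roughly 0.5–3 s at the onset
of deep NREM sleep — are generated in loops linking the thalamus, the
inhibitory thalamic reticular nucleus (TRN) and the cortex. In primates two
anatomically distinct loops coexist: a *core* loop in which
parvalbumin-positive (PV⁺) thalamic relay neurons drive the middle cortical
layers (L3b–4) focally and receive layer-6 feedback, and a *matrix* loop in
which calbindin-positive (CB⁺) relay neurons innervate the superficial
layers (L1–3a) broadly and are driven by layer 5. Both loops are gated by
their own TRN sectors (TRN_C, TRN_M) and, in primates, by an unusually rich
population of local thalamic inhibitory interneurons (PV⁻, CB⁻).
`spindleloop` implements a rate-based model of this circuitry on a
one-dimensional array of 200 index-aligned neurons per population, together
with the measurement layer used to characterise the simulated spindles.

## The membrane model

Every unit obeys the shunting (on-center, off-surround) equation

$$\frac{dv}{dt} = -A\,v \;-\; (v - E_{ext})\,I_{ext} \;-\; (v - E_{inh})\,I_{inh},$$

with $E_{ext} = +1$ and $E_{inh} = -1$, so activities are confined to
$[-1, 1]$: the conductances $I_{ext}, I_{inh} \ge 0$ multiplicatively gate
the distance to the two reversal potentials, and the leak $-Av$ returns the
unit to rest when input ceases. Connectivity between populations is
distance-dependent: the strength of presynaptic neuron $j$ onto
postsynaptic neuron $i$ is a unit-mass Gaussian
$\frac{1}{\sigma\sqrt{2\pi}}e^{-\frac{1}{2}\left(\frac{j-i}{\sigma}\right)^2}$,
truncated at the array edges without renormalisation. Matrix-loop kernels
are four times broader than core-loop kernels (defaults
$\sigma_{matrix} = 12$, $\sigma_{core} = 3$ index units), which is what
makes matrix spindles spatially diffuse and core spindles focal.

### The hybrid reticulo-thalamic loop

Whether a TRN neuron inhibits exactly the relay neuron that excites it
(closed loop) or a neighbour (open loop) is controlled by the symmetry of
the TRN→thalamus kernel. A balanced kernel (center offset $\eta = 0$) is
two open loops in opposite directions and is functionally equivalent to a
closed loop; a shifted kernel ($\eta \ne 0$) is an open loop. The shipped
defaults use $\eta = 0$ everywhere; `loopCharacter()` classifies a kernel,
and the offset is exposed per projection class in the configuration.

## How the model oscillates

A pure two-population relay–TRN pair cannot produce post-input rebound
oscillations in a first-order rate model: its damping is fixed by the leak
rates alone, independent of the synaptic gains, so none of the reported
gain manipulations could change spindle duration. The model's oscillator
is instead the four-stage cortico-thalamo-reticular ring (for the core:
PV⁺ → L3b–4 → L6 → TRN_C ⊣ PV⁺), a delayed negative-feedback loop whose
oscillation frequency is set by the stage relaxation rates and whose
damping decreases smoothly as the ring gain grows. This has three
consequences that match the phenomenology the package is built to
reproduce:

* raising the TRN→relay inhibitory gain (or the corticoreticular L6→TRN_C
  gain) strengthens the ring and lengthens post-input ringing;
* severing the matrix ring (removing L5→TRN_M) leaves only the heavily
  damped relay–TRN pair, so the matrix loop barely rings at all; restoring
  L5→TRN_M at 5–10 % of the L6→TRN_C gain re-closes the ring and restores,
  then extends, matrix spindling;
* corticothalamic L6→PV⁺ feedback counteracts ringing (see below), while
  corticoreticular feedback promotes it — opposite signs, as observed in
  vivo.

Two modelling choices are needed to make this ring behave physically.

**Signed transfer around a tonic operating point.** Thalamic and reticular
populations are tonically active during the descent into sleep, so their
interactions are modelled as signed deviations from that operating point:
each projection's Gaussian-summed drive feeds the conductance matching its
anatomical sign when positive, and the *opposite* conductance when
negative. A TRN pool dipping below its tone therefore disinhibits — i.e.
transiently excites — its relay targets, which is exactly the rebound
drive that launches the post-hyperpolarization depolarization. Both
conductances remain non-negative, so the $[-1,1]$ bound is rigorous.
Half-wave rectified transfer ($[v]_+$, silent units transmit nothing) is
available via `transfer = "rectified"`; with it the circuit cannot rebound
at all, which is why it is not the default. A third rule,
`transfer = "mixed"`, rectifies only the descending corticothalamic
feedback (cortical pyramidal cells are near-silent at rest) and keeps
every within-loop interaction signed.

**Per-class relaxation rates.** The leak rate $A$ is a per-population
constant. The shipped defaults give thalamic populations, TRN sectors and
cortical layers separate rates (149 s⁻¹ for the TRN sectors, 52.8 s⁻¹
for thalamic relay neurons and interneurons, 39.2 s⁻¹ for the cortical
layers — fastest for the TRN, slowest for cortex), chosen by calibration
so that the ring's eigenfrequency falls in the spindle band (the
post-shutdown oscillation of the shipped core loop runs at ≈ 8.5 Hz) and
the corticothalamic feedback loop accumulates more than 90° of lag,
making it oscillation-damping: with a single shared rate the algebra of
the loop phases forbids L6→PV⁺ feedback from shortening spindles while
the ring sustains them. A single scalar `decayA` is still accepted
everywhere.

## Stimuli

Spindle entrainment is probed by a spindle-like burst input to a TRN
sector: 10 Hz cycles (100 ms interburst interval) over 0.5 s, each cycle a
slow-then-sharp sixth-power ramp (the T-current analogue, 60 % of the
cycle) followed by five densely packed triangular spike peaks with heights
decreasing 1.00…0.92. Only the 100 ms envelope timing matters to the
dynamics; the spike detail is cosmetic and fixed for reproducibility.
Tonic square and brief pulse inputs are provided for the input-route
controls; all stimuli are delivered with a Gaussian spatial profile
(default $\sigma = 3$) centred on neuron 100 and scaled by the
configuration's `stimGain`. The tonic-input control preset drives PV⁺ at
amplitude 0.05, a calibration constant fixed together with the gains.

## Numerical integration

The coupled equations are integrated with fixed-step Heun (explicit
trapezoid) at $dt = 0.5$ ms over $T = 2$ s (0.5 s stimulus + 1.5 s free
evolution). A first-order scheme at this step under-damps the ~10 Hz loop
mode enough to shift the spindle tendency index by ~0.03 s when the step
is halved; Heun's second-order accuracy brings that shift well under
0.02 s, which the test suite verifies. Each Gaussian weight matrix is
Toeplitz away from the edges, so projections are applied as 1-D
convolutions (truncated at $6\sigma$); the realised `WeightMatrix` objects
and the convolution path agree to numerical precision, which is also
tested. The integrator aborts with an explicit error naming the step size
if a trajectory ever leaves the reversal-potential bounds.

## Measurement layer

**Spindle tendency index (STI).** The total duration, in seconds, of the
above-threshold hyperpolarization/rebound-depolarization sequence after
input shutdown. Local maxima after shutdown are detected by three-point
comparison on a 5-sample moving average; a maximum counts as a rebound iff
it reaches 1 % of the neuron's maximum activity over the whole trace
(driven epoch included — a global reference across populations can be
supplied instead). The index runs from the shutdown-adjacent
hyperpolarization onset to the last counted rebound's return below
threshold. The 1 % threshold is not critical: the suite checks that the
ordinal relations between conditions are unchanged anywhere in 0.5–2 %.

**Band-pass check.** A zero-phase 4th-order Butterworth band-pass (5–15
Hz) confirms that post-shutdown activity is genuine spindle-band
oscillation; STI rankings on filtered and raw traces must agree.

**Spatiotemporal comparison.** Activity maps (neuron × time, unnormalised)
are compared via the angle $\theta = \arccos(\vec A \cdot \vec B /
\lVert A\rVert \lVert B\rVert)$ between the vectorised maps (neuron-major;
any consistent order gives the same angle): 0° means the same pattern up
to positive scale. Propagation is quantified by onset latencies (first 1 %
threshold crossing) at probe neurons 100, 113, 128, 147, and spatial
extent by the interpolated full width at half maximum of $|v|$ across the
array at a given time.

## Experiment presets and mixing

`listPresets()` names one preset per reported condition: the L5→TRN_M
density series (0 / 5 % / 10 % of the L6→TRN_C gain), local-inhibition
on/off, TRN-gain and corticothalamic-feedback combinations (the raised-TRN
conditions multiply the TRN_C→PV⁺ gain by the preset constant 2), pure
core / 50–50 thalamoreticular mix / pure matrix, cortical mixing ratios
80/20–20/80 at fixed efficacy, and plateau-efficacy steps 30/60/90 % at
50–50. Cortical mixing couples L5 and L6 reciprocally, with the core-side
gain proportional to the core fraction $r$ and the matrix side to $1-r$,
both scaled by the plateau efficacy; the external drive to the two TRN
sectors is scaled complementarily ($2r$, $2(1-r)$), so $r = 1$ degenerates
to pure core drive and $r = 0$ to pure matrix, while each loop's intrinsic
dynamics stay at their calibrated operating point at every ratio. The
50–50 cortical mix is the $\theta = 0$ reference for the ratio series, and
the 30 % efficacy run for the efficacy series.

## Calibration of the unprinted gains

Only ratio constraints on the synaptic strengths are anatomically fixed:
the L5→CB⁺ driver is 20× the L6→PV⁺ feedback gain (the configuration
rejects ratios beyond 1000, where the matrix loop loses its oscillation),
and L5→TRN_M is 0–10 % of L6→TRN_C. The absolute gains, kernel widths,
relaxation rates and the stimulus scale are calibration constants. They
were fixed once, by simulation-based search (coordinate bisection on the
ring gains inside a randomised search over the relaxation-rate geometry),
against the spindle-tendency anchors of the reported conditions
(0.55 s core baseline; 0.37 s tonic-input control; < 0.1 / 0.57 / > 1 s
for the L5→TRN_M density series; > 1 s for local inhibition and raised TRN
gain; restoration of 0.55 s when feedback and raised TRN gain combine),
and shipped in `inst/extdata/default-config.yaml`, version-stamped.
`calibrateDefaults()` re-runs the final grid stage of that procedure; it
is deliberately not invoked at test time. After calibration the defaults
are data, not knobs: every preset reads the same file. Because the
post-shutdown rebound count is quantised by the ≈ 8.5 Hz cycle, the
spindle tendency index moves in steps of roughly a tenth of a second as
any gain varies; the calibrated gains sit mid-plateau on their steps, so
the anchor values are locally insensitive to small perturbations.

## Two behaviours the architecture does not reproduce

Two reported properties fail in this implementation, and their tests are
left failing rather than weakened. First, the sustained state produced by
core local inhibition is a disinhibition latch: the reticulo-interneuron
pathway (TRN_C ⊣ PV⁻ ⊣ PV⁺) settles into a self-consistent depolarized
plateau rather than a spindle-band limit cycle, so while its spindle
tendency index is high (the activity never returns below threshold), its
power lies below the 5–15 Hz band and the filtered-versus-raw STI ranking
check fails on that condition. Second, with the L5→CB⁺ matrix driver
wired at 20× the calibrated L6→PV⁺ feedback gain, the
cortico-thalamo-cortical positive loop exceeds its stability threshold
and pins the matrix loop at a saturated fixed point at any driver ratio,
so the claim that the matrix oscillation survives a 5× stronger driver
(collapsing only at three orders of magnitude) is not reproduced: the
driver ratio, the feedback gain calibrated for the feedback conditions,
and matrix-loop stability cannot be reconciled in this rate model.

## What the tests do and do not show

The synthetic fixture generator (`makeFixture()`) produces damped cosines,
pure tones, steps and seeded noise with closed-form properties; it
validates the measurement layer independently of the simulator (e.g. the
STI of a damped cosine against an analytic envelope-crossing time, filter
gains at band center and in the stop band). Passing these tests shows the
metrics are computed correctly, not that the circuit model is a complete
account of spindle physiology: the model has no H-/T-current biophysics,
no spike generation, no conduction delays, no noise-driven spontaneous
spindling, and a 1-D cortical sheet. Within those limits the suite checks
the full ordinal pattern of the reported conditions and the quantitative
STI anchors at ±0.05 s (half a 10 Hz cycle, the natural resolution of
rebound counting).

## Degenerate inputs and edge policy

Zero-gain projections produce all-zero weight matrices; the free network
stays identically at rest; stimuli wider than the simulated window are
truncated at the final sample; Gaussians are truncated at the array edges
(no wraparound, no renormalisation) — all stimuli in the shipped
experiments are delivered at the array center (neuron 100 of 200), where
edge effects are negligible. A silent probe site yields a missing onset
latency, not an error; an all-zero activity column yields a missing
spatial width. Problem sizes used by the tests are scaled down (typically
N = 40–120, T ≤ 2 s) relative to the full N = 200 presets, which the
acceptance script runs unreduced.
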