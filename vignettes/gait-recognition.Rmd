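---
title: "Recognising pathological gait from plantar-pressure arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising pathological gait from plantar-pressure arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gaitpress)
```

## The problem

Toe-in, toe-out and flat foot are the most common reasons children are
referred for gait assessment. The diagnostic signal lives in the spatial
distribution of plantar pressure: in-toeing shifts load toward the
lateral midfoot and forefoot (by up to 61 % and 49 % respectively),
out-toeing toward the medial aspects (up to 72 % and 52 %), and a flat
foot enlarges the midfoot contact area. A low-cost 8×8 piezoresistive
insole sampled at 50 Hz captures enough of this to drive a classifier,
in two regimes: *dynamic* (natural level walking) and *static* (quiet
standing).

This vignette records how the package implements that pipeline, which
knobs matter, and which choices were genuinely open.

## From pressure to features

A walking recording is an (frames × 64) matrix of non-negative cell
pressures. The dynamic feature extractor assumes the underlying process
is approximately stationary over a window spanning several gait cycles,
so temporal structure can be discarded in favour of spectral structure:

1. slide a 512-frame window (≈ 10 cycles at 50 Hz and a 2 steps/s
   cadence) along each sensor, default stride 25 frames (0.5 s);
2. taper with a Hann window and take DFT magnitudes, `|S(k)|`,
   k = 0…511;
3. sum magnitudes over the five half-open bands (0,2], (2,4], (4,6],
   (6,8], (8,10] Hz, using one-sided bins k = 1…256 only — the DC bin
   is excluded because it carries bodyweight, not gait;
4. concatenate the 30 masked sensors × 5 bands into a 150-vector and
   normalise to unit L2 norm, which cancels any positive rescaling of
   the input (bodyweight invariance is exact up to floating point, and
   is tested as such).

Static segments use only the per-sensor time-mean (the DC component):
a unit-norm 30-vector.

Interpretation choices that the design left open, fixed here:
"amplitude" is read as magnitude `|S(k)|`, not power; band edges are
half-open (lo, hi] at bin frequencies k·fs/L; the taper is a Hann
window of the same width as the FFT; an all-zero window (foot in the
air for a full window) yields a flagged zero vector rather than an
error. The 30-cell mask is not recoverable exactly from the source
figure, so the package ships a foot-shaped default (3×2 heel block,
eight in-arch midfoot cells, sixteen forefoot cells, row-major order)
and makes the mask a configuration item — downstream only the dimension
and its fixed order matter.

## Reduction and classification

Features are reduced either by PCA (centred, sample covariance,
minimal leading components reaching a 90 % explained-variance target)
or by a multiclass linear discriminant maximising

$$J(W) = \frac{\operatorname{tr}(W^\top S_B W)}{\operatorname{tr}(W^\top S_W W)}$$

through the generalized eigenproblem $S_B w = \lambda S_W w$, keeping
$d \le C-1$ directions (3 for the four gait classes). With 150 features
and few samples $S_W$ is singular, so it is ridge-regularised with
$\varepsilon\,\mathrm{tr}(S_W)/p \cdot I$, $\varepsilon = 10^{-6}$ —
the standard shrinkage fix, small enough not to perturb well-posed
problems. Eigenvector signs follow the largest-magnitude-entry-positive
convention so serialised models are reproducible.

The SVM solves each one-vs-one soft-margin dual by SMO-style pairwise
coordinate ascent (penalty C = 1, KKT tolerance 1e-3). The first index
sweeps all points in order; the partner is chosen by the maximal
|E_i − E_j| heuristic, falling back through the remaining candidates
when an update is degenerate — without that fallback the solver can
stall on non-separable data with live KKT violations. The RBF width
defaults to 1/(n_features × variance of the pooled feature entries).
Multiclass prediction is one-vs-one voting with ties broken toward the
earlier class in the canonical order (normal, toe-in, toe-out, flat).

The neural alternative is deliberately small: 3 layers in total, 10
logistic hidden units, softmax output, full-batch gradient descent on
the mean cross-entropy (500 epochs, learning rate 0.01, seeded
N(0, 1/√fan-in) initialisation). Activation, optimiser and epoch count
were unstated in the source design; these defaults favour bit-level
reproducibility over training speed.

## The sensor model

Cell resistance follows $R_x = K_{p-r}/P$; the non-inverting amplifier
and m-bit ADC give

$$D = 2^m \frac{K_{p-r} + P R_f}{K_{p-r}} \frac{V_{ref}}{V_{adc\_ref}}.$$

Defaults: $V_{ref}$ = 0.5 V, $V_{adc\_ref}$ = 5 V, m = 10,
$R_f$ = 10 kΩ, and $K_{p-r}$ = 1.2 MΩ·kPa chosen so the 0–1000 kPa
sensing range maps inside the 1024-count span without saturation
(children's pressures stay below 700 kPa). The ADC truncates: the real
value is floored, then clipped to [0, 1024] — rounding behaviour was
unspecified and floor matches hardware truncation. Zero load is an open
circuit, represented in network computations by a finite 1 MΩ unloaded
resistance: that value is typical of an unloaded piezoresistive film,
keeps the nodal solver well posed, and is what makes sneak-path
crosstalk visible at all (with a much larger sentinel the perturbation
rounds to zero counts).

Crosstalk is modelled by exact nodal analysis rather than a first-order
approximation: with unselected row/column channels floating, Kirchhoff
current balance at the 14 floating nodes yields the effective
resistance seen by the amplifier; the same code run with the
elimination drive scheme (unselected rows grounded, unselected columns
at $V_{ref}$) degenerates analytically to the single-cell path, so an
eliminated scan equals the ideal per-cell output bit for bit — an
identity the test suite asserts, alongside agreement of the floating
solve with an independently built full-graph-Laplacian oracle on 2×2
and 3×3 arrays.

Calibration fits counts on load (kg) by ordinary least squares over the
0 → 11 → 0 kg double pass; a perfect fit through constant counts is
defined to have r² = 1.

## What the generator emulates — and what it does not

No public recordings exist, so the generator is a first-class module
defining the study conditions:

* **Spatial templates.** An 8×8 region map (heel rows 1–3, midfoot rows
  4–5, forefoot rows 6–8; medial columns low-numbered) with a
  heel-dominant normal template (45 % heel, 4 % arch, 11 % lateral
  midfoot, 40 % forefoot). Class templates apply the regional
  multipliers quoted above before renormalising; the flat template
  additionally activates all twelve midfoot cells (versus eight
  nonzero in the normal template) at a 30 % midfoot share.
* **Temporal structure.** Stance occupies 60 % of the cycle (standard
  gait physiology); within stance, heel → midfoot → forefoot regions
  are activated by raised-cosine bumps centred at 15 %, 45 % and 80 %
  of stance. The gait-cycle rate is cadence/2 (two steps per cycle);
  the default 2.0 steps/s puts ≈10 cycles in each 512-frame window.
  Integer frame-periods are generated exactly periodic.
* **Scale.** Pressure is physical: p = m·g·(load share)/cell area, with
  2.5 cm² cells (a 64-cell insole of ≈160 cm²) and a peak dynamic load
  factor of 1.8× bodyweight; the default cohort's masses (paediatric
  2×age+8 kg for ages 5–10) keep peaks well under 700 kPa.
* **Noise and individuality.** I.i.d. truncated Gaussian sensor noise
  (default sd 2 kPa); log-normal per-region template jitter per subject
  (sd 0.05) modelling individual load patterns; per-trial posture
  jitter in the static section (sd 0.1) modelling children standing
  unnaturally when asked to stand still; a slow anterior–posterior sway
  (0.25 Hz, 3 %) on standing trials. The default 17-subject cohort
  mirrors a realistic referral mix: 9 flat, 4 normal, 2 toe-in,
  2 toe-out.
* **Bookkeeping.** `make_dataset()` plans recording durations so that
  downstream windowing yields exactly the requested samples per class,
  and is bit-deterministic under its seed.

Foot-progression angle is carried as subject metadata only; the class
label, not the angle magnitude, selects the template — the method
classifies categories, not angles.

Not emulated: left/right asymmetry, biomechanically simulated gait
(double support, speed variation within a trial), inter-trial drift,
sensor hysteresis and temperature effects. Consequently a passing suite
shows that the pipeline recovers class structure of the kind the
published percentages describe; it cannot certify accuracy on real
children, whose recordings are unavailable.

## What the evaluation shows

The acceptance suite runs the full chain at 200 windows per class
(seed 0): the discriminant + linear-SVM pipeline reaches ≥95 %
stratified tenfold accuracy in the dynamic section and ≥90 % in the
static section, while the same pipeline on label-permuted data sits at
25 ± 5 % — the chance floor for four balanced classes. These problem
sizes were chosen as the smallest at which the fold counts are
meaningful (20 test samples per fold per class).

Generalization to unseen subjects is a different matter, and the
package reproduces the direction of the published observation
deliberately: with strongly idiosyncratic subjects (template jitter
sd 0.5, two subjects per class) leave-one-subject-out accuracy falls
toward chance while within-subject cross-validation stays above 90 %.
Even at the default jitter the 17-subject LOSO accuracy is low: FFT
band-energy features are cadence-sensitive, every synthetic subject
walks at its own cadence (1.8–2.2 steps/s), and the rare classes have
only two subjects — so held-out subjects land between training
clusters. This is the amplified form of the real finding (toe-in and
toe-out generalization below 50 % on seventeen real children) and is
reported honestly by `scripts/acceptance.R` rather than smoothed away.
Static accuracy is kept at or below dynamic accuracy by the posture
jitter, again matching the reported direction.

## Numerical and degenerate-input choices

* ADC quantisation: floor then clip (see above).
* All-zero feature windows: flagged zero vector, not an error
  (robustness in streaming use).
* `calibrate_cell()` on identical loads: error (slope undefined).
* One Euro filter: first sample passes through unchanged; with β = 0 it
  is exactly the single-pole smoother with
  α = 1/(1 + fs/(2π·min_cutoff)). Defaults min_cutoff = 1 Hz,
  β = 0.05, d_cutoff = 1 Hz; filtering is *off* by default in the
  classification pipeline — the filter serves display smoothing, and
  nearly all gait energy lies below 10 Hz anyway.
* Fold dealing: within-class shuffle then round-robin, so per-fold
  class proportions are exact to ±1 sample.
* t-tests: Welch by default (safer under unequal fold variances), the
  pooled-variance form as an option; two identical zero-variance groups
  report t = 0, p = 1.
* Timing (`Time cost (ms)`) is reported but never asserted against — it
  is hardware-dependent.
* "Average precision (%)" is computed as macro-averaged precision over
  the four classes; the overall accuracy is reported alongside it since
  the two are used interchangeably in this literature and coincide on
  balanced, near-diagonal results.

## Known limitations

The generator's class separations are, by construction, cleaner than
real paediatric data: within-subject cross-validated accuracy saturates
near 100 %, so the package's CV numbers should be read as "the pipeline
is implemented correctly and the conditions are separable", not as a
forecast of clinical performance. The sensor mask and several circuit
constants are reconstructions of unpublished details and are exposed as
configuration rather than asserted as ground truth. The crosstalk model
captures first-order sneak paths through an idealised resistive
network; switch on-resistance, line resistance and amplifier input
impedance are ignored.
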