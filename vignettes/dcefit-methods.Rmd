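---
title: "Models and methods behind dcefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcefit)
```

# The problem

Dynamic contrast-enhanced MRI (DCE-MRI) acquires a rapid series of
T1-weighted images while a gadolinium contrast agent (CA) washes into and
out of tissue. The CA shortens T1, so signal enhancement over time encodes
the exchange of tracer between blood plasma and the extravascular
extracellular space (EES). `dcefit` estimates, pixel by pixel over a region
of interest (ROI), the parameters of five standard open two-compartment
formulations of that exchange, along with model-free descriptive statistics,
and ships a digital reference object (phantom) generator so the entire
pipeline can be validated against known ground truth without any external
data. It is aimed at preclinical (small-animal) studies, where arterial
sampling is impractical and AIF-free models (Hoffmann, reference region)
matter most.

# Kinetic models

All models derive from first-order exchange between plasma (concentration
$C_p$, fractional volume $v_p$) and EES (concentration $C_e$, fractional
volume $v_e$), governed by the transfer constant $K^{trans}$ (min$^{-1}$)
and washout rate $k_{ep} = K^{trans}/v_e$:

$$\frac{dC_e}{dt} = \frac{K^{trans}}{v_e}\left(C_p - C_e\right),
  \qquad C_t = v_p C_p + v_e C_e.$$

**Tofts** (`"tofts"`). Ignores the vascular term. With a bi-exponential
population input $C_p(t) = D \sum_i a_i e^{-m_i t}$ (instantaneous bolus),
the solution is closed-form:

$$C_t(t) = D\,K^{trans}\sum_{i=1}^{2}
  a_i\,\frac{e^{-k_{ep}t} - e^{-m_i t}}{m_i - k_{ep}}.$$

Fitted parameters: $K^{trans}$, $v_e$. With a sampled AIF the same curve is
computed as the discrete convolution
$C_t = C_p \ast K^{trans} e^{-k_{ep}t}$.

**Extended Tofts** (`"ext_tofts"`). Adds the intravascular term
$v_p C_p(t)$; fitted parameters $K^{trans}$, $v_e$, $v_p$. Appropriate for
well-perfused tumours where the plasma signal is not negligible.

**Hoffmann** (`"hoffmann"`). Works directly on the signal ratio, requiring
neither an AIF nor concentration calibration:

$$\frac{S(t)}{S_0} = 1 + A^H k_{ep}
  \frac{e^{-k_{ep}t} - e^{-k_{el}t}}{k_{el}-k_{ep}},$$

with amplitude $A^H$ (approximately the EES size) and renal elimination
rate $k_{el}$. It assumes slow plasma-to-EES transfer and a linear
signal-concentration relation.

**Larsson** (`"larsson"`). Also signal-domain, but driven by the shape of a
known multi-exponential plasma curve; the curve is normalised so that its
initial slope equals the fitted parameter $\dot S(0)$ exactly:

$$S(t) = S_0 + \dot S(0)\,
  \frac{\sum_i a_i (e^{-k_{ep}t} - e^{-m_i t})/(m_i - k_{ep})}
       {\sum_i a_i}.$$

The published typesetting of this model is ambiguous about the
normalisation; we resolved it to the form above because it makes
$\dot S(0)$ the exact initial slope — a property the test suite verifies by
numerical differentiation.

**Reference region** (`"rr"`). Eliminates $C_p$ by combining the rate
equation for the tissue of interest with that of a well-characterised
reference tissue (concentration $C_{t,r}$, known constants $K^{trans,r}$,
$v_{e,r}$):

$$C_t(t) = \frac{K^{trans}}{K^{trans,r}}\left[C_{t,r}(t) +
  \left(\frac{K^{trans,r}}{v_{e,r}} - \frac{K^{trans}}{v_e}\right)
  \int_0^t C_{t,r}(u)\,e^{-k_{ep}(t-u)}\,du\right].$$

The published grouping of this expression is also ambiguous; the form above
is the one that satisfies the exact identity $C_t \equiv C_{t,r}$ when the
tissue parameters equal the reference parameters, which the tests assert.

# MR signal calibration

The concentration-domain models need $C_t(t)$ from signal. The fast-exchange
linear relation $1/T_1(t) = 1/T_{10} + r_1 C_t(t)$ links concentration to
relaxation ($r_1$ in s$^{-1}$mM$^{-1}$, $T_{10}$ the pre-contrast T1).
Signal models:

* spin echo (short TE): $S = S_0\,(1 - e^{-TR/T_1})$;
* spoiled gradient echo (SPGR):
  $S = S_0\,(1-E)\sin\alpha / (1 - E\cos\alpha)$, $E = e^{-TR/T_1}$.

Both are inverted against the *measured* pre-injection baseline
$S_{0,\mathrm{base}}$ (per pixel, the mean over the pre-injection frames —
the variance-minimising estimator). Note the deliberate naming split: $S_0$
in the signal equations is the unknown equilibrium amplitude, while
$S_{0,\mathrm{base}}$ is the measured baseline; the two are never conflated.
For SPGR, substituting the baseline estimate of the equilibrium
magnetisation reduces the published inversion to

$$e^{-TR/T_1(t)} = \frac{1-q}{1-q\cos\alpha},\qquad
  q = \frac{S(t)}{S_{0,\mathrm{base}}}\cdot\frac{1-m}{1-m\cos\alpha},
  \qquad m = e^{-TR/T_{10}},$$

which is the exact algebraic inverse of the forward model — the test suite
round-trips both inversions to 1e-9 over random physiologic parameters.
Both calibrations depend only on the ratio $S(t)/S_{0,\mathrm{base}}$, so
they are invariant under detector gain.

$T_{10}$ can be estimated from variable-TR spin-echo images
(`estimate_t10()`): the two-image method solves the TR-ratio equation by
bracketed root finding on [1, 20000] ms; with more images a per-pixel
least-squares fit of $(S_0, T_{10})$ is used. The solver and bracket are our
choices; the source method statement does not prescribe them.

# Estimation

`dce_fit()` minimises the unweighted residual sum of squares with a bounded
Levenberg–Marquardt algorithm (MINPACK-derived, via `minpack.lm`). Choices
that matter:

* **Starting values** (unless overridden): $K^{trans} = 0.1$ min$^{-1}$,
  $v_e = 0.3$, $v_p = 0.02$, $A^H = 1$, $k_{ep} = 1$ min$^{-1}$,
  $k_{el} = 0.05$ min$^{-1}$; Larsson's $\dot S(0)$ is initialised from the
  first post-injection rise. These sit mid-range of the physiologic grids.
* **Bounds**: rates $\ge 0$; $v_e \in (0,1]$, $v_p \in [0,1]$. Box
  constraints prevent non-physical optima under noise.
* **Convergence**: relative tolerance $10^{-8}$ on cost and parameters,
  at most 200 iterations.
* **Uncertainties**: 1-sigma standard errors from
  $(J^\top J)^{-1}\hat\sigma^2$ at the solution (reported as the "±"
  values). They are stored only for converged cells.
* **Degenerate input**: an exactly flat curve is flagged
  `reason = "degenerate"` and never sent to the optimiser; `NA`/`NaN`
  frames are dropped (with an error if fewer than $p+1$ frames remain).
  Non-converged cells carry `NA` in maps — never silently dropped.
* **Hoffmann/Larsson baseline**: $S_0$ is fixed to the measured baseline
  mean rather than fitted (the alternative is a single extra free
  parameter; fixing it keeps the signal models identifiable on short
  series).

`fit_roi()` applies this per cell of the binned grid. Cells are
statistically independent and processed in a deterministic order; rerunning
a fit yields bit-identical maps. There is no randomness anywhere in
fitting — the only RNG in the package is phantom noise, which is always
seeded.

## Coarse resolution (binning)

ROIs carry a bin factor $k \in \{1,\dots,10\}$. The ROI bounding box is
tiled with non-overlapping $k \times k$ blocks anchored at its origin; each
cell's curve is the unweighted mean of its masked member pixels, and cells
without masked pixels are skipped. Averaging a full block of i.i.d. pixel
noise of standard deviation $\sigma$ leaves $\sigma/k$ — the 20% → 10/4/2%
ladder at $k$ = 2/5/10 that the acceptance suite verifies empirically.

## Semi-quantitative parameters

`semiquant_map()` computes, per cell: RCE (percent peak post-injection
enhancement over baseline; pre-injection frames cannot set the maximum),
IAUC (trapezoidal integral over a window after injection; default 60 s, the
conventional IAUC60, on calibrated concentration when relaxation parameters
are supplied, otherwise on percent enhancement — the units are recorded in
the map's configuration snapshot), and TTM (seconds from injection to the
first maximal frame, ties resolved to the earliest). Whether peak or
final-frame enhancement defines RCE is not prescribed by the source method
description; we use the peak.

# The phantom generator

`default_tofts_spec()` reproduces the layout of the public QIBA-style
single-compartment validation object: $K^{trans} \in \{0.01, 0.02, 0.05,
0.1, 0.2, 0.35\}$ min$^{-1}$ by $v_e \in \{0.01, 0.05, 0.1, 0.2, 0.5\}$ in
10×10-pixel patches (a 50×60 tissue region), a whole-blood strip beneath,
SPGR at flip angle 30°, TR 5 ms, 0.5 s frames, a 10-minute study with
injection at 60 s, tissue $T_{10}$ 1000 ms, blood $T_{10}$ 1440 ms,
haematocrit 45%. `default_ext_tofts_spec()` is the extended-model
counterpart: $K^{trans} \in \{0,\dots,0.2\}$, $v_e \in \{0.1,0.2,0.5\}$,
$v_p \in \{0.001,\dots,0.1\}$ — 108 combinations (60×180 tissue region), a
60×20 strip, flip angle 25°, 3.5 minutes, injection at 5 s, and a lower
equilibrium amplitude (250 vs 1000) echoing the stronger discretisation of
that set.

Synthesis runs through the package's own forward chain — kinetic model →
relaxation calibration → sequence equation — per patch; the strip carries
$(1-\mathrm{Hct})\,C_p$ with the blood $T_{10}$. Noise is i.i.d. Gaussian
with per-pixel sigma equal to a fraction of that pixel's baseline, always
seeded.

What the phantom deliberately does **not** emulate: the original object's
physiologic simulator and its exact AIF (not printed anywhere we can read
them from), bulk-magnetic-susceptibility shifts, $T_2^*$/echo-time effects,
partial volume, motion, or Rician magnitude noise. The AIF used for
synthesis is the configurable Weinmann/Tofts population bi-exponential
($D$ = 0.2 mmol/kg, $a$ = 3.99, 4.78 kg/L, $m$ = 0.144, 0.0111 min$^{-1}$ —
literature values), and the *same* AIF is used when refitting, so recovery
results validate the estimation machinery independent of AIF shape but say
nothing about AIF misspecification on real data. Passing phantom tests
demonstrates correctness of calibration, convolution and optimisation — not
robustness to the physiological confounds listed above. Integer rounding of
synthesised signals (the discretisation present in the original DICOM
objects) is available via the DICOM writer but off in the in-memory
phantom.

Grid orientation: patch columns sweep $K^{trans}$ along X, patch rows sweep
$v_e$ (and $v_e \times v_p$, $v_p$ fastest) along Y; the orientation is
recorded in the returned ground-truth planes.

# Numerical choices

* **Convolution quadrature.** The discrete convolution treats the sampled
  input as piecewise linear and integrates each interval against the
  exponential kernel in closed form (first-order hold), accumulated by an
  exact O(n) recursion. Plain trapezoidal quadrature was rejected: at the
  phantom's fastest washout ($k_{ep} = 35$ min$^{-1}$ with 0.5 s frames)
  its error reaches ~0.6%, while the first-order-hold scheme stays well
  below the 0.1% agreement with the analytic bolus solution that the
  validation suite demands. At $k_{ep} = 0$ it reduces exactly to the
  running trapezoid; below $k_{ep}\,\Delta t < 10^{-6}$ the weights switch
  to series expansions to avoid cancellation.
* **Removable singularities.** The bolus solutions and the Hoffmann model
  are singular at $m_i = k_{ep}$ and $k_{el} = k_{ep}$; when the rate gap is
  below $10^{-8}$ min$^{-1}$ the analytic limit branch
  ($a\,t\,e^{-k_{ep}t}$) is used. Continuity across the switch is tested.
* **Calibration domain violations.** Noise can push a signal outside the
  invertible range of the log/fraction expressions. Values are clamped to
  within $10^{-6}$ of the valid range and the curve is flagged
  (`invalid`), propagating to the map, rather than emitting `NaN`
  mid-pipeline. Small *negative* concentrations from baseline noise are
  legitimate and kept unflagged so they average out in the fit.
* **Units.** Interfaces take TR/T1/T10 in ms, times in seconds, rates in
  min$^{-1}$; conversions happen once, internally. Model time is "minutes
  since injection"; the injection instant maps to
  `injection_frame * frame_interval` on the acquisition clock.

# Validation problem sizes

The test and acceptance suites fit patch-mean curves (30 and 108 patches at
the 10×10 patch resolution) for the full-grid recovery checks, which makes
the recovery experiments exact to quadrature precision and fast. The
noisy-bias property (σ = 20% of baseline) is evaluated at the 2×2 coarse
resolution of the validation protocol (equivalent σ = 10%) on a fixed
random subset of cells per patch: at the finest per-pixel resolution the
smallest $K^{trans}$ patches (0.01 min$^{-1}$) enhance at the level of the
noise floor and the non-negativity bound induces the well-known positive
median bias there, which is expected behaviour, not an estimator defect.
The noise-equivalence law uses ~10^5 independent draws per bin factor.

# Known limitations

* Single-slice ROIs only (matching the intended preclinical workflow).
* The DICOM support is a deliberate minimal subset: explicit-VR
  little-endian, single-frame 16-bit files with standard geometry/temporal
  tags; real-valued data round-trips only to 16-bit quantisation
  (integer-valued data in [0, 65535] is lossless). Vendor dialects,
  sequences, and compressed transfer syntaxes are rejected explicitly.
* Patlak, deconvolution and Bayesian estimators are out of scope, as are
  multi-compartment models beyond the open two-compartment scheme.
* The "±" uncertainties are asymptotic 1-sigma standard errors, not
  confidence intervals; for strongly nonlinear regimes (tiny enhancement)
  they understate the true uncertainty.
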