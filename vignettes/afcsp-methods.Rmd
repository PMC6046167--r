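---
title: "Decoding single-joint motor imagery with AF-CSP, twin SVMs and NSGA-II"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-joint motor imagery with AF-CSP, twin SVMs and NSGA-II}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcsp)
```

## The decoding problem and the signal model

Motor imagery modulates the power of the mu (8–13 Hz) and beta (13–30 Hz)
rhythms over sensorimotor cortex: imagining a movement desynchronizes the
rhythm (ERD, a band-power decrease) on movement-specific channels. For
*different joints* the spatial patterns differ strongly; for different
movements of the *same* joint (here shoulder flexion, extension, abduction)
they are subtle, which is what makes the three-class problem hard.

The pipeline assumes:

* the class information lives in mu/beta band power on a small set of
  frontal–central channels (FC5, F3, F4, FC6 of a 14-channel 10-20
  montage at 128 Hz);
* the modulation is stable over the analysis window (1–4 s post cue), so
  whole-segment spectra are sufficient statistics — no within-trial
  dynamics are modeled;
* trials are independent and class-balanced (20 per class per session).

## Stage by stage

### Preprocessing

A second-order IIR notch at 50 Hz (Q = 30) removes line interference. The
design is pre-warped (tangent bandwidth) because 50 Hz sits close to the
64 Hz Nyquist frequency, where the common small-angle biquad approximation
misplaces the band edges; the filter runs forward–backward with
odd-reflection padding and steady-state initial conditions, so it is
zero-phase and its edge transients are suppressed. Q = 30 keeps the
stopband to ±~0.8 Hz: wide enough to kill the line, narrow enough not to
erode the upper beta band.

Common average referencing subtracts the instantaneous mean across the four
selected channels. The method's printed formula averages the four selected
electrodes while the accompanying prose says "all the electrodes"; the
formula is the only unambiguous statement, so four-channel CAR is the
default and `car_scope = "all"` exposes the full-montage variant.
Processing order is notch first, then CAR.

### EMD and the amplitude–frequency matrix

Empirical mode decomposition sifts each channel into intrinsic mode
functions. Numerical choices, all exposed as arguments:

* envelopes are cubic splines through the extrema with **two extrema
  mirrored past each boundary**, which suppresses end swings on the short
  384-sample windows;
* sifting stops per IMF when the Cauchy criterion
  `sum((h_prev − h)²)/sum(h_prev²) < 0.2` fires, with a 10-sift cap;
* decomposition stops when the residual has fewer than three extrema
  (or too few of either kind to build an envelope).

The identity `sum(IMFs) + residual = input` holds exactly by construction
and is asserted in the tests. On band-limited signals of this kind, IMF1
captures the beta range and IMF2 the mu range, so the 8 × M trial matrix
stacks the one-sided FFT amplitude spectra (rectangular window, `2/N`
scaling, so a unit sinusoid on a bin center reads 1) of IMF1 and IMF2 of
the four channels, restricted to the closed 8–30 Hz interval. At the
default 1–4 s window this gives M = 67 bins at 1/3 Hz spacing. M is frozen
from the first trial processed; a later mismatch is an error, which
guarantees a rectangular feature tensor. Whether the original study used a
contiguous 8–30 Hz interval or concatenated mu/beta sub-bands is not
stated; the contiguous interval is used here.

### Pairwise CSP on AF matrices

Per-trial covariances are trace-normalized (`R = XXᵀ/tr(XXᵀ)`) and averaged
per class — the standard CSP convention; the averaging step is a design
choice since only the per-trial form is printed. A relative ridge
(`1e-8 · tr/N`, split evenly between the two class covariances so the
complementarity identity stays exact) guards against rank deficiency.
Whitening the composite covariance and eigendecomposing the whitened
left-class covariance gives the filter matrix `W` whose rows solve the
generalized eigenproblem `R_l w = λ (R_l + R_r) w`; rows are ordered by
descending λ and sign-canonicalized (largest-magnitude entry positive),
since eigenvector signs are arbitrary. With m = 2, rows {1, 2, 7, 8} are
retained and the log-normalized variances form a 4-D feature whose
exponentials sum to one.

Filters are fit **per cross-validation fold on training trials only**. The
source method does not state this, but anything else leaks test labels into
the features. Equal class covariances produce the documented `degenerate`
flag (all eigenvalues 0.5, no discriminative direction).

### One-vs-one twin SVM

Each class pair gets two nonparallel hyperplanes. Plane 1 minimizes
`½‖A_i w + e b‖² + c1 eᵀξ` subject to the other class lying at unit margin
with slack ξ; plane 2 is symmetric with penalty c2. The duals are
box-constrained QPs solved with `kernlab::ipop`, with a `1e-7 · trace`
ridge on the Gram inverse (the kernel equations as printed contain evident
typos — repeated class matrices, equalities where inequalities belong — so
the standard kernel twin SVM is implemented: surfaces `K(x, Cᵀ)w + b = 0`
with `C` stacking both classes). The interior-point solver needs a
non-degenerate constraint system, so the vacuous inequality
`0 ≤ Σα ≤ n·c` (implied by the box) replaces an all-zero equality row.

The RBF kernel is parameterized as `exp(−‖u−v‖²/(2λ²))` with λ the width
searched over `[2⁻²⁰, 2³]`; the source never writes the kernel formula, so
this convention is fixed here and tested (small λ approaches the identity
kernel on distinct points).

Voting: each sub-classifier votes for the class with the nearer hyperplane
(perpendicular distance `|w·φ(x)+b|/‖w‖` in the kernel feature space; a
within-pair distance tie votes for the pair's first class). A three-way
(1,1,1) tie is broken by the smallest sum of distances to the candidate's
own planes across its two pairs, then by lowest class index. Penalties are
shared across the three sub-classifiers (`c11=c21=c31`, `c12=c22=c32`),
which reduces the search space to two penalty genes.

### NSGA-II over (c1, c2, λ)

The three maximized objectives are the **per-class** pooled 5-fold
cross-validated correct rates; the pooled total rate CR is tracked for
model selection but does not enter dominance, so the front keeps solutions
that trade classes off against each other. Specifics:

* genome in log₂ space: c1, c2 over [−3, 3], λ over [−20, 3]. λ's bounds
  span 23 octaves; linear encoding would make most of the range invisible
  to the variation operators;
* simulated binary crossover and polynomial mutation with distribution
  indices 20 (the operator names are prescribed, the indices are not;
  these are the customary defaults), crossover rate 0.9, per-gene mutation
  rate 0.1, population 100 by default;
* offspring genes are clipped to the bounds;
* folds are stratified and **fixed for the whole run**, so objective
  differences between individuals reflect parameters, not fold noise;
* elitist (μ+λ) survival by non-dominated rank then crowding distance,
  plus a best-CR archive that can never lose the best individual
  evaluated;
* per-class rates are pooled across folds (sum of corrects over sum of
  totals), the form the count-ratio definitions imply, not averaged per
  fold.

The reported model is the front member with maximal CR, ties broken by the
larger minimum per-class rate, then lowest index. One published Pareto set
contains a penalty below the published lower bound (0.01 < 2⁻³); the bounds
are enforced here and the discrepancy is simply noted.

### Evaluation

`confusion_and_rates()` implements the count-ratio definitions
(CRF/CRE/CRA/CR, in percent); `cohen_kappa()` computes
`(P_o − P_e)/(1 − P_e)` from any count or percentage matrix; and
`aggregate_subjects()` reports mean ± **population** SD (divisor *n*): the
subjects summarized are the entire group under study, and only this
convention reproduces the published group spreads from the published
per-subject values (the sample SD does not).

## What the synthetic generator emulates — and what it does not

Each channel is 1/f-power background noise (spectrally shaped white noise)
plus a 50 Hz line tone plus amplitude-modulated mu (carrier 10.5 ± 0.5 Hz,
10 µV) and beta (21 ± 0.5 Hz, 6 µV) oscillations. ERD is a multiplicative
amplitude attenuation (default depth 0.5) applied over the whole trial on a
class-specific channel subset: flexion attenuates FC5+F3, extension
F4+FC6, abduction FC5+FC6 — three spatially distinct, pairwise-separable
patterns confined to the four analysis channels. Oscillator and modulation
frequencies are snapped to the trial-length FFT grid so that, with noise
switched off, the spectrum is exactly band-limited (this makes the spectral
contract testable at a 1% leakage threshold). Amplitudes (10/6/8/15 µV for
mu/beta/background-RMS/line) were chosen once as plausible scalp-EEG
magnitudes.

Deliberately **not** modeled: forward-projected scalp topographies and
channel correlations, eye-blink/EMG artifacts, within-trial ERD latency,
inter-trial nonstationarity, and subject-specific SNR (the source does not
characterize its subjects' SNR, so the depth is a calibration choice, not a
reproduced fact). Consequently, passing the end-to-end tests shows the
pipeline recovers class structure of the assumed kind at realistic SNR — it
does not certify performance on real recordings, whose headline accuracies
depend on data that are not deposited.

## Problem sizes and reproducibility

The test suite and examples run the study-scale dataset (60 trials,
20 per class, 5-fold stratified CV) and a scaled search (population 20,
10 generations ≈ 220 evaluations; the optimizer-vs-random check uses a
200-evaluation budget each) — large enough to exercise every code path and
demonstrate recovery far above the 33.3% chance level, small enough to run
in minutes on one core. Defaults in `ga_config()` remain at the published
presets (population 100, 200 generations). All randomness flows through
explicit seeds: the simulator and fold assignment restore the caller's RNG
state, and the CLI fans a single global seed out to named sub-streams
(`simulate`, `folds`, `ga`) so stages can be re-run independently.

## Known limitations

* EMD is the classical sifting algorithm; mode mixing on noisy data is
  possible (ensemble variants are out of scope), though the AF matrix only
  needs IMF1/IMF2 to capture 8–30 Hz energy, which is asserted (≥ 80%) on
  simulated trials.
* The interior-point QP solver can report non-convergence on pathological
  Gram matrices; this surfaces as a labeled error naming the fold rather
  than a silent fallback.
* `evaluate_genes()` refits three twin SVMs per fold per individual;
  feature extraction is hoisted out of the search (CSP does not depend on
  the classifier's hyperparameters), which is what makes the search cheap,
  but a different CSP `m` requires rebuilding the fold features.
* EDF import is not provided; the documented long-format CSV is the
  interchange format.
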