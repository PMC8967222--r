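---
title: "Models and methods behind tidysmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tidysmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidysmt)
```

tidysmt analyses live-cell single-molecule tracking (SMT) of nuclear
proteins — transcription factors such as the glucocorticoid receptor
imaged by HILO microscopy with a HaloTag dye — and answers two questions:
how is the population divided among chromatin-bound, confined and freely
diffusing molecules, and how long do bound molecules stay on chromatin
once photobleaching is accounted for. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic
benchmarks do and do not establish.

## The dual-acquisition design

Two acquisition protocols are built in, reflecting common practice:

* **fast** — 12 ms frame interval, 10 ms exposure, 800 frames. Continuous
  acquisition used for diffusive-state classification, where short
  exposures minimize motion blur. (Hardware frame rates near 83 Hz
  correspond to this continuous 12 ms interval; some instruments report
  the exposure as 10 ms and the readout-limited interval as 12 ms — both
  numbers appear in the literature for the same mode, so the preset keeps
  the pair Δt = 12 ms, t~E~ = 10 ms and both are overridable.)
* **slow** — 200 ms frame interval, 10 ms exposure, 800 frames.
  Time-lapse acquisition that blurs out diffusing molecules and isolates
  the slow, bound population for residence-time analysis.

The pixel size defaults to 0.107 µm (typical of a 150× objective on an
EM-CCD); it is a parameter of every protocol and never hard-coded in any
formula.

## The trajectory generator

`simulate_tracks()` produces 2D trajectories under the same assumptions
the estimators make, plus ground truth, so every stage of the analysis is
testable without microscope data:

* **Motion.** Each molecule carries one of K motion states: free
  (Brownian, diffusivity D), bound (Brownian with small D), or confined
  (Brownian reflected at a disk of radius L centered on the position
  where the state was entered). A hard reflecting disk is chosen because
  it has a testable MSD plateau: the stationary uniform distribution on a
  disk gives an asymptotic MSD of exactly L², so the plateau must sit at
  or below L².
* **Switching.** States are left at exponential times (rate 1/mean
  dwell) with a uniform choice of destination, so the stationary
  occupancy is proportional to the mean dwells — another closed-form
  check.
* **Motion blur.** The true path is integrated with 10 sub-steps per
  exposure window (and dead-time steps no longer than the exposure); the
  observed position is the average of the sub-step positions inside the
  exposure. For this scheme the lag-1 per-axis displacement variance is
  exactly 2D(Δt − t~E~/3 + t~E~/(3m²)) + 2σ², i.e. the standard
  continuous-blur expression up to a relative error of order 1/m² ≈ 1%
  of the blur term at m = 10 — far below the sampling noise of any
  benchmark used here. The default of 10 sub-steps is therefore an
  accuracy/speed compromise validated against the closed form.
* **Noise and bleaching.** Isotropic Gaussian localization noise of s.d.
  σ per axis (default 0.03 µm) is added per frame; each molecule
  photobleaches after an exponential lifetime with hazard k~b~, and a
  frame is recorded only if the molecule survives the whole exposure.
  Tracks need at least two recorded frames, matching the tracking rule.
* **Determinism.** All randomness flows from one integer seed through
  named substreams (simulation, fitting, rendering draw from independent
  streams), so identical inputs give byte-identical outputs.

A separate generator, `simulate_residence_tracks()`, produces bound
molecules whose visible lifetime is min(residence, bleach lifetime,
movie span), with power-law, exponential, or unbounded ("stable", an
H2B-like control) residence laws. `simulate_control_dwells()` draws
control dwell samples directly from a ≤3-exponential bleaching survival,
quantized to the frame grid with the midpoint convention, which keeps the
sample mean unbiased. `render_frames()` rasterizes tracks into
Poisson-noise image stacks for end-to-end detection tests.

## Detection and linking

`detect_spots()` applies a PSF-matched Gaussian filter, thresholds local
maxima at `threshold_sd` robust noise standard deviations above the frame
median, and refines positions by least-squares Gaussian fitting; nearby
candidates merge, keeping the brighter. `link_tracks()` connects
consecutive frames by an optimal bipartite assignment (Hungarian
algorithm with birth/death dummies priced at the squared gate) that
minimizes total squared displacement among pairs closer than the gate —
4 pixels for 5 Hz movies, 6 pixels for 83 Hz movies — with no gap
closing, and discards tracks shorter than 2 frames. An optimal rather
than greedy assignment is this package's choice: published trackers often
leave the rule unstated, and the optimal matching is deterministic and
order-independent up to exact cost ties, which resolve by input row
order.

## Diffusive-state classification (pEM + BIC)

Whole trajectories are classified into K diffusive states by a
perturbation expectation-maximization over the stationary Gaussian model
of blurred SPT displacements. Under state k, each axis of a track's
displacement sequence has

* variance 2D~k~Δt + 2ε~k~²,
* covariance −ε~k~² between adjacent displacements, zero beyond lag 1,

with effective noise ε~k~² = σ² − D~k~t~E~/3. One **static localization
variance σ² is shared across states** (one camera, one noise floor); the
per-state blur term −D~k~t~E~/3 follows from it. This is deliberate:
with exposures comparable to the frame interval (10 of 12 ms in the fast
preset), a single state-independent effective noise cannot represent a
slow and a fast state simultaneously and biases the slow state's
diffusivity severely, whereas the σ²-parametrization keeps the covariance
positive definite for any D ≥ 0, σ² ≥ 0, t~E~ ≤ Δt and leaves the
parameter count at p = 2K (K−1 weights, K diffusivities, σ²). ε~k~² may
legitimately be negative when blur exceeds static noise; σ² itself is
floored at zero with a warning flag.

The E-step evaluates the tridiagonal Gaussian likelihood per track and
state in O(n) via an LDLᵀ recursion (checked against a dense
multivariate-normal evaluation to 1e-10 relative). The M-step updates
weights from posterior sums and re-estimates each D~k~ from the
posterior-weighted lag-0/lag-1 covariances via D~k~ = (Var + 2Cov)/(2Δt)
— the combination that cancels both blur and noise bias — and σ² from
the pooled lag-1 covariances. Because moment updates do not formally
guarantee likelihood ascent, a backtracking safeguard halves the step
towards the previous parameters whenever the proposed update would lower
the log-likelihood, and stops when no improving step exists; the recorded
likelihood trace is therefore non-decreasing within every run, and in
practice the full moment step is accepted essentially always.

Local maxima are escaped the pEM way: after convergence the
diffusivities are multiplied by log-normal factors (s.d. 0.3 in log
space) and EM re-runs, keeping the best likelihood over
`n_perturbations` trials and `n_restarts` quantile-based
initializations. Convergence is declared at a relative log-likelihood
change below 1e-7 or 500 iterations.

`select_model()` fits a range of K and minimizes BIC = −2 ln L +
p ln n, with n the total number of 2D displacements — displacements are
the likelihood's observation unit, which is why they, and not tracks or
positions, enter the penalty. K values whose states collapse (no
supporting tracks) are recorded as errors and skipped.

`filter_states()` implements the population rule used for SMT state
models: a state's population is the fraction of tracks with posterior
above 0.6, and states below 5% population are discarded, the surviving
weights renormalized and posteriors recomputed under the reduced model.
Whether discarded tracks should instead trigger a refit is genuinely
open; renormalization is the default and `refit = TRUE` is available.

`state_msd()` computes the posterior-weighted time-averaged MSD per
state and `summarize_fractions()` labels states by mobility: states with
D ≤ `bound_D_max` (default 0.03 µm²/s, the order of the apparent
mobility floor that localization noise imposes on truly bound molecules;
always reported alongside the result) form the bound class, the slowest
of which is chromatin-bound and the rest confined; everything faster is
free.

## Residence times with photobleaching correction

The slow channel measures how long bound molecules stay put:

* **Bound criterion.** A molecule counts as bound while every
  frame-to-frame displacement stays within `bound_radius_um` (default
  0.2 µm, of the order of the slow-channel tracking gate in micrometers);
  maximal bound stretches of ≥ 2 frames become dwells of
  (frames − 1)·Δt. The criterion is a package default — declared, swept
  in tests, and not claimed to be anyone else's operational definition.
* **Pooling.** Dwells are pooled across cells as the weighted ensemble
  survival Σ~c~ w~c~S~c~(t) with w~c~ proportional to the number of
  contributing tracks per cell; equivalently, per-dwell repetition
  weights.
* **Bleach model.** A stable H2B-like control imaged identically is
  fitted with a mixture of up to three exponentials by least squares on
  the log survival, with A~i~ ≥ 0, ΣA~i~ = 1, τ~i~ > 0 enforced by
  softmax/log reparametrization, 10 seeded multi-starts,
  inverse-variance weights (Var log Ŝ ≈ (1 − S)/(NS), so the sparse far
  tail does not dominate), and a free overall scale that absorbs the
  left-truncation of unobservably short control dwells. The reported,
  renormalized mixture satisfies S(0) = 1 exactly; the correction is
  invariant to the scale.
* **Correction.** S~corr~(t) = S~obs~(t)/S~b~(t), renormalized to 1 at
  the smallest observed dwell and projected onto non-increasing step
  functions (cumulative minimum) so sampling noise cannot produce an
  invalid survival. Division uses the full fitted mixture; dividing by a
  single chosen component is available (`component =`) because the
  phrasing "the exponential component" is ambiguous in parts of the
  literature.
* **Power-law tail.** The corrected distribution's tail t ≥ t~min~
  (default 3 frames = 0.6 s at the slow protocol) is fitted by the
  continuous maximum-likelihood estimator α̂ = 1 + n/Σln(t~i~/t~min~)
  with masses as repetition weights — tail MLE rather than log-log
  regression, which is biased. For frame-quantized dwells a half-frame
  continuity offset is added inside the logarithms (midpoint
  correction): the measured dwell of a stretch of k frames is (k−1)Δt,
  whose survival is that of the true dwell shifted by about half a
  frame, and ignoring this inflates α̂ by ~0.1–0.2 at the default
  t~min~. The offset engages automatically when the distribution carries
  a protocol and is zero otherwise (preserving exact scale invariance
  for continuous data).
* **Comparison.** `compare_dwell()` computes the two-sample
  Kolmogorov–Smirnov statistic on the (weighted) empirical distributions
  with the asymptotic p-value; "paired" KS tests reported in the SMT
  literature are, operationally, this two-sample statistic.

## Problem sizes and what the benchmarks show

The test suite runs entirely on synthetic data at desk scale: the
canonical two-state benchmark uses 2,000 tracks of 20 displacements at
the fast protocol (D = 0.02 and 0.5 µm²/s, weights 0.3/0.7, σ = 0.03
µm), 20 seeded replicates for model selection and parameter recovery;
the residence benchmark uses 3,000 bound molecules with α = 2 power-law
residence through the triple-exponential bleach (0.5/0.3/0.2 at
0.5/2/10 s), 10 seeds; linking uses ≤ 0.02 spots/µm². Model selection
identifies the true K in ≥ 18/20 replicates, diffusivities are recovered
within 5% (median), weights within 0.03, track assignment above 95%, and
the corrected tail exponent within ±0.15 of truth. These sizes are the
package's chosen benchmark conditions, and the published headline
fractions for GR (bound and confined fractions falling after cohesin
loss) are statements about live-cell data — the synthetic benchmarks
validate the estimators, not the biology.

What the generator does **not** emulate: drift, defocus loss (axial
escape is absorbed into the bleaching hazard rather than modeled
separately), astigmatic/3D PSFs, blinking and gap closing,
within-track state inference (vbSPT-style HMMs), anomalous-diffusion
exponents, and detector artifacts beyond Poisson shot noise. Passing
tests therefore show correctness of the estimators under the stated
model, not robustness to every property of real movies.

## Degenerate inputs and edge rules

All-zero displacement data fits to D = 0, σ² = 0 with a finite
(variance-floored) likelihood; a state with no supporting tracks raises
a collapse diagnostic naming the state; filtering refuses to remove all
states; dwell distributions refuse re-correction and correction through
a bleach survival below 1e-6; power-law fits refuse tails under 50
dwells or with zero log-spread; linking rejects duplicate (frame,
position) rows naming the frame; track tables reject frame gaps, missing
columns and non-finite coordinates with distinct messages.
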