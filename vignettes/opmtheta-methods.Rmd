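---
title: "Localising deep theta power changes with a wearable OPM array: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising deep theta power changes with a wearable OPM array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmtheta)
```

## The problem

Optically-pumped magnetometers (OPMs) are cryogen-free magnetic field
sensors that can be worn on the scalp, an order of magnitude closer to the
brain than sensors in a conventional cryogenic MEG helmet. Because they are
magnetometers rather than gradiometers, they are acutely sensitive to
environmental magnetic interference, and the central methodological
question for deep-source work is whether a small scalp array (a few tens of
channels), after software interference suppression, retains enough
sensitivity to localise activity in structures as deep as the hippocampus.

`opmtheta` implements an end-to-end, fully synthetic test bed for this
question. It simulates a two-condition cognitive experiment — a "scene
imagery" condition in which a hippocampal-depth theta (4–8 Hz) source
*decreases* in power relative to a "counting" baseline — records it with a
virtual OPM array plus a reference array, and then analyses the recording
with the standard source-localisation chain: trial-wise reference
regression (synthetic gradiometry), a scalar linearly-constrained
minimum-variance (LCMV) beamformer, voxelwise two-condition power
statistics, a multi-participant maximum-p conjunction with
false-discovery-rate (FDR) control, and a bootstrap stability map of the
significant clusters. Because the generator plants a known source, every
stage of the chain can be tested for parameter recovery.

## Forward model

The head is a homogeneous conducting sphere. For a current dipole inside a
sphere the external magnetic field has an exact closed form; the package
evaluates it directly (`dipole_field_sphere()`). Two consequences shape the
whole design:

* **Radial silence.** A dipole oriented along the sphere radius produces no
  external field, as does any dipole at the centre. Candidate source
  orientations are therefore restricted to a two-dimensional tangential
  basis at each grid point (`tangential_basis()`), which keeps the
  beamformer's orientation optimisation well posed.
* **Exactness.** The sphere model is *exact* for the geometry the generator
  simulates, so forward-model error is eliminated as a confound; the
  pipeline itself (not mesh quality) is what is under test. The analysis
  chain is forward-model agnostic, so a mesh-based model could be swapped
  in for real-data use.

Sensors are single-axis magnetometers with radial sensitive axes, placed at
a 6.5 mm standoff (typical OPM vapour-cell-to-scalp distance) on a
Fibonacci lattice over the scalp, excluding the inferior cap below
−0.4 · radius (the coverage a scanner-cast leaves free). A four-sensor
reference array sits ~10 cm behind the head: three orthogonal sensitive
axes plus one repeated axis at a small spatial offset, so that both the
uniform field and the gradient component of the interference are
identifiable from the reference signals alone.

## The synthetic study

The generator's defaults define one fixed virtual study, chosen once from
physical and physiological considerations:

| quantity | default | rationale |
|---|---|---|
| sample rate | 1200 Hz | standard OPM acquisition rate |
| epoch length | 3 s | task-period length of the emulated paradigm |
| head radius | 0.075 m | typical adult head sphere |
| scalp channels | 21 | small wearable array |
| source depth | 0.45 · radius | hippocampal depth, right-lateral-anterior |
| counting moment SD | 20 nAm | effective deep-source moment; projected source power a few times the beamformer noise floor, so F statistics fall in the tens — the scale reported for real hippocampal theta contrasts |
| scene/counting amplitude ratio | 0.7 | ~2× power decrease during scenes |
| sensor noise | 367 fT/sample | 15 fT/√Hz over the 600 Hz bandwidth |
| uniform interference | 200 pT per component | residual field after active nulling |
| gradient interference | 0.1 nT/m | residual gradient: the nulling coils cancel measured gradients, so only a small residual remains |
| interference corner | 3 Hz | environmental drift concentrates below a few hertz |
| geometry jitter | 2 mm SD | co-registration error across participants |
| participants | 3 | multi-participant conjunction design |

Trial numbers per participant reproduce a realistic accounting: completed
trials per condition (45, 75, 48 for participants one to three), of which
only self-rated-successful, artefact-free trials are usable, and trial
numbers are then *equivocated* — the larger condition is subsampled
(seeded, uniformly) to the smaller usable count — giving 35, 61 and 45
analysed trials per condition. The subsampling rule is the package's own
choice; how the original counts were equated is not otherwise specified.

A `moment_scale` multiplier (3 in the "high-SNR" variant used by the
localisation-accuracy checks) scales the source without touching noise or
interference.

**The interference model** is a time-varying uniform field (three
independent low-pass Gaussian processes) plus a single low-pass gradient
process multiplying a fixed, randomly drawn, symmetric traceless tensor
pattern. This gives exactly four temporal degrees of freedom — the number a
four-channel reference array can identify — so with noiseless references
the trial-wise regression removes scalp interference *exactly*. A fuller
model (five independent gradient tensor components, eight degrees of
freedom total) would leave an irreducible residual after regression on four
reference channels; the package deliberately matches the interference
complexity to the reference array, because the property under test is the
regression chain, not reference-array sufficiency. This is a known
limitation relative to real environments, where synthetic gradiometry is
only approximate.

**What the generator does not emulate:** head movement, cardiac/ocular
artefacts, sensor gain drift and cross-talk, the hardware anti-aliasing
chain (the ±1.5 nT dynamic range is recorded and checkable via
`check_dynamic_range()`, but clipping is not applied), non-spherical
anatomy, and multiple simultaneous sources. Passing the package's tests
therefore demonstrates correctness of the analysis chain under its own
assumptions, not performance on real recordings.

## Preprocessing

1. **Baseline correction** subtracts each trial-channel's whole-epoch mean.
   No baseline window is singled out because any constant is annihilated by
   the band-pass anyway; this is pure DC removal.
2. **Synthetic gradiometry** regresses, per trial, each scalp channel on an
   intercept plus all reference channels (ordinary least squares) and keeps
   the residual. Trial-wise estimation tracks temporal non-stationarity of
   the interference. The design matrix uses the recorded reference channels
   as-is rather than a reconstructed field model. An intercept is included
   because magnetometer offsets are large and a constant regressor is
   harmless. Rank-deficient reference matrices (collinear references) fall
   back to the minimum-norm solution with a warning. The regression is a
   projection: it is idempotent and can only reduce per-trial variance.
3. **Band-pass** to 4–8 Hz with a 5th-order Butterworth applied forward and
   backward (zero phase; the magnitude response is squared).

### Numerical notes on the filter

At 4–8 Hz and 1200 Hz sampling the classical expanded-polynomial form of a
10-pole Butterworth is numerically unstable in double precision (filtered
white noise diverges to ~1e15). The design is therefore kept in
second-order sections: analytic prototype poles → analog band-pass
transform → bilinear transform, verified against the closed-form
frequency-warped Butterworth magnitude response. Edge handling uses
odd-symmetric padding with step-matched initial conditions per section; the
default pad length is six cycles of the slowest corner frequency, because
the impulse response of so narrow a band rings for roughly a second and
shorter pads leave visible edge transients.

## Beamformer

The scalar LCMV beamformer follows the standard unit-gain construction.
The data covariance `C` is pooled over *all* trials of *both* conditions
(one covariance window covering the whole 0–3 s epoch), estimated as the
mean of per-trial covariances with per-trial means removed, and regularised
by diagonal loading `C + λ·mean(diag(C))·I` with λ = 0.05 by default (the
reference implementations leave their value unstated; it is exposed in the
configuration). Per voxel:

* **Orientation.** For tangential lead-field pair `L` (sensors × 2), the
  unit-gain output power along orientation `u` is `1 / (u' L' C⁻¹ L u)`;
  the maximum-power orientation is the eigenvector of `A = L' C⁻¹ L` with
  the smallest eigenvalue — solved in closed form for the 2 × 2 case across
  all voxels at once, and verified against an exhaustive angle search.
* **Weights.** `w = C⁻¹l / (l' C⁻¹ l)` with `l = L u`; unit gain `w'l = 1`.
* **Trial power.** The variance of the projected trace per trial, computed
  as the quadratic form `w' C_t w` in the per-trial covariance — this
  identity is what makes the bootstrap cheap, since resampling trials only
  reindexes precomputed `C_t`.

**Statistics.** Trial band powers are log-transformed (power is
right-skewed; the two-sample machinery assumes approximate normality) and
compared between conditions with the pooled-variance two-sample t statistic
(scene − counting; negative = theta decrease) and the equivalent two-group
ANOVA F = t², df (1, n₁+n₂−2). Voxels with zero within-group variance get
an infinite-F sentinel and are flagged. Because the log transform makes the
contrast scale-free, voxels dominated by *leakage* of a strong source show
the same expected contrast as the source itself; significant regions are
therefore spatially extended around a strong source, and the peak — not the
mask extent — carries the localisation information.

## Group inference

Per participant, the F map is smoothed with a 9 mm FWHM Gaussian
(separable point-sampled kernel, renormalised over the in-mask support so a
constant map is unchanged at boundaries; smoothing precedes the p
conversion), converted to upper-tail p values at that participant's df, and
the three participants are combined voxelwise by the **maximum-p
conjunction** — a valid, conservative test of the null that *no*
participant shows an effect. The conjunction map is thresholded by
**Benjamini–Hochberg** step-up FDR at q = 0.005 over all in-mask voxels
(BH rather than Benjamini–Yekutieli, matching common voxelwise practice).
Significant voxels are decomposed into 6-connected (face-adjacent)
clusters; each cluster reports its peak (maximum of the voxelwise *minimum*
smoothed F across participants, the statistic matching the max-p rule),
with peak ties broken to the lowest linear voxel index.

Spatial normalisation across participants is the identity: the synthetic
participants share one grid, and the 2 mm geometry jitter plays the role of
registration error.

The default analysis grid is a 24³ × 3 mm region of interest centred on
the head centre — it covers the deep brain, including the planted source
with margin, at the full 3 mm resolution while keeping every map small
enough for dense resampling analyses; whole-head grids are available by
passing a larger `grid_dim`.

## Bootstrap stability

Per participant, usable trials are resampled with replacement —
independently within each condition, preserving the per-condition counts
(the alternative, joint resampling, is not what "resampled their usable
trials" most naturally reads as, and independent resampling keeps the
design balanced) — and the beamformer image is recomputed; 100 replicates
per participant by default. Then, repeatedly (500 by default), one image
per participant is drawn uniformly and the *entire* group analysis
(smooth → p → conjunction → FDR, with the FDR threshold re-estimated within
each conjunction) is rerun; each voxel's significance is coded 0/1, the
codes are summed and expressed as a percentage of the number of
conjunctions. The result is a stability map in [0, 100] that is exactly
100 × the mean of the binary masks.

On saturated maps (many voxels at 100%), `map_peak()` reports the plateau
voxel nearest the plateau centroid — a deterministic convention independent
of voxel ordering; the first-index convention would report an arbitrary
plateau corner.

## Reproducibility and problem sizes

Every stochastic stage (simulation, trial equivocation, bootstrap
resampling, conjunction draws) takes an explicit seed, and sub-streams are
derived with a deterministic hash so stages never perturb one another;
identical configurations and seeds give bit-identical sessions and maps.
Run configurations serialise losslessly to JSON (YAML emitters round
doubles, which breaks bit-reproducibility of reread configurations).

The package's own test and verification runs use the default study at full
temporal resolution (1200 Hz × 3 s × 35–61 trials per condition per
participant) on the 24³ deep-brain grid; end-to-end recovery checks use 20
independently seeded studies, and the bootstrap stability check uses 25
replicates per participant and 100 conjunctions per study. These sizes
keep a complete verification cycle to minutes on a single core while
leaving every scientific default at its stated value.

## Known limitations

* The conducting-sphere model is exact only for the simulated world; real
  heads need a boundary-element or corrected-sphere forward model.
* Interference is matched to the reference array's four degrees of freedom
  (see above); real interference is richer and reference regression
  correspondingly less complete.
* The unit-gain LCMV power contrast does not normalise source leakage, so
  significance masks around a strong deep source are broad by construction;
  localisation claims should rest on peaks and stability maps, not mask
  extent.
* Artefact handling is bookkeeping only (trial counts), not waveform
  modelling.
* No time-resolved (windowed) beamforming, no noise-normalised variants,
  no random-effects group model: the implemented inference is the
  fixed-effect conjunction described above.
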