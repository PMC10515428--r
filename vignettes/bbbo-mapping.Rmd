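---
title: "Mapping blood-brain-barrier opening from delayed-contrast MRI"
author: "bbbomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping blood-brain-barrier opening from delayed-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An intact blood-brain barrier (BBB) excludes gadolinium contrast agents, so
a single post-contrast T1 scan shows nothing when the barrier is opened
only subtly — for example by low pulsed electric fields applied through the
intact skull. Delayed-contrast MRI (DCM) instead acquires repeated 3D T1
volumes for up to ~30 minutes after injection; where the barrier leaks,
contrast accumulates slowly and the voxel signal drifts upward over the
scan window. `bbbomap` turns such a 4D series into quantitative maps of
BBB opening (BBBo) and a voxel-count/volume summary per brain.

## Signal model

Each voxel's intensity curve is normalized to its first post-contrast time
point (the first normalized value is 1 by construction) and fitted to a
two-exponential function motivated by the Tofts two-compartment exchange
picture:

$$f(t) = x_1\, t\, e^{-t/x_2} + x_3\, e^{-t/x_4} + x_5$$

with time $t$ in minutes post injection. $x_1$ (1/min) scales a
slow-accumulation-then-washout term peaking at $t = x_2$; $x_3$
(dimensionless) and $x_4$ (min) describe a decaying component; $x_5$ is
the asymptotic offset. An alternative reading of the second term as a
saturating uptake, $x_3(1 - e^{-t/x_4})$, is available as
`modelVariant = "uptake"` in `kineticsControl()`; the two variants span
the same practical shapes and the washout form is the default.

Three derived parameters summarize each fitted curve, all computed from
the *fitted* curve on a dense grid of 1000 points over the scan window
(no extrapolation beyond the last frame):

* **Dyn** (%): the maximal fitted signal increase over the first time
  point — the intensity of the opening.
* **TT** (min): the time the fitted curve spends at or above a 5 %
  signal increase — the duration of the opening *within the scan window*,
  not of the entire BBBo episode.
* **AOT** (min x normalized units): the area between the fitted curve and
  the 5 % threshold — a composite of intensity, duration and curve shape,
  and the package's primary per-voxel BBBo level.

The 5 % threshold (`threshold = 0.05`) and the grid resolution
(`gridN = 1000`) are configurable. TT is the grid fraction above threshold
times the window length; AOT uses trapezoidal quadrature of the clamped
excess, so a curve sitting exactly at the threshold contributes zero.

## Fitting

The model is linear in $(x_1, x_3, x_5)$ once $(x_2, x_4)$ are fixed, so
the fit uses variable projection: a log-spaced grid of time-constant pairs
(5 x 5 by default) is screened with exact linear least-squares solves, and
up to ten of the best starts are polished sequentially with bounded
Levenberg-Marquardt (`minpack.lm::nls.lm`, analytic Jacobian), keeping the
lowest-SSE solution. Polishing stops early once a fit is essentially
perfect ($r^2 > 1 - 10^{-9}$), or — for clearly noisy curves only
(residual SSE above `1e-4` absolute and relative to SST) — once three or
more starts have plateaued, because two-exponential fits are multimodal
and near-noiseless curves often need a later start to reach the exact
basin while noisy voxels gain nothing from extra polishing. The
multistart is deterministic — no random restarts are needed, though
seeded extra restarts remain available (`extraRestarts`).

Two numerical guards matter:

* **Identifiability bounds.** Time constants are bounded to
  [mean inter-frame spacing, 2 x window length] by default. With ~4-minute
  frame spacing, components decaying faster than a frame interval are not
  determined by the data; left unbounded they let the fitted curve spike
  *between* sample points, which inflates the dense-grid Dyn of pure-noise
  voxels by orders of magnitude. The bounds are configurable
  (`tcLower`, `tcUpper`).
* **Degenerate curves.** $r^2 = 1 - SSE/SST$ with SST about the mean of
  the observed values. For an exactly constant curve SST is 0; the package
  then reports $r^2 = 1$ when the fit is exact and 0 otherwise (such
  voxels carry Dyn = 0 and are removed by the Dyn filter regardless).
  Voxels whose first-frame intensity is at or below a noise floor
  (`epsBaseline`, a fraction 1e-6 of the series maximum) cannot be
  normalized and are flagged unfittable rather than fitted.

## Classification

A voxel represents BBBo when $r^2 > 0.6$ and Dyn > 5 %, and it belongs to
a 3D connected component of at least 30 such voxels. The three filters are
applied in that fixed order for reproducible logs; the result is
order-independent. Components use 26-connectivity by default — the
standard choice for lesion masks and the least likely to split a curved
cortical sheet of enhancement; 6-connectivity is available. The minimal
cluster size is interpreted as a *voxel count* (30); at the acquisition's
zero-filled voxel size of 0.39 x 0.39 x 0.4 mm^3 that corresponds to
about 1.8 mm^3. BBBo volume is the voxel count times the voxel volume,
and the same rule gives tumor volumes from enhancing-ROI masks.

For tumor-bearing brains, `bbboOutsideTumor()` restricts classification to
brain-and-not-tumor and then re-applies the cluster-size filter: the
filter defines what counts as BBBo, so a cluster cut in half by the tumor
ROI must still reach 30 voxels outside it.

## Registration

`registerSeries()` rigidly (6-DOF) aligns every frame to the first
post-contrast scan, maximizing normalized correlation with trilinear
interpolation; a coarse integer-translation search supplies the capture
range before Nelder-Mead refinement. The stage is pluggable and off by
default in `dcmConfig()` because synthetic phantoms are aligned by
construction; it should be enabled for scanner data. A frame whose
refinement fails to improve on the identity passes through unaligned with
a warning rather than poisoning the series.

## Distributions

Over the BBBo voxels of a brain, histograms of Dyn, TT and AOT are built
with default bin widths of 2.5 %, 2.5 min and 0.2 AOT units (all
configurable; bins are left-closed and start at 0, so counts always sum to
the BBBo voxel count). Group-level histograms average per-subject counts
bin-wise with an SEM across subjects. The AOT histogram is fitted by least
squares to $A e^{-x/\tau}$ on raw counts through the last nonempty bin;
raw counts rather than log counts, because empty bins have no logarithm
and the log transform reweights the tail. `cumulativeFraction()` reports
the percentage of voxels below a threshold, and
`calibrateExponentialRate()` / `exponentialCdfPercent()` convert one
printed cumulative anchor of an exponential AOT distribution into
predictions at other thresholds.

## Pharmacology and efficacy

`ugPerGToNanomolar()` converts a tissue concentration by dimensional
analysis: ug/g x density (g/mL) gives ug/mL, dividing by the molecular
weight (g/mol) gives umol/L, i.e. nM after scaling. With the doxorubicin
defaults (d = 1.046 g/mL, MW = 579.98 g/mol), 0.3 ug/g converts to about
541 nM. `foldOverIC50()` rounds a concentration/IC50 ratio to an integer
fold. `fitIC50()` fits the variable-slope four-parameter logistic to mean
confluence per concentration in log10-concentration space — the standard
model behind confluence-based dose-response IC50s — and reports the IC50
with a delta-method standard error. Tumor growth rate is the follow-up
over baseline volume fold: volumes enter in mm^3 and rates near 1-3 over a
few days are dimensionless, which is the only definition consistent with
such magnitudes. Group comparisons use the pooled-variance (Student)
two-sample t-test.

## The synthetic phantom

`generatePhantom()` builds a study-condition phantom with analytic ground
truth: a 64^3 grid at 0.39 x 0.39 x 0.4 mm^3, eight frames between 1 and
30 min, an ellipsoidal brain (semi-axes 42 % of the grid), and spherical
enhancement clusters placed as far out radially as full containment
allows (capped at 85 % of the ellipsoid radius), echoing the cortical
localization of field-induced opening. Default cluster radii of 4-5.5
voxels give four clusters totaling roughly 1.9 thousand voxels, the scale
of the reported treated-group counts. Cluster kinetics are drawn by
rejection so the true Dyn lies in [6, 30] % with uptake and washout time
constants of 8-25 and 5-25 min, and the first-frame value is exactly 1.
Sham phantoms (`generateShamPhantom()`) carry only isolated enhancing
blobs of 1-5 voxels — every component is below the 30-voxel minimum, so
their true BBBo mask is empty.

**Noise model.** Noise is Gaussian on the *normalized* signal (default
sigma 0.02), and the baseline frame is the noiseless normalization
reference — the normalized curve's first value is 1 by construction, so
noise enters from the second frame on. This keeps the ground truth
analytic and the noise level interpretable as curve-level scatter. It is a
deliberate idealization: real data add baseline noise (which the division
couples into every later point), Rician rather than Gaussian statistics at
low SNR, motion, and spatially correlated reconstruction noise. Passing
phantom tests therefore demonstrates the correctness of the fitting,
filtering and bookkeeping machinery under the stated noise model, not
robustness to every artifact of scanner data. Registration is likewise
exercised on known rigid shifts of smooth volumes, not on real motion.

Truth maps are computed from the generating parameters with the same
dense-grid definitions the analysis uses, so noiseless generate-and-refit
agreement is a genuine round trip through the optimizer rather than a
shared-code tautology only at the map level; the independent oracles for
TT and AOT (root finding and fine-grid quadrature) close that loop.

The dose-response generator reproduces the in vitro design (six wells per
concentration, 4PL surface plus Gaussian confluence noise clipped to
[0, 100] %, a 3-fold dilution ladder spanning the transition), and the
efficacy-cohort generator draws growth-rate folds at the reported group
means with SDs implied by the reported SEMs at n = 5. Baseline volumes
use an SD of 1.5 mm^3 around the reported means — a spread that keeps
volumes positive without truncation distortion. At these study sizes the
pooled t-test separates the groups in roughly three quarters of seeded
replicates; detection is not guaranteed in any single cohort of five.

## Problem sizes and runtime choices

The test suite exercises the full 64^3 phantom (about 81k brain voxels)
for the recovery and sham criteria and smaller 16-32^3 grids elsewhere;
voxelwise fitting costs a few milliseconds per voxel, dominated by the
Levenberg-Marquardt polish, whose iteration cap (`maxIter = 60`) was
chosen because clean curves converge in well under 30 iterations and
additional iterations on pure-noise voxels change SSE negligibly.

## Known limitations

* No arterial input function, T1 mapping or signal-to-concentration
  conversion: the model describes normalized signal, not Ktrans/ve.
* Masks are inputs; there is no skull stripping or tumor segmentation.
* Registration is rigid only and assumes brains, not deformable anatomy.
* The exponential AOT summary describes a distribution's tail; it is not
  a per-voxel model and says nothing about spatial structure.
* The printed tissue-concentration conversion of the motivating study
  (0.3 ug/g to 690 nM) is not reproducible from the stated density and
  molecular weight; the package follows dimensional analysis (~541 nM)
  and treats the printed figure as an input where downstream printed
  folds are checked.
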