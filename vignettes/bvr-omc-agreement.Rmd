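---
title: "Simulated agreement between biplanar videoradiography and optical motion capture for foot kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated agreement between biplanar videoradiography and optical motion capture for foot kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footbvr)
```

## The problem this package studies

Optical motion capture (OMC) measures foot motion through skin-mounted
retro-reflective markers; biplanar videoradiography (BVR) measures it by
tracking the bones themselves in synchronized two-view x-ray image
sequences. The two disagree for two reasons: skin markers move relative to
the underlying bone (soft-tissue artifact, STA), and markerless bone
tracking has its own, much smaller, error. `footbvr` builds the complete
comparison as a seeded simulation: every trial has a known ground truth, so
each error source can be switched on and off and the agreement statistics
can be checked against exact analytic expectations.

The pipeline reproduces a standard laboratory workflow: phantom "CT" bone
volumes; ground-truth stance-phase bone poses; two calibrated x-ray views
rendering digitally reconstructed radiographs (DRRs); undistortion-grid,
bead-cube and drop-trial calibration; markerless tracking by normalized
cross-correlation (NCC) with downhill-simplex optimization; rigid
co-registration of the two coordinate systems; virtual markers replayed
from tracked bone poses; multi-segment foot kinematics; and waveform
agreement via the linear fit method (LFM), RMSE and per-marker RMS
trajectory differences.

## The synthetic world

**Bones and markers.** Four segments (shank, calcaneus, navicular,
metatarsal) are voxel attenuation volumes built from unions of ellipsoids
with deliberate asymmetries and a seeded 8% attenuation texture, so all six
pose degrees of freedom are observable in two radiographic views.
Anatomical realism of the shapes is *not* attempted: pose observability is
the requirement, since the study's questions concern the measurement chain,
not bone morphology. Each segment carries its share of the 14-marker
Rizzoli multi-segment foot set (3 shank, 4 calcaneus, 1 navicular, 6
metatarsal); marker rest positions approximate the anatomical landmark
layout on a right foot, with the global frame X anterior-posterior,
Y medial-lateral, Z superior-inferior (mm). Rest positions were chosen so
the shank and calcaneus segment frames coincide with the ankle joint frame
in the reference posture, which makes the Cardan planes of the generated
motion decompose cleanly.

**Motion.** Pose programs are closed-form in real time, so the same truth
can be sampled on the radiographic clock and on a mismatched optical clock.
Stance lasts 0.6 s walking and 0.4 s running at 250 Hz (recordings may
truncate it). Ankle rotation amplitudes are sagittal 25°, frontal 5°
(peak-to-peak), transverse 3°, pitched about the ankle joint frame —
sagittal-dominant as in stance-phase gait, with the transverse plane
smallest. The arch flattens and recovers by 8° about a midfoot axis, half
of which the navicular follows. The calcaneus center descends 20 mm into
stance and rises 20 mm out of it through two Gaussian velocity lobes
(width 8% of stance, roughly the 50 ms heel-pad loading time scale), so its
vertical velocity has exactly one interior minimum (heel-strike-like) and
one interior maximum (toe-off-like) — the signature the event detector
relies on. Running scales rotations by 1.3 and deepens the vertical
excursion to 28 mm.

**Soft-tissue artifact.** Each marker's STA displacement is
`amp * (sqrt(1 - g^2) * band-limited noise + g * sagittal drive * u)`,
rescaled so the realized 3D RMS equals `amp`: a fraction `g = 0.6` follows
the ankle's sagittal excursion in a seeded fixed direction `u` per marker
(skin stretch tracks joint motion), and the rest is Gaussian noise
low-passed at 6 Hz (zero-phase 2nd-order Butterworth), covering movement
frequencies. Amplitudes default to per-segment 3D RMS values of 4 mm
(shank, most soft tissue), 2.5 mm (calcaneus), 3 mm (navicular), 3.5 mm
(metatarsals), scaled by 1.6 for running; these sit in the 2–6 mm range
that skin-marker validation studies report for the foot and shank. A
constant per-marker bias and a transient heel-pad compression (10–12 mm
inferior displacement of the calcaneal markers over the first 50 ms after
heel strike) are available but off by default. STA is independent across
markers; real STA is spatially correlated (neighboring skin moves
together), so segment-frame distortions here are somewhat harsher per
millimetre of STA than in vivo — a deliberate, conservative choice.

**Imaging.** Two source/detector pairs sit 130° apart about the global
vertical axis, 600 mm from the scene at 15° elevation, with 128×128
detectors and a 320 px focal length. A DRR pixel is the line integral of
the posed attenuation volume along the source ray, fixed-step (1 mm)
trilinear sampling, computed in compiled code; a scene is the sum of its
bones' DRRs plus optional Gaussian pixel noise. The radiographic global
frame is offset from the optical frame by a fixed rigid transform (20°
about Z, 5° about X, a 250/−120/30 mm translation) that the
co-registration stage must recover.

**Fixtures.** The calibration cube holds 4 layers × 16 beads = 64 known
positions; the co-registration object 11 bead/marker pairs; five
dropped-marker trials share a synchronization trigger; the undistortion
grid is a lattice of Gaussian holes warped by a configurable radial field.
Drop trials bounce elastically off a compliant surface (a smoothed
`|t - T|` valley, 4 ms time constant), so the vertical coordinate is
smooth and symmetric at impact and sub-frame localization is unbiased.

## The measurement chain

**Calibration.** Cameras are solved by normalized direct linear
transformation (homogeneous least squares on 2n×12 with Hartley
normalization) — exact on noiseless beads, with reprojection RMS reported.
Undistortion fits bivariate cubic polynomial displacement fields; the
inverse field is fit against the *fitted* forward map (two extra degrees),
so the forward-then-inverse round trip closes to well below 10⁻³ px
instead of accumulating detection noise twice. Synchronization localizes
each drop's impact as the sub-frame quadratic-interpolated minimum of the
vertical coordinate in both systems; the frame offset comes from trial 1
and the rate ratio is the least-squares slope of optical on radiographic
impact frames across trials. Optical markers are then linearly resampled
onto the radiographic time base; frames mapping outside the optical record
become occlusion gaps.

**Tracking.** For each keyframe (stride 10 frames) the bone's pose is
found by minimizing `1 − mean(NCC)` over the two views with Nelder–Mead in
a local 6-parameter chart (translation offsets in mm, world-frame rotation
vector in radians about the current estimate; scales 10 mm / 0.2 rad, with
two restarts at 0.2× and 0.05× scale to refine convergence). The NCC mask
is the nonzero-DRR region dilated by 5 px; rendering is restricted to a
fixed pixel window around the initial projection so the cost stays cheap
and continuous. Intermediate frames get squad (spherical cubic) quaternion
interpolation and natural cubic splines for translation. Keyframes costing
more than 1.5× the median are re-optimized from their neighbors' spline —
an automated stand-in for manual retracking, chosen so the pipeline is
fully reproducible. Frames whose bone leaves either view are flagged
untracked and excluded downstream. Tracked trajectories are filtered with
a zero-phase 2nd-order Butterworth at 10 Hz applied to the
hemisphere-aligned quaternion components (renormalized afterwards) and to
translations; truth-pose replays skip this smoothing step since they carry
no jitter, which also keeps the zero-STA comparison an exact identity.

**Co-registration and virtual markers.** The rigid map between systems is
the SVD orthogonal Procrustes solution over all available bead pairs, with
the determinant sign corrected so a reflection can never be returned.
Virtual markers are seeded from a static standing trial
(`local = pose⁻¹(marker)`) and replayed through the tracked poses;
untracked frames propagate as gaps.

**Kinematics.** Markers are filtered at 10 Hz (zero-phase, never across
occlusion gaps; the filter uses reflected-and-flipped end padding because
stance series are short relative to the cutoff period). Heel strike and
toe off are the global interior minimum and subsequent maximum of the
central-difference vertical velocity of the inferior calcaneal ridge
marker (ICR), falling back to the superior ridge marker when occlusions
remove a substantial part of the ICR record. Segment frames follow
documented marker-triad recipes (see `?segment_frames`) finished by a
common Gram–Schmidt step; the ankle angle is the Z–X–Y Cardan
decomposition of `t(shank) %*% calcaneus` — z sagittal, x frontal,
y transverse — matching the plane-to-axis naming convention for the ankle.
The MLA angle projects ICR→ST and ST→FMH onto the foot's sagittal plane
(spanned by the ST→FMH axis and the foot-plane normal) and returns the
absolute angle between the projections; the supplement convention is a
documented alternative, and a static reference can be subtracted. Angle
series are isolated from heel strike to toe off, linearly interpolated to
101 points, and analyzed over the 11–75% stance window (65 samples).

**Agreement.** The LFM regresses the radiographic waveform (test) on the
optical waveform (reference) — the direction is a convention, stated here
once — and reports R² (computed directly from residual and total sums of
squares), the intercept a0 and slope a1; identical waveforms give exactly
R² = 1, a0 = 0, a1 = 1, and RMSE = 0. Marker trajectory differences are
true RMS values — the root of the mean squared difference, reported in mm —
with per-axis components along the global axes. Group comparisons use
Shapiro–Wilk normality checks, a Wilcoxon rank-sum test (the usual reading
of a "non-parametric t-test" for unpaired condition comparisons) for
walking vs running RMS, and Kruskal–Wallis across the X/Y/Z directional
components; all statistics are reported without significance gatekeeping.

## Numerical choices

* Quaternions are wxyz with the scalar kept non-negative on conversion;
  sequences are hemisphere-aligned before filtering or spline fitting.
* Zero-phase filtering pads with up to 90 reflected-and-flipped samples
  per end, which suppresses the transients that raw forward–backward
  filtering produces on short stance records.
* The DRR step is 1 mm (roughly one voxel); trilinear sampling keeps the
  NCC cost continuous in the pose parameters, which Nelder–Mead requires.
* Sub-frame impact localization fits a parabola through the discrete
  minimum and its neighbors; the rate ratio is unrecoverable at
  integer-frame resolution over short drops.
* The rate ratio is a single global scalar, mirroring a one-number clock
  correction; per-trial ratios are not fit.
* Degenerate inputs error early and loudly: collinear triads, coplanar
  bead sets, constant images inside the NCC mask, cutoffs at or above
  Nyquist, windows shorter than the 13 frames a 2nd-order zero-phase
  filter needs.

## Problem sizes and the truth-replay mode

The package is sized for deterministic desk-scale runs: volumes at or
below 96³ voxels, 128² detectors, 60–150-frame trials. Full DRR tracking
of one bone over 60 frames takes on the order of a minute; tracking four
bones over ten trials does not belong in a statistics loop. Batch
experiments therefore default to `tracking_mode = "truth"`, which replays
exact ground-truth poses through the whole radiographic chain
(co-registration, virtual markers, resampling, filtering). This isolates
STA and processing effects — the dominant terms in the comparison, since
tracking error is two orders of magnitude smaller than STA — while
`tracking_mode = "drr"` exercises the full image-based path and is
validated separately against ground truth. The plane-dependence experiment
(ten trials per condition) runs in truth mode for exactly this reason.

## What the simulation does and does not show

Passing tests establish that the measurement chain is internally correct:
exact identities with every error source off, tracking accuracy against
known truth, calibration and synchronization recovery of known parameters,
and the qualitative plane dependence of waveform agreement when STA is on
(strongest in the sagittal plane, weakest where motion is small). They do
not certify in-vivo accuracy: phantom bones are ellipsoid unions, STA is a
stochastic model rather than measured skin deformation (and is independent
across markers, unlike real spatially-correlated STA), radiographs carry
no scatter, beam hardening, intensifier distortion or occluding anatomy,
and the marker geometry is one synthetic foot, not a population.
Quantities that depend on those specifics — absolute R² levels, absolute
RMS differences — should be read as scale-realistic, not subject-accurate.
```
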