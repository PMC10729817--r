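---
title: "Detecting the rotation direction of a spinning translucent head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the rotation direction of a spinning translucent head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinsense)
```

## The problem

A human sperm head is translucent, roughly a flattened ellipsoid, and rolls
about its long axis while the cell swims. Because the head barely absorbs
light, a single bright-field focal plane shows it mostly through
*defocus contrast*: the head appears bright when it lies behind the focal
plane (farther from the objective) and dark in front of it, and the switch
happens within a micrometre or two of focus. Watching a 2D movie of such an
object is actively misleading — the eye falls into perception bistability,
and the moving bright feature is an optical artifact whose direction need
not match the physical rotation. `spinsense` implements the multi-plane
(3D+t) approach to this problem: a fast camera synchronized with a
triangular piezo scan of the objective acquires a z-stack on every rising
slope (50 planes of 0.4 µm at 80 Hz in the reference acquisition), each
stack is collapsed to a maximum intensity projection (MIP), and the
direction of rotation is read from how the accumulated bright feature
moves across the head.

## Image formation

Two image-formation constructions are provided, because they answer two
different questions.

**The scene model** (used by the phantom renderer,
`render_frame()`) is multi-slice coherent propagation: the 3D head is cut
into axial slabs, a unit plane wave travelling toward the objective
accumulates each slab's phase (proportional to the material thickness
crossed), and the field is Fresnel-propagated (angular spectrum, paraxial)
between slabs, then to the focal plane, and finally low-pass filtered by
the objective pupil carrying the spherical-aberration phase
$\exp(i\,s\,A_s\rho^4)$. Under this model the through-focus inversion is
not imposed — it emerges: a positive-phase head is a weak converging lens,
so the transmitted light concentrates downstream (toward the objective)
and the head renders bright when the focal plane lies below it, i.e. when
the head is *behind* the plane. Which side renders bright is ultimately a
property of the optical train; the propagation sign is exposed
(`prop_sign`) for systems with the opposite convention.

**The panel model** (`image_weak_phase_object(method = "diffraction")`)
reproduces the classic demonstration figures on the 128×128 grid with a
40×40 object of 0.1 rad phase. Here the aberration function
$W = A_d\rho^2 + A_s\rho^4$ is accumulated with the object field and the
recorded pattern is the squared modulus of a single Fourier transform.
This construction has the distinctive property that the images of a
symmetric object at $\pm A_d$ with $A_s = 0$ are mirror images of each
other — defocus alone produces *no* contrast inversion — while a small
spherical term breaks that symmetry and the interior contrast sign follows
$\mathrm{sign}(A_d A_s)$. The shift-invariant convolution form
(`method = "convolution"`, the textbook pupil-filter model) behaves
differently: its first-order phase contrast is odd in $A_d$ regardless of
$A_s$, which is the familiar under/over-focus inversion and the behaviour
real defocused cells show. Both are kept, with separately calibrated
dimensionless scales (`scale`), because the printed aberration amplitudes
do not fix their physical units; only signs and ratios carry meaning.

One consequence is worth stating plainly: in any first-order
shift-invariant treatment, the bright/dark split across an *inclined*
object is controlled by the sign of the local defocus, not by the sign of
$A_s$ (the half-difference term of the transfer is
$\sin W_d \cos W_s$, even in $A_s$). The package therefore reproduces the
inclined-plate split and its reversal under tilt reversal or an
opposite-sign optical train, but flipping $A_s$ alone does not swap the
halves in the convolution model, and the object-in-aperture construction
degenerates for near-focus slices. This is the one piece of panel
phenomenology the implementation does not reproduce as prose describes it.

## The phantom

`head_phantom()` is a triaxial head (default semi-axes 2.5 × 1.6 × 0.8 µm)
with two deliberate departures from a textbook ellipsoid:

* **Peak phase 0.9 rad**, the optical path of a ~1.6 µm thick head at a
  refractive-index excess of about 0.05 over the medium. The 0.1 rad used
  in the demonstration panels is kept for those objects, but it is an
  illustration value; a real head is not that weak, and at 0.1 rad the
  rendered rotation signature drowns in quantization.
* **Dorso-ventral face asymmetry** (`face_asymmetry = 0.25`): one face is
  rounder, the other flatter, as in the paddle-like shape of real human
  sperm heads. This matters for a structural reason. A perfect triaxial
  ellipsoid is mirror-symmetric, so the image sequence of a CW roll is
  exactly the column-mirror of the CCW sequence, and the weighted-average
  trace obeys $\bar{x}_{CW}(t) = 1 - \bar{x}_{CCW}(t)$. A waveform that is
  symmetric within its period is invariant under that flip up to a time
  shift — the rotation direction of an ideal ellipsoid is mathematically
  ambiguous in this observable. The face asymmetry (and, in real cells,
  every other departure from perfect symmetry) skews the waveform: the
  bright border sweeps slowly across the head and snaps back, and the
  excursions of $\bar{x}$ are predominantly toward one end of the probe
  segment. That skew is the chirality signal.

Motion is rigid-body: constant in-plane velocity along a fixed heading,
constant roll rate (CCW defined by an observer looking from the tip toward
the flagellum with "up" away from the objective; the label `"none"` means
zero roll), and a 1 µm axial wobble at the roll frequency so the head
crosses focal planes as real cells do. An optional translucent particle
attached near the neck co-rotates on a ring about the roll axis; it
renders bright while above the focal plane and dark below, the behaviour
used to validate the method against a physical marker.

`generate_stack_series()` renders one frame per camera tick along the
triangular scan and groups rising slopes into stacks. `pose_per = "stack"`
freezes the pose at each slope's mid-time and reuses one propagated field
for all of its planes — a rising slope lasts 1/160 s, over which a
3–8 Hz head advances 7–18°, and the approximation changes no validation
outcome while making large cohorts an order of magnitude cheaper. Noise is
additive Gaussian on intensity (the unit background), seeded; the
acquisition seed makes whole records byte-reproducible.

## Detection

Per stack: the MIP, then a moment-based tracker (Otsu threshold of the
absolute deviation from the background, largest connected component,
deviation-weighted centroid and principal axis), with the tip direction
resolved from the motion of the centre (the tip leads). The probe segment
is built as follows: the perpendicular line crosses the head
axis $L/3$ ahead of the centre toward the tip, with endpoints $b$, $b'$ at
±`w` µm. The handedness is fixed by the imaging geometry declared above:
$b'$ lies along the tip direction rotated by −90° in image (x = column,
y = row) coordinates — the side toward which the slow sweep of the bright
border advances under CCW roll, as both the lab-frame right-hand-rule
derivation and the rendered phantoms agree — which makes the operational
rule, the profile feature moving from $b$ to $b'$ means CCW, hold end to
end against the generator's ground truth. Stated prose conventions for which
side is "left" in a head-to-tail view depend on an unstated screen-mirror
convention and cannot be fixed from text alone; deriving the handedness
from the rendering geometry resolves the ambiguity by construction.

The weighted average $\bar{x} = \sum_i I_i x_i / \sum_i I_i$ is computed on
min-subtracted profiles by default: on raw grey levels the statistic is
dominated by the flat background (adding a constant provably pulls
$\bar{x}$ toward 0.5), while min-subtraction isolates the moving feature.
Raw mode remains available.

`classify_rotation()` gates non-rotating cells on the robust amplitude
of the x-bar trace (5th–95th percentile span, threshold 0.035 in
normalized units, about twice the trace noise at 5 % intensity noise).
The advance direction is then measured directly on the kymograph: the
dominant cross-correlation lag between consecutive profiles — after
subtracting the temporal mean profile, so the static head structure does
not pin the lag at zero — is the local slope of the kymograph stripes.
The slow border sweep gives many small same-sign lags; the half-turn
resets give rare large opposite ones, which are discarded before the
majority vote. Confidence is the fraction of retained lags agreeing with
the call; sweep cycles are counted from alternating trace extrema with
prominence of half the amplitude. For trace-only input (no profiles) the
classic step rule applies: the median step gives the drift, large
counter-drift steps are discarded as resets, and the call is the sign
majority of the rest. Calls with fewer than two sweeps or confidence
below 0.6 fall back to non-rotating with a low-confidence flag. All
thresholds are exposed in `classify_params()` and the run
configuration.

## Validation suite and its scope

The acceptance tests (and `scripts/acceptance.R`) validate the chain at a
scaled acquisition chosen so the full render–detect loop stays cheap:
128×128 frames at 0.10 µm/pixel, 16 planes of 0.5 µm per rising slope at
80 Hz (2560 frames/s), with records long enough to hold at least three
full rotations (0.5–1 s; the reference 3.4 s records hold ten or more at
any plausible roll rate) — against the reference acquisition's 640×480 at
8000 frames/s, 50 planes of 0.4 µm. Thirty phantoms mix
CCW/CW/non-rotating, roll rates 3–8 Hz, four diagonal swim quadrants and
head heights spanning the scan middle, at 2 % and 5 % intensity noise.
Plane spacing and scan margins matter: with ~1 µm planes or a head within
~1.5 µm of the scan top, the near-focus renderings that carry the
asymmetry are missed and weak-signal cells degrade toward non-rotating
(never toward the opposite direction), which is why the suite keeps
0.5 µm spacing and central head heights.

What passing shows, and what it does not: the phantom exercises the
geometry, the optics of a rolling translucent body, noise, and every
orientation convention end to end — but it is a rigid body with a clean
background. Real recordings add flagella, debris, intensity flicker,
imperfect triangular scans and tracking hand-off; the classifier
thresholds here are calibrated to the phantom's signal scale and would
need recalibration against annotated real data.

## Degenerate inputs and numerical choices

Zero-phase objects render exactly flat frames under the convolution scene
model; an all-zero (background-free) profile raises an undefined-x̄ error
and the stack is excluded; a trace shorter than `min_stacks` raises an
insufficient-data error; a blank or featureless MIP raises a tracking-lost
error carrying the stack index. Frames are stored as 16-bit grey levels
with an affine intensity calibration in the JSON sidecar, which makes the
write–read–write cycle byte-identical while keeping files text-tool
friendly. FFT grids use even sizes with the optical axis at
`n/2 + 1`; mirroring a scene through a vertical image plane is exact at
the pixel level, and the mirror test (CW phantom = column-mirrored CCW
phantom, opposite call) is asserted pixel-exactly in the suite.
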