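# spinsense

Determining which way a translucent, axially symmetric object spins —
the human sperm head being the motivating case — from multi-plane
bright-field microscopy.

## The problem and who this is for

A sperm head rolls about its long axis as the cell swims. The head is
translucent and nearly mirror-symmetric, so 2D movies are unreliable: the
visible bright feature is a defocus-contrast artifact whose apparent motion
need not follow the physical rotation, and human observers fall into
perception bistability. The multi-plane (3D+t) approach acquires a z-stack
on every rising slope of a triangular piezo scan (50 focal planes of
0.4 µm at 80 Hz, 8000 frames/s in the reference acquisition), collapses
each stack to a maximum intensity projection (MIP), and reads the rotation
direction from the motion of the accumulated bright feature across the
head. `spinsense` implements that pipeline for people building or
validating rotation assays: the image-formation simulator, a synthetic 4D
phantom generator with ground-truth labels, the detection chain, and
population-level reporting.

## The method

Per rising-slope stack, with `I_MIP` the maximum intensity projection:

1. Track the head on the MIP (threshold, largest component, weighted
   centroid `a`, principal-axis angle `φ`; the tip direction is resolved
   from the motion of `a` — the tip leads).
2. Construct the probe segment: the line `C'` perpendicular to the head
   axis crosses it `L/3` ahead of `a` toward the tip; endpoints `b`, `b'`
   sit `±w` µm along `C'`.
3. Sample the grey-level profile along `b→b'` and form the weighted
   average (the intensity centre of mass)

   `x̄ = Σᵢ I_MIP,i · xᵢ / Σᵢ I_MIP,i ,  x ∈ [0, 1]`.

4. Classify the trace `x̄(t)`: the bright border sweeping from `b` to `b'`
   between abrupt resets means counterclockwise (CCW) rotation as seen from
   head to tail; `b' → b` means CW; a flat trace means non-rotating.

The simulator renders rolling 3D head phantoms through multi-slice Fresnel
propagation (the head is a weak converging lens, so it appears bright
behind the focal plane and dark in front — the through-focus contrast
inversion the method exploits), and separately reproduces the classic
contrast-inversion demonstration panels in which a small spherical
aberration term `A_s ρ⁴` gates the inversion of a defocused weak phase
object. See the methods vignette (`vignettes/rotation-direction.Rmd`) for
the models, conventions and their calibration.

## Worked example

```r
library(spinsense)

cfg <- acquisition_config(fps = 2560, scan_hz = 80, scan_amplitude = 8,
                          pixel_size = 0.10, frame_shape = c(128, 128),
                          duration = 0.5, noise_sd = 0.02, seed = 7)
motion <- motion_model("ccw", rotation_hz = 5, swim_speed = 9,
                       initial_position = c(-2.2, 0, 4))
series <- generate_stack_series(head_phantom(), motion, cfg,
                                aberration_model(A_s = -4e-4,
                                                 pupil_frac = 0.6),
                                pose_per = "stack")
res <- detect_series(series, L = 5, w = 2)
str(res$call)
#> List of 7
#>  $ direction     : chr "ccw"
#>  $ confidence    : num 0.964
#>  $ amplitude     : num 0.0705
#>  $ frequency_hz  : num 12.3
#>  $ n_halfcycles  : int 12
#>  $ n_stacks      : int 40
#>  $ low_confidence: logi FALSE
```

A 0.5 s record of a 5 Hz CCW phantom: the call recovers the planted
direction with 96 % of the retained kymograph shifts agreeing, the x̄
trace sweeps with a normalized amplitude of about 0.07, and twelve sweep
segments are counted over the 40 stacks (`frequency_hz` is the x̄
oscillation rate — about twice the roll rate here, because the
asymmetric-faced head produces two excursions per full turn). `res$trace`
holds the x̄ series and `res$kymograph` the position-by-time profile image
whose stripe slopes encode the direction.

The same pipeline is scriptable end to end:

```sh
inst/cli/spinsense simulate --config run.yaml --out sim/
inst/cli/spinsense detect   --in sim/ --out det/
inst/cli/spinsense report   --calls det/call.csv --out rep/
inst/cli/spinsense optics-demo --out panels/
```

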