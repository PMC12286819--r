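---
title: "Glottis-driven prompt engineering for vocal-fold segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glottis-driven prompt engineering for vocal-fold segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfprompt)
```

## The problem

Laryngeal high-speed videoendoscopy resolves individual oscillation cycles
of the vocal folds. Segmenting the *glottis* — the dark air gap between the
folds — is a well-served task: large annotated datasets exist and a plain
U-Net does it well. Segmenting the *vocal folds themselves* is not: fold
tissue has variable outline and color, annotations are scarce, and most
clinical waveforms (such as the glottal area waveform) are therefore
derived from the glottis alone, which says nothing about each fold
individually.

`vfprompt` implements a pipeline that bridges this gap without any
fold-level training data. The key observation is that a glottis network's
*sub-threshold* activations carry fold information: thresholding the
per-pixel probabilities at the usual 0.5 yields the glottis, but
thresholding at a very small value (the default is 1e-20) uncovers a rough,
noisy mask of the surrounding fold region. The pipeline distills that rough
evidence into two clean prompts — a bounding box and up to nine foreground
points — and hands them to a promptable segmentation backend (a
Segment-Anything-style model behind a minimal function contract), which
produces the actual fold mask. Thresholds are applied to probabilities
(post-sigmoid); adapters for networks that emit logits must apply the
sigmoid first.

## Pipeline

For each frame:

1. **Masks.** The probability map is binarized twice: at
   `glottis_threshold` (0.5) for the glottis mask and at `low_threshold`
   (1e-20) for the fold evidence. Binarization is strict (`p > t`), so a
   tie at 0.5 is deterministic.
2. **Box prompt.** A second low-threshold mask is mined from the
   CLAHE-enhanced frame (local contrast enhancement makes the network
   respond on more of the fold surface, at the price of more spurious
   activations). The enhanced mask replaces the raw one *only inside the
   detector's box*, so the extra noise cannot leak elsewhere; the glottis
   mask is added; the union is pose-normalized (glottal axis made
   vertical, glottis centroid moved to the image center); morphological
   closing connects nearby components; the connected region that contains
   the glottis is selected, mapped back to the original frame through the
   inverse transform, and its bounding box is averaged corner-wise with
   the detector box.
3. **Point prompt.** Three scan lines orthogonal to the glottal axis pass
   through the quadrisection points of the top-to-bottom glottal segment.
   Along each line the gray profile is sampled bilinearly at 1-px
   stations, differentiated by central differences, and smoothed by a
   moving average. Scanning outward from the glottis, the first
   qualifying local maximum on the left and local minimum on the right
   mark the outer fold boundaries (intensity rises sharply from shadow
   onto the left fold and falls sharply off the right fold). The found
   boundary points plus the three glottis landmarks (top, centroid,
   bottom) form the point prompt — nine points when every line succeeds
   on both sides.
4. **Backend iterations.** Iteration 1 passes the points only and keeps
   the returned mask logits; intermediate iterations pass points plus the
   previous logits; the final iteration adds the box. The default is two
   iterations. The resulting fold mask has the glottal gap removed and is
   split into left and right folds by the infinite line through the top
   and bottom glottis landmarks; pixels exactly on the line go left.

Waveforms are then read off the labeled masks per frame: the glottal area
waveform (GAW, glottis pixel count), and for each fold side and midline
station the vocal-fold movement (VFM, mean distance of the fold's inner
and outer boundary from the midline) and vocal-fold width (VFW, gap
between inner and outer boundary). The midline is the segment from D (the
midpoint of the bottommost glottis row) through the centroid C to T, the
last point of the mask along that ray.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `low_threshold` | 1e-20 | probability | uncovers fold evidence in the network output; the best-performing value of the method's configuration sweep |
| `glottis_threshold` | 0.5 | probability | standard binarization |
| `clahe_clip`, `clahe_tiles` | 2.0, 8x8 | -, tiles | stock CLAHE settings; the method prescribes CLAHE but no parameters |
| `kernel_radius` | 5 | px | closing element radius; large enough to bridge the few-pixel gaps between low-threshold fragments, small enough not to merge with distant noise |
| `iterations` | 2 | - | the best-performing iteration count of the method |
| `smooth_window` | 5 | stations | moving-average width for the derivative profile |
| `prominence` | 1.0 | gray/px | floor on the derivative magnitude of a boundary extremum (see below) |
| `detector_margin` | 30 | px | "a few dozen pixels" of dilation when generating detector training labels |
| `n` (stations) | 3 | - | midline stations for VFM/VFW |
| `max_radius` | width/2 | px | marching limit for scan lines and fold intersections |

## The phantom

`phantom_params()` / `generate_frame()` render a lens-shaped glottis (the
intersection of two circular arcs, which gives distinct top and bottom
landmark points) flanked by two brighter fold bands on darker tissue, with
a controllable axis angle, a linear illumination gradient along the image
diagonal (so CLAHE has something to equalize), Gaussian sensor noise
(added after quantization, clipped to [0, 255]), and a sinusoidally
oscillating glottal half-width `g(t) = g + A sin(2 pi f t)`. Frames where
the oscillation closes the glottis have an empty glottis mask while the
fold masks remain intact, which exercises the closed-glottis exclusion
rule of the width waveform. `emulate_probability_map()` reproduces the
low-threshold phenomenon (high probability on the glottis, a tiny positive
value on the folds and on a seeded fraction of background pixels), and
`jittered_detection()` reproduces a detector's failure modes (missing,
grossly displaced, or undersized boxes).

Every frame carries analytic ground truth computed from the continuous
geometry — per-row fold-edge x-coordinates and per-scan-line edge
crossings at 0.05-px resolution — so tests compare extracted quantities
against closed-form geometry rather than against the rasterized masks
they were derived from.

The phantom deliberately does *not* emulate color, specular highlights,
camera motion, mucus, or anatomical asymmetry. Passing tests therefore
demonstrate the correctness of the geometry, prompt logic and waveform
extraction, not clinical performance on real recordings; the backend
mocks (an oracle keyed to prompt quality and an Otsu-box filler) likewise
test the prompting contract, not any foundation model.

## Numerical choices

* **Coordinates** are 0-based pixel centers, x rightward along columns,
  y downward along rows; boxes are `(x_min, y_min, x_max, y_max)` in
  those continuous coordinates.
* **Nearest-pixel lookup** rounds half-integers up (`floor(x + 0.5)`)
  rather than half-to-even, so 1-px marching from half-integer anchors
  visits every pixel exactly once.
* **Adaptive prominence.** A fixed 1.0 gray/px floor admits spurious
  extrema once sensor noise is realistic: with noise SD 5 the smoothed
  derivative has noise SD about 1.6. The effective threshold is therefore
  `max(floor, 3 * MAD of the smoothed derivative)`, which suppresses
  noise extrema on the fold surface while leaving clean imagery at full
  sensitivity. On the phantom pose/noise sweep this keeps the mean
  boundary error near 1 px.
* **Plateau ties.** On noise-free imagery the smoothed derivative can
  plateau exactly across two stations at an edge; strict extremum
  comparisons would then find nothing. Ties within 1e-6 are bridged and
  the outward plateau end is taken, which matches the continuous edge
  location.
* **Pose normalization** resamples binary masks by nearest neighbor
  (preserving binarity) under a rotation about the glottis centroid
  followed by a translation to the image center. The residual-angle
  checks use a long-glottis phantom (half-length 80 px in a 256-px
  frame): the landmark definition — midpoint of the extreme mask row's
  run — carries +-0.5 px of quantization, about 0.45 degrees at
  half-length 32, which would otherwise measure the landmark estimator
  rather than the transform.
* **Contour selection** closes the union of evidence and glottis with a
  disc element, fills holes, labels components, and picks the component
  containing at least 99% of glottis pixels (largest on ties), falling
  back to the largest overlapping component, then to the glottis dilated
  by the kernel radius. CLAHE requires tile-multiple dimensions, so the
  image is edge-padded and cropped back.
* **T point** of the midline is found by marching the ray from D through
  C at 0.25-px steps; the last sample inside the mask is T, which can
  overshoot the last pixel center by up to half a pixel (the mask edge).
* **Degenerate inputs.** An empty glottis raises a typed closed-glottis
  condition that `segment_frame()` converts into a flagged result (empty
  fold labels) instead of a crash; detector boxes with area below 25 px^2
  are treated as absent; a single-pixel glottis yields coincident
  landmarks with angle 0.

## Open design points, resolved

* *Box mapping direction.* The selected region lives in the normalized
  frame; its pixels are mapped through the **inverse** transform back to
  the original frame before the bounding box is taken, so the averaged
  boxes share the detector's coordinate frame.
* *Glottis points as fold prompts.* The glottal gap is not fold tissue,
  yet the three glottis landmarks are kept in the point prompt by
  default, as the method prescribes; `vf_config(include_glottis_points =
  FALSE)` switches them off.
* *Glottal gap in the fold mask.* The gap is subtracted before the
  left/right split by default; `vf_config(keep_glottis_in_vf = TRUE)`
  keeps it.
* *Left/right* follow image orientation (left = smaller x), not patient
  orientation.
* *No-prompt ablation* calls the backend with no prompts and takes the
  single mask it returns with its confidence; the shipped mocks return
  one candidate.

## Problem sizes

The test suite and the acceptance script run entirely on generated
phantoms: 128-px frames for most checks, a 6-condition pose/noise sweep
of 20 frames each for boundary recovery, 50 frames for the end-to-end and
ablation comparisons, 100 frames for waveform frequency recovery, 256-px
frames for the orientation-residual checks, and 100 randomized multi-blob
masks for the contour-selection oracle.

## Known limitations

* The backend contract is per-frame; video propagation (memory-bank
  tracking across frames) is out of scope.
* Real SAM/SAM2 checkpoints are not bundled; adapters satisfying the
  backend contract plug in, but the shipped backends are deterministic
  mocks.
* Waveform station distances are integer-pixel (1-px marching); widths
  are accurate to about a pixel.
* The left/right split is a straight midline cut; strongly curved
  glottides would mislabel pixels near the midline.
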