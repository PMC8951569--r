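---
title: "Dye-free coronary tracking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye-free coronary tracking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corotrack)
```

## The problem

During cardiac catheterization a cine-angiogram records the beating heart
under X-ray. Coronary arteries are only visible while radio-opaque contrast
dye fills them; in the frames before injection (and after washout) the
vessels are invisible, even though structures of clinical interest — e.g.
calcifications, stents — are only assessable there, because the dye masks
them. Every acquisition, however, contains at least one *dye-free* cardiac
cycle before injection, and the heart's motion is periodic: for every
dye-free frame there exists a contrasted frame showing the heart in (nearly)
the same mechanical configuration.

`corotrack` exploits exactly this. It:

1. segments the coronary tree in the contrasted ("template") frames with a
   multi-scale Hessian vesselness filter plus morphological cleanup;
2. finds the contrasted window automatically from the per-frame count of
   segmentable vessel pixels (with manual override);
3. associates every dye-free frame with its most similar template by
   zero-lag normalized cross-correlation (NCC) — the arg-max over templates
   is the cardiac-phase association;
4. transfers the winning template's vessel contour onto the dye-free frame,
   yielding a dye-free estimate of coronary position.

It does **not** register or deform anything: association is wholesale,
per-frame. It does not measure the lumen (no QCA), and it has no GUI — the
workflow is driven from R or the bundled CLI.

## The vesselness model

For a frame $I$ smoothed at scale $\sigma$, let
$\lambda_1, \lambda_2$ ($|\lambda_1| \le |\lambda_2|$) be the eigenvalues of
the $\sigma^2$-normalized Hessian. With blobness $R_B = \lambda_1/\lambda_2$
and structureness $S = \sqrt{\lambda_1^2 + \lambda_2^2}$, the per-scale
response is

$$V_\sigma = \begin{cases}
0 & \text{if the polarity sign condition fails}\\[2pt]
\exp\!\left(-\dfrac{R_B^2}{2\beta^2}\right)
\left(1 - \exp\!\left(-\dfrac{S^2}{2c^2}\right)\right) & \text{otherwise,}
\end{cases}$$

and the vesselness is $V = \max_\sigma V_\sigma$. Contrast-filled vessels are
dark on bright in standard display, so the default polarity keeps
$\lambda_2 > 0$.

### Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `sigmas` | 1–5 px | vessel half-widths expected at the working resolution; strictly increasing, config-exposed |
| `beta` | 0.5 | classic line-vs-blob sensitivity of the reference filter |
| `c` | 15/255 ≈ 0.059 | the classic default of 15 presumes 8-bit intensities; the Hessian scales linearly with intensity, so on `[0,1]`-normalized frames the equivalent value is 15/255 |
| threshold | Otsu over *nonzero* vesselness | the zero-forced margin and polarity-suppressed pixels would otherwise dominate the histogram |
| `min_component_px` | 50 | specks below ~50 px at this resolution are noise, not vessel segments |
| `closing_radius_px` | 1 | bridges 1-px gaps along faint vessels |
| `dilation_radius_px` | 5 | background mask must exclude the dye-gradient halo, not just the lumen (see below) |
| detection `fraction` | 0.3 | relative threshold adapts across acquisitions with different tree sizes |

Two numerical details are deliberate:

* **Border handling.** Gaussian derivatives use reflect padding, and the
  response is forcibly zeroed on a margin of $\lceil 3\sigma_{\max}\rceil$
  pixels — boundary derivative estimates are unreliable and would otherwise
  seed spurious components.
* **Structuring element.** All binary morphology uses the Chebyshev ball
  (a $(2r{+}1)\times(2r{+}1)$ square). The package fixes 8-connectivity for
  components and boundary tracing throughout, and the Chebyshev ball is the
  element whose radius-1 closing bridges exactly the gaps that break
  8-connectivity; a Euclidean radius-1 disk (a diamond) cannot close a 1-px
  gap in a 1-px line.

## Contours as exact objects

Contours are traced on the pixel *crack* grid: polyline vertices are
half-integer corners between pixels, outer boundaries and holes are separate
closed polylines, and filling is an even-odd parity scan over pixel centers.
This representation makes `fill_contours(extract_contours(m)) == m` an exact
identity for *any* mask — not an approximation — which in turn makes
"transferred contour vs. true mask" Dice values trustworthy: any loss is
attributable to segmentation or association, never to contour plumbing.

## Matching on the background, not the vessel

The central gap in a template-matching design is *which pixels to compare*:
templates contain dye, dye-free frames do not, so correlating on or near the
vessel systematically rewards templates whose dye pattern happens to match
background texture. Each template therefore carries a background mask — the
complement of its vessel mask dilated by 5 px (lumen plus dye halo) — and
the default `region_mode = "background"` scores NCC only there, on
dye-independent anatomy. `region_mode = "full"` is retained for comparison.

Degenerate comparisons (zero variance over the region) score 0 with a
warning and can never beat a genuine positive correlation; exact ties
resolve to the lowest template frame index, for determinism.

## What the synthetic world does and does not emulate

`phantom_config()` renders 96×96 px, 60-frame loops (period 20 frames, bolus
frames 20–45 with 3-frame linear wash-in/wash-out ramps): a desk-scale
stand-in for 512×512 clinical loops, chosen once so the full 50-replicate
detection study runs in minutes on one CPU. It emulates:

* a branching tree of cubic-spline centerlines with linearly varying width,
  optional Gaussian-profile stenoses (throat width = width × (1 − severity));
* periodic cardiac motion — translation plus a row-dependent sinusoidal
  bending — applied **globally**, to vessels *and* background. The
  configuration calls the background anatomy "static" in the sense of
  time-invariant content, but that content rides the cardiac deformation:
  if it did not, dye-free frames (in which vessels are invisible) would
  carry no phase information at all and similarity-based phase association
  would be impossible in principle, not just in this implementation;
* background anatomy at two spatial scales: smooth structures (illumination
  gradient, broad blobs, a gentle diaphragm-like step, a wide rib band) and
  *fine static texture* (smoothed noise, sd 0.04, ~1.5 px correlation). The
  fine texture is what gives NCC its phase discrimination — smooth
  structures barely decorrelate under pixel-scale displacements — while
  staying below the vesselness filter's contrast regime so it does not
  segment as vessel;
* additive Gaussian temporal noise (σ = 0.02) and value clipping to [0, 1].

The displacement depends on the frame index only through `t mod P`, so in
the noise-free limit frames one period apart are bit-identical — several
tests rely on this exactness.

Not emulated: X-ray physics (scatter, beam hardening, quantum noise
statistics — noise is Gaussian, not Poisson), ECG signals, breathing or
table panning, deformable (non-periodic) motion, calcifications, and
anything out-of-plane. A green test suite therefore establishes that the
pipeline is internally correct and recovers phase/geometry under periodic
motion with realistic contrast ordering — it does not establish clinical
performance on patient angiograms.

## The static limit

With zero motion and zero noise every frame is identical and "cardiac
phase" is unobservable by construction; any template is as correct as any
other. The static-limit criterion (mean Dice and phase hit rate exactly 1)
is therefore asserted on *phase-perfect assignments* built from a
ground-truth-derived template bank: it pins down the evaluation arithmetic
and the exactness of contour transfer. The real tracker is run in the same
test and must also reach Dice exactly 1 (whichever template wins a tie, its
contour is identical in the static limit).

## DICOM support

No DICOM library exists in the deployment environment, so the package
carries a minimal codec: Part 10 files, implicit/explicit VR little endian,
uncompressed single-sample MONOCHROME1/2 at 8 or 16 bits, multi-frame
objects or single-frame series (ordered by InstanceNumber, ties by
filename). MONOCHROME1 is inverted on read so radio-opaque structures are
always dark. Compressed transfer syntaxes and undefined-length elements are
rejected with a clear error. Intensity normalization is min–max over the
*whole sequence* — per-frame normalization would erase the inter-frame
brightness dynamics that bolus detection measures. The codec is validated by
round-trips against the package's own writer; it has not been exercised
against third-party DICOM implementations, which is the main caveat for
clinical files.

## Known limitations

* Zero-lag association only: no translation search, registration or optical
  flow; accuracy degrades if breathing/table motion breaks periodicity.
* Per-frame association, no temporal smoothing of template assignments.
* Frames after washout are excluded from tracking by default (residual-dye
  risk); opt in via `include_post_washout`.
* The automatic window rule (longest run ≥ 30% of peak opacity) is this
  package's declared criterion — the clinical workflow it models leaves the
  rule unspecified — and manual override is always available.
* Overlay export is a PNG sequence; no video encoder is assumed present.
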